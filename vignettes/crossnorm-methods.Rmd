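---
title: "Cross normalization: model, conventions and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross normalization: model, conventions and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossnorm)
```

# The problem cross normalization solves

Quantile normalization and its relatives rest on two assumptions: only a
small fraction of genes change between arrays, and up- and down-regulation
are roughly balanced. Many tumour/normal comparisons violate both —
transcriptional amplification raises the majority of transcripts in the
tumour, so the *biological* signal itself is a condition-wide distribution
shift. A column-wise normalizer cannot distinguish that shift from a
technical batch difference and removes it, with two consequences for
downstream differential analysis: fold changes of genuinely up-regulated
genes shrink (lost recall), and genes that did not change acquire apparent
*down*-regulation (false positives with inverted direction).

Cross normalization changes the unit that is normalized. With control
profiles $C_1,\dots,C_{n_1}$ and disease profiles $D_1,\dots,D_{n_2}$ over
$m$ genes (log2 scale):

* **Pairwise variant** (requires a paired design, $n_1=n_2$): form one
  cross-column $Z_i = [C_i; D_i] \in \mathbb{R}^{2m}$ per matched pair,
  normalize the $n_1$ cross-columns jointly with the base normalizer, and
  split each back into its halves.
* **General variant** (unpaired): form all $n_1 n_2$ cross-columns
  $Z_{ij} = [C_i; D_j]$, normalize them jointly, then average each control
  sample's $n_2$ normalized copies and each disease sample's $n_1$ copies.

The key assumption is exchangeability of the cross-columns, not of the
individual arrays: each $Z$ contains one draw from each condition, so all
cross-columns share a distribution even when the two conditions differ
systematically. Matching *their* distributions removes array-level
technical variation while the between-condition difference — which lives
*inside* each cross-column — survives. Because a quantile map is monotone
within a column, the sign of every within-pair difference $D_i[g]-C_i[g]$
is preserved exactly; this is the mechanism behind the method's robust
direction calls.

The cost of the general variant is $n_1 n_2$ columns of length $2m$; the
package materializes this matrix directly (about 240 MB of doubles for
$m = 12{,}752$ and $34\times34$ samples), which is well within a typical
analysis machine and keeps the implementation exactly equal to the
definition.

# Base normalizers and their conventions

* **Quantile** (`quantileNormalize`): the reference distribution is the
  across-column mean of within-column sorted values; each value is replaced
  by the reference value at its within-column rank. *Ties*: all members of
  a tied run receive the mean of the reference values over the tied rank
  span — deterministic, order-independent, and idempotent. Ranks use a
  stable sort. This tie rule differs slightly from limma's rank
  interpolation; on tie-free input the two agree to machine precision, and
  the test suite uses limma as an independent cross-check there.
* **Baseline** (`baselineNormalize`): median scaling, implemented as an
  additive shift on the log2 scale, to the median of all column medians.
* **Cyclic loess** (`loessNormalize`): pairwise M–A loess via
  `limma::normalizeCyclicLoess(method = "pairs")` with span 2/3 and one
  iteration by default (both configurable). One sweep leaves a small
  residual trend on strongly heteroscedastic input; the tests therefore
  assert a large *reduction* of the M–A trend rather than an exact zero.
  Nothing downstream depends on loess specifics.

All calculations are on the log2 scale throughout, which makes the fold
change a difference of group means; raw intensities can be transformed at
load time with `log2(v + 1)`. Missing values are rejected rather than
imputed. Probe-to-gene collapsing averages the mapped probes' values on
the stored (log2) scale, and outputs genes in lexicographic order so the
operation is deterministic; collapsing before versus after log transform is
not equivalent, and this package defines the operation on the stored scale.

# Differential calling and consistency statistics

DEGs are called by the dual criterion $|\mathrm{log2FC}| \ge 0.8$ **and**
$p < 0.01$ (fold-change threshold inclusive, p threshold exclusive), with
no multiple-testing correction by default — fold-change ranking with a
non-stringent p filter is the composition that gives reproducible lists
across sites and platforms; an optional BH adjustment is available. The
test is Welch's unequal-variance two-sample t by default (a paired t is
available but not the default, since group-comparison calling is the
established benchmark convention). Degenerate genes: zero pooled standard
error with equal means gives $t = 0, p = 1$; with unequal means, $p = 0$.

The overlap coefficient is the Dice form
$\mathrm{OC} = 2|X \cap Y| / (|X| + |Y|)$ — the form that reproduces the
published consistency percentages from their printed counts (e.g.
$2\cdot 3111/(3120+3145) = 99.31\%$), which min- or max-denominator
variants do not. Direction overlap DOC1 is the fraction of list 1's DEGs
whose log2FC *sign* in the other route's table agrees; genes absent from
the other table cannot match. Empty sets yield coefficient 1 (vacuous
agreement) by documented convention; zero-denominator metrics yield 0 with
a warning (for MCC, 0 is the random-prediction value). ROC summaries are
deliberately omitted: differential calling uses one or a few fixed cutoffs,
so cutoff-sweeping curves answer a different question than MCC does.

# The simulation engine

`synthBaseMatrix` emulates a cohort of normal-tissue arrays: gene means
$\mu_g \sim 4 + \mathrm{Gamma}(2, 1.5)$ clipped at 14 (right-skewed, the
typical log2-intensity range), gene standard deviations
$\sigma_g \sim U(0.2, 0.6)$, values $\mathcal{N}(\mu_g, \sigma_g)$. The
default study scale mirrors a 12,752-gene, 34-samples-per-group esophageal
cohort.

`simulatePairedDataset` injects truth: $\mathrm{round}(m\cdot
\texttt{deRatio})$ DEGs of which $\mathrm{round}(m\cdot
\texttt{downFraction})$ (default 10% of all genes) are down-regulated and
the rest up — e.g. 20% up + 10% down at a 30% DE ratio — each with a
magnitude drawn uniformly from $\{0.8, 1.0, 1.2\}$. The disease mean is
the control group mean plus the assigned log2FC, plus an optional
condition-wide `globalShift`, plus centred, variance-standardized
chi-squared noise $s\,(\chi^2_k - k)/\sqrt{2k}$. The chi-squared
parameters are not pinned down by any published value; the package adopts
$k = 4$ and $s = 0.05$ log2 units — skewed, and deliberately small against
the biological $\sigma_g$ — as its defaults, configurable. Down-DEGs are
drawn first, then up-DEGs, from a single shuffled index stream, so the
down count is exact and truth-set sizes depend only on $(m,$ ratios$)$,
not the seed. Rounding is half-up, documented so truth sizes are
reproducible. Pairing is positional (control $i$ with disease $i$).

What the generator does **not** emulate: probe-level effects
(cross-hybridization, GC content), array-specific intensity-dependent
distortions, batch structure, and correlated gene modules. Tests passing
on this generator therefore demonstrate the *algorithmic* claims
(shift preservation, direction preservation, variant consistency), not
robustness to every artifact of real arrays.

The spike-in constructor mirrors a comparison-design spike-in chip:
14,010 probes, 1,331 with concentration fold $> 1$ (the true DEGs), 2,535
spiked unchanged, the rest empty. A profile at DE ratio $r$ contains all
fold-changed probes plus $\mathrm{round}(1331/r) - 1331$ probes sampled
without replacement from the unchanged + empty pool (4,437 genes at
$r = 0.3$), three replicate arrays per condition, disease elevated by
$\log_2(\mathrm{fold})$. An alternative construction — sweeping the fold
threshold instead of the pool size — exists but is not implemented, since
the pool-size construction is the one that reproduces the published
profile size.

# Titration trend analysis

A titration series (L, M1, M2, K mixtures of two tissues, equal replicate
counts) implies monotone expression trajectories without per-gene ground
truth. For each gene the three adjacent differences (M1−L, M2−M1, K−M2)
are tested with Welch t-tests at $\alpha = 0.01$ (configurable); the
verdict triple maps to eight categories: NMT (≥1 significant increase and
≥1 significant decrease — a processing artifact, since a titration cannot
be non-monotone), NST (no significant change), and 1–3 up/down for
monotone trends by their number of significant steps. The original
published trend analysis used a dedicated order-restricted testing package;
this package substitutes the per-step Welch construction deliberately — the
category logic and the cross-method orderings it is used for do not depend
on the specific trend test, and the substitution keeps the dependency
surface small. Note that with three tests per gene, a flat gene has about
$3\alpha$ probability of showing one spurious significant step, so even
perfect data yield a few percent non-NST calls.

How to cross-normalize four groups is genuinely open (the method is
defined for two conditions). The package's convention
(`normalizeTitration`): L↔M1 and M2↔K are cross-normalized pairwise by
replicate position, then the two blocks are aligned by a general cross
normalization between M1 and M2. This is this package's choice, documented
as such, and only cross-method *orderings* (e.g. NMT counts near raw-data
levels) are asserted on it.

# Problem sizes and determinism

Every stochastic function takes an explicit integer seed and restores the
RNG state afterwards; identical inputs give bit-identical outputs, and the
general variant equals the pairwise variant exactly at $n_1 = n_2 = 1$.
The test suite exercises the full-scale study conditions (12,752 genes,
34 per group, DE ratios 20–50%, five seeds) for the headline false
positive rate and variant-consistency checks, and smaller matrices
(hundreds of genes) elsewhere, where the properties under test are
scale-free. The acceptance script (`scripts/acceptance.R`) re-runs the
full-scale sweep from scratch and writes machine-readable results.

# Known limitations

* Cross normalization assumes technical biases are independent of
  condition; it cannot correct a batch confounded with group, and samples
  should come from one experimental batch.
* The general variant assumes the control profiles (and the disease
  profiles) are exchangeable; strong subgroup structure within a condition
  would violate this.
* With an injected global shift, a down-regulated DEG's *net* expression
  change is assigned FC plus shift; interpreting recall against the
  assigned-FC truth then undercounts by design, and the package's
  benchmarks use shift-free truth for metric sweeps.
* The fold-change criterion is scale-dependent: inputs must be log2.
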