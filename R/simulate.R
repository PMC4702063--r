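# Deterministic truth-set sizes: round half away from zero.
roundHalfUp <- function(x) floor(x + 0.5)

#' Synthesize a base (normal-tissue) expression matrix
#'
#' Generates a genes-by-samples log2-intensity matrix emulating a cohort of
#' normal-tissue microarrays: per-gene means are drawn from a right-skewed
#' distribution on the typical log2 range (offset + Gamma(shape, scale),
#' clipped to \code{meanMax}), per-gene standard deviations from
#' Uniform(\code{sdMin}, \code{sdMax}), and sample values are Gaussian
#' around the gene mean.  Fully reproducible from \code{seed}.
#'
#' The generated means/sds are attached as attributes \code{geneMean} and
#' \code{geneSd} and reused by \code{\link{simulatePairedDataset}}.
#'
#' @param m number of genes (>= 2).
#' @param n number of samples (>= 2).
#' @param seed integer seed.
#' @param meanOffset,meanShape,meanScale,meanMax parameters of the gene-mean
#'   distribution (default 4 + Gamma(2, 1.5), clipped at 14 log2 units).
#' @param sdMin,sdMax range of the per-gene standard deviation (log2 units).
#' @return a numeric matrix with rownames \code{g1..gm} and colnames
#'   \code{ctrl1..ctrln}.
#' @export
synthBaseMatrix <- function(m, n, seed = 1L, meanOffset = 4, meanShape = 2,
                            meanScale = 1.5, meanMax = 14, sdMin = 0.2,
                            sdMax = 0.6) {
    stopifnot(m >= 2L, n >= 2L)
    withSeed(seed, {
        mu <- pmin(meanOffset + stats::rgamma(m, shape = meanShape,
                                              scale = meanScale), meanMax)
        sigma <- stats::runif(m, sdMin, sdMax)
        x <- matrix(stats::rnorm(m * n, mean = mu, sd = sigma), m, n,
                    dimnames = list(paste0("g", seq_len(m)),
                                    paste0("ctrl", seq_len(n))))
        attr(x, "geneMean") <- mu
        attr(x, "geneSd") <- sigma
        x
    })
}

# Evaluate expr with a local, restorable RNG state.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
    } else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Simulate a paired control/disease dataset with injected DEGs
#'
#' Takes a base (control) matrix and simulates an equally sized disease
#' group: a fraction \code{deRatio} of genes are selected as DEGs
#' (\code{downFraction} of all genes down-regulated, the rest of the DEGs
#' up-regulated — e.g. the default 10\% down plus 20\% up when
#' \code{deRatio = 0.3}).  Each DEG is assigned a log2 fold-change magnitude
#' drawn uniformly from \code{fcMagnitudes} with its sign.  The disease mean
#' of every gene is the control group mean, plus the assigned log2FC for
#' DEGs, plus \code{globalShift} for all genes, plus centred and
#' variance-standardized chi-squared noise
#' \code{noiseScale * (chisq_df - df) / sqrt(2 df)}.  Disease sample values
#' are Gaussian around that mean with the gene's base standard deviation.
#' Control samples are the base columns unchanged; pairing is positional.
#'
#' Down-regulated genes are drawn first, then up-regulated, from one
#' shuffled index stream, so the down count is exactly
#' \code{round(m * downFraction)}.
#'
#' @param base control matrix from \code{\link{synthBaseMatrix}} (or any
#'   matrix; per-gene sds are then estimated from its rows).
#' @param deRatio fraction of genes differentially expressed, in (0, 1).
#' @param downFraction fraction of all genes down-regulated (default 0.10);
#'   must not exceed \code{deRatio}.
#' @param fcMagnitudes candidate absolute log2 fold changes (default
#'   0.8, 1.0, 1.2).
#' @param globalShift log2 units added to every disease gene (condition-wide
#'   shift; default 0).
#' @param noiseScale scale of the chi-squared mean noise in log2 units
#'   (default 0.05).
#' @param noiseDf chi-squared degrees of freedom (default 4).
#' @param seed integer seed.
#' @return a list with \code{exprs} (genes x 2n matrix, controls first),
#'   \code{design} (paired \code{\linkS4class{StudyDesign}}) and
#'   \code{truth} (\code{DataFrame} of injected DEGs with columns
#'   \code{direction} and \code{log2FC}, rownames the gene ids).
#' @export
simulatePairedDataset <- function(base, deRatio, downFraction = 0.10,
                                  fcMagnitudes = c(0.8, 1.0, 1.2),
                                  globalShift = 0, noiseScale = 0.05,
                                  noiseDf = 4, seed = 1L) {
    stopifnot(is.matrix(base), ncol(base) >= 2L)
    if (downFraction > deRatio)
        stop("downFraction must not exceed deRatio")
    m <- nrow(base)
    n <- ncol(base)
    nDE <- roundHalfUp(m * deRatio)
    if (nDE < 1L) stop("deRatio * m must be at least 1")
    nDown <- roundHalfUp(m * downFraction)
    sigma <- attr(base, "geneSd")
    if (is.null(sigma)) sigma <- apply(base, 1L, stats::sd)
    ctrlMean <- rowMeans(base)
    withSeed(seed, {
        idx <- sample.int(m)
        downIdx <- idx[seq_len(nDown)]
        upIdx <- if (nDE > nDown) idx[(nDown + 1L):nDE] else integer(0)
        assigned <- numeric(m)
        assigned[downIdx] <- -sample(fcMagnitudes, nDown, replace = TRUE)
        assigned[upIdx] <- sample(fcMagnitudes, nDE - nDown, replace = TRUE)
        noise <- noiseScale * (stats::rchisq(m, df = noiseDf) - noiseDf) /
            sqrt(2 * noiseDf)
        disMean <- ctrlMean + assigned + globalShift + noise
        dis <- matrix(stats::rnorm(m * n, mean = disMean, sd = sigma), m, n,
                      dimnames = list(rownames(base),
                                      paste0("dis", seq_len(n))))
        exprs <- cbind(base, dis)
        attr(exprs, "geneMean") <- NULL
        attr(exprs, "geneSd") <- NULL
        design <- StudyDesign(
            stats::setNames(rep(c("control", "disease"), each = n),
                            colnames(exprs)),
            pairs = data.frame(control = colnames(base),
                               disease = colnames(dis)))
        deIdx <- sort(c(downIdx, upIdx))
        truth <- S4Vectors::DataFrame(
            direction = factor(ifelse(assigned[deIdx] > 0, "up", "down"),
                               levels = c("up", "down")),
            log2FC = assigned[deIdx],
            row.names = rownames(base)[deIdx])
        list(exprs = exprs, design = design, truth = truth)
    })
}

#' Synthetic spike-in chip design
#'
#' Builds a synthetic stand-in for a spike-in chip layout designed for group
#' comparison: \code{nProbes} probe sets of which \code{nAssigned} carry a
#' known concentration fold greater than 1 (the true DEGs), \code{nUnchanged}
#' are spiked at identical concentrations in both conditions (fold exactly
#' 1), and the remainder are empty (not spiked).  The defaults mirror a
#' 14,010-probe chip with 1,331 fold-changed and 2,535 unchanged probe sets.
#' Fold values are drawn from \code{folds} (all >= 1.2), deterministically
#' from \code{seed}.
#'
#' @param seed integer seed.
#' @param nProbes,nAssigned,nUnchanged layout counts.
#' @param folds discrete set of candidate concentration folds (> 1).
#' @return a \code{DataFrame} with rownames the probe ids and columns
#'   \code{category} (\code{assigned_fc}/\code{unchanged}/\code{empty}) and
#'   \code{fold} (the concentration fold; 1 for unchanged, NA for empty).
#' @export
simulateSpikeInDesign <- function(seed = 1L, nProbes = 14010L,
                                  nAssigned = 1331L, nUnchanged = 2535L,
                                  folds = c(1.2, 1.5, 2, 3, 4)) {
    stopifnot(nAssigned + nUnchanged <= nProbes, all(folds >= 1.2))
    withSeed(seed, {
        category <- factor(rep(c("assigned_fc", "unchanged", "empty"),
                               c(nAssigned, nUnchanged,
                                 nProbes - nAssigned - nUnchanged)),
                           levels = c("assigned_fc", "unchanged", "empty"))
        fold <- rep(NA_real_, nProbes)
        fold[category == "assigned_fc"] <- sample(folds, nAssigned,
                                                  replace = TRUE)
        fold[category == "unchanged"] <- 1
        S4Vectors::DataFrame(category = category, fold = fold,
                             row.names = paste0("probe", seq_len(nProbes)))
    })
}

#' Build a spike-in expression profile at a target DE ratio
#'
#' Assembles an expression profile from a spike-in design so that a chosen
#' fraction of its genes are true DEGs: all fold-changed probes are
#' included, and enough non-DE probes are drawn without replacement from the
#' unchanged + empty pools to reach a total of
#' \code{round(nDE / deRatio)} genes (e.g. 1,331 DE probes at ratio 0.3 give
#' a 4,437-gene profile).  Each condition gets \code{replicatesPerGroup}
#' replicate arrays; disease intensities are elevated by \code{log2(fold)}
#' for the DE probes, and iid Gaussian array noise is added throughout.
#'
#' @param design spike-in design from \code{\link{simulateSpikeInDesign}}.
#' @param deRatio target fraction of true DEGs in the profile, in (0, 1].
#' @param replicatesPerGroup arrays per condition (default 3).
#' @param seed integer seed.
#' @param noiseSd sd of the Gaussian array noise in log2 units.
#' @param meanOffset,meanShape,meanScale,meanMax base-intensity distribution
#'   (as in \code{\link{synthBaseMatrix}}).
#' @return a list with \code{exprs}, a paired \code{design}
#'   (\code{\linkS4class{StudyDesign}}) and \code{truth}, the character
#'   vector of true-DEG probe ids.
#' @export
buildSpikeInProfile <- function(design, deRatio, replicatesPerGroup = 3L,
                                seed = 1L, noiseSd = 0.25, meanOffset = 4,
                                meanShape = 2, meanScale = 1.5,
                                meanMax = 14) {
    stopifnot(deRatio > 0, deRatio <= 1)
    deProbes <- rownames(design)[design$category == "assigned_fc"]
    pool <- rownames(design)[design$category != "assigned_fc"]
    nDE <- length(deProbes)
    total <- roundHalfUp(nDE / deRatio)
    nNonDE <- total - nDE
    if (nNonDE > length(pool))
        stop("non-DE pool too small for deRatio = ", deRatio)
    withSeed(seed, {
        nonDE <- sample(pool, nNonDE)
        probes <- c(deProbes, nonDE)
        mTot <- length(probes)
        mu <- pmin(meanOffset + stats::rgamma(mTot, shape = meanShape,
                                              scale = meanScale), meanMax)
        shift <- numeric(mTot)
        shift[seq_len(nDE)] <- log2(design[deProbes, "fold"])
        r <- replicatesPerGroup
        ctrl <- matrix(stats::rnorm(mTot * r, mean = mu, sd = noiseSd),
                       mTot, r)
        dis <- matrix(stats::rnorm(mTot * r, mean = mu + shift,
                                   sd = noiseSd), mTot, r)
        exprs <- cbind(ctrl, dis)
        dimnames(exprs) <- list(probes,
                                c(paste0("ctrl", seq_len(r)),
                                  paste0("dis", seq_len(r))))
        sd2 <- StudyDesign(
            stats::setNames(rep(c("control", "disease"), each = r),
                            colnames(exprs)),
            pairs = data.frame(control = paste0("ctrl", seq_len(r)),
                               disease = paste0("dis", seq_len(r))))
        list(exprs = exprs, design = sd2, truth = deProbes)
    })
}
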