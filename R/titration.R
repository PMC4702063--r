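trendLevels <- c("NMT", "NST", "1up", "2up", "3up", "1down", "2down", "3down")

#' Categorize per-gene expression trends across a titration series
#'
#' For each gene, tests the three adjacent mixture differences (M1-L,
#' M2-M1, K-M2) with a two-sample Welch t-test at level \code{alpha}, taking
#' the direction from the sign of the mean difference.  The three verdicts
#' (significant up / significant down / not significant) are mapped to
#' eight trend categories:
#' \itemize{
#'   \item \code{NMT} — non-monotonous trend: at least one significant
#'     increase together with at least one significant decrease (a data
#'     artifact in a titration series);
#'   \item \code{NST} — non-significant trend: no significant change;
#'   \item \code{1up}/\code{2up}/\code{3up} and
#'     \code{1down}/\code{2down}/\code{3down} — monotonous trends with the
#'     stated number of significant changes, all in one direction.
#' }
#'
#' @param x numeric genes-by-arrays matrix on the log2 scale.
#' @param layout a \code{\linkS4class{TitrationLayout}} covering every
#'   column of \code{x}.
#' @param alpha per-step significance level (default 0.01).
#' @return a list with \code{calls}, a \code{DataFrame} of the three step
#'   verdicts (\code{sig_up}/\code{sig_down}/\code{ns}) and the
#'   \code{category} per gene, and \code{counts}, the category histogram
#'   over all eight categories.
#' @export
trendCategorize <- function(x, layout, alpha = 0.01) {
    stopifnot(is.matrix(x), is.numeric(x))
    if (!is(layout, "TitrationLayout"))
        stop("'layout' must be a TitrationLayout")
    g <- mixtureGroups(layout)
    missing <- setdiff(colnames(x), names(g))
    if (length(missing))
        stop("array(s) not in layout: ", paste(missing, collapse = ", "))
    cols <- lapply(c("L", "M1", "M2", "K"),
                   function(lv) x[, names(g)[g == lv], drop = FALSE])
    if (any(vapply(cols, ncol, 1L) < 2L))
        stop("every mixture group needs at least 2 arrays")
    verdictOf <- function(a, b) {
        res <- rowWelchT(a, b)
        diff <- rowMeans(b) - rowMeans(a)
        v <- rep("ns", nrow(x))
        v[res$p < alpha & diff > 0] <- "sig_up"
        v[res$p < alpha & diff < 0] <- "sig_down"
        factor(v, levels = c("sig_up", "sig_down", "ns"))
    }
    s1 <- verdictOf(cols[[1L]], cols[[2L]])  # M1 - L
    s2 <- verdictOf(cols[[2L]], cols[[3L]])  # M2 - M1
    s3 <- verdictOf(cols[[3L]], cols[[4L]])  # K - M2
    nUp <- (s1 == "sig_up") + (s2 == "sig_up") + (s3 == "sig_up")
    nDown <- (s1 == "sig_down") + (s2 == "sig_down") + (s3 == "sig_down")
    category <- rep("NST", nrow(x))
    category[nUp > 0 & nDown > 0] <- "NMT"
    mono <- nUp > 0 & nDown == 0
    category[mono] <- paste0(nUp[mono], "up")
    mono <- nDown > 0 & nUp == 0
    category[mono] <- paste0(nDown[mono], "down")
    category <- factor(category, levels = trendLevels)
    calls <- S4Vectors::DataFrame(step1 = s1, step2 = s2, step3 = s3,
                                  category = category,
                                  row.names = rownames(x))
    list(calls = calls, counts = table(category))
}

#' Simulate a four-mixture titration fixture with known trend truth
#'
#' Generates a titration experiment (groups L, M1, M2, K with
#' \code{replicates} arrays each) whose genes follow known mean
#' trajectories: a fraction of monotone-up genes (equal increments of
#' \code{effect} log2 units per step), monotone-down genes, optional
#' non-monotone genes (up then down), and flat genes for the remainder.
#' The default down fraction is one sixth of the up fraction, emulating the
#' strong upward skew of a liver-to-kidney titration in which kidney
#' expression is globally higher.
#'
#' @param m number of genes.
#' @param replicates arrays per mixture group (default 24).
#' @param upwardFraction fraction of monotone-up genes (default 0.30).
#' @param downwardFraction fraction of monotone-down genes (default
#'   \code{upwardFraction / 6}).
#' @param nonMonoFraction fraction of non-monotone genes (default 0).
#' @param effect per-step mean change in log2 units (default 1).
#' @param sd within-group standard deviation (default 0.25).
#' @param seed integer seed.
#' @param meanOffset,meanShape,meanScale baseline intensity distribution.
#' @return a list with \code{exprs}, \code{layout}
#'   (\code{\linkS4class{TitrationLayout}}) and \code{truth}, a factor per
#'   gene in \code{up}/\code{down}/\code{nonmono}/\code{flat}.
#' @export
simulateTitration <- function(m, replicates = 24L, upwardFraction = 0.30,
                              downwardFraction = upwardFraction / 6,
                              nonMonoFraction = 0, effect = 1, sd = 0.25,
                              seed = 1L, meanOffset = 4, meanShape = 2,
                              meanScale = 1.5) {
    stopifnot(replicates >= 2L,
              upwardFraction + downwardFraction + nonMonoFraction <= 1)
    nUp <- roundHalfUp(m * upwardFraction)
    nDown <- roundHalfUp(m * downwardFraction)
    nNon <- roundHalfUp(m * nonMonoFraction)
    truth <- factor(rep(c("up", "down", "nonmono", "flat"),
                        c(nUp, nDown, nNon, m - nUp - nDown - nNon)),
                    levels = c("up", "down", "nonmono", "flat"))
    steps <- list(up = c(0, 1, 2, 3) * 1, down = c(0, -1, -2, -3),
                  nonmono = c(0, 1, 0, -1), flat = c(0, 0, 0, 0))
    withSeed(seed, {
        truth <- sample(truth)  # shuffle gene order
        base <- meanOffset + stats::rgamma(m, shape = meanShape,
                                           scale = meanScale)
        arrays <- paste0("arr", seq_len(4L * replicates))
        grp <- rep(c("L", "M1", "M2", "K"), each = replicates)
        profile <- t(vapply(as.character(truth),
                            function(tt) steps[[tt]], numeric(4L))) * effect
        mu <- base + profile[, match(grp, c("L", "M1", "M2", "K"))]
        exprs <- matrix(stats::rnorm(length(mu), mean = mu, sd = sd),
                        m, 4L * replicates,
                        dimnames = list(paste0("g", seq_len(m)), arrays))
        layout <- TitrationLayout(stats::setNames(grp, arrays))
        list(exprs = exprs, layout = layout, truth = truth)
    })
}

#' Normalize a titration experiment
#'
#' For conventional methods all 4r arrays are normalized together as one
#' matrix.  For cross normalization the package's convention is to treat
#' adjacent mixture groups as conditions: L and M1 are cross-normalized
#' pairwise (by replicate position), M2 and K likewise, and the two blocks
#' are then aligned by a general cross normalization between the M1 and M2
#' groups.
#'
#' @param x numeric genes-by-arrays matrix.
#' @param layout a \code{\linkS4class{TitrationLayout}}.
#' @param method \code{"raw"}, \code{"quantile"}, \code{"baseline"},
#'   \code{"loess"} or \code{"crossnorm"}.
#' @param base base normalizer for crossnorm (default \code{"quantile"}).
#' @return the normalized matrix, arrays in input order.
#' @export
normalizeTitration <- function(x, layout, method = "crossnorm",
                               base = "quantile") {
    method <- match.arg(method, c("raw", "quantile", "baseline", "loess",
                                  "crossnorm"))
    if (method != "crossnorm")
        return(applyNormalization(x, method))
    g <- mixtureGroups(layout)
    ids <- lapply(c("L", "M1", "M2", "K"), function(lv) names(g)[g == lv])
    pairBlock <- function(a, b) {
        d <- StudyDesign(stats::setNames(rep(c("control", "disease"),
                                             c(length(a), length(b))),
                                         c(a, b)),
                         pairs = data.frame(control = a, disease = b))
        crossNorm(x[, c(a, b), drop = FALSE], d, variant = "pairwise",
                  base = base)
    }
    out <- x
    blk1 <- pairBlock(ids[[1L]], ids[[2L]])
    blk2 <- pairBlock(ids[[3L]], ids[[4L]])
    out[, colnames(blk1)] <- blk1
    out[, colnames(blk2)] <- blk2
    # align the two blocks through the interior mixtures
    a <- ids[[2L]]; b <- ids[[3L]]
    d <- StudyDesign(stats::setNames(rep(c("control", "disease"),
                                         c(length(a), length(b))),
                                     c(a, b)))
    mid <- crossNorm(out[, c(a, b), drop = FALSE], d, variant = "general",
                     base = base)
    out[, c(a, b)] <- mid[, c(a, b)]
    out
}
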