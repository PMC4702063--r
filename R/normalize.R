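#' Quantile normalization
#'
#' Forces every column of a matrix onto one reference distribution, defined
#' as the across-column mean of the within-column sorted values.  Each value
#' is replaced by the reference value at its within-column rank; tied values
#' receive the mean of the reference values over the tied rank span, so the
#' result is deterministic and within-column ordering is preserved.
#'
#' This is the column normalizer that conventional pipelines apply directly
#' to a two-condition matrix — which flattens any condition-wide expression
#' shift.  \code{\link{crossNorm}} applies it (or another base normalizer) to
#' concatenated cross-columns instead, so the shift survives.
#'
#' @param x numeric genes-by-samples matrix (log2 scale by convention).
#' @return a matrix of the same shape, dimnames preserved.
#' @examples
#' x <- cbind(s1 = c(2, 6, 4), s2 = c(8, 4, 6))
#' rownames(x) <- paste0("g", 1:3)
#' quantileNormalize(x)  # reference distribution is c(3, 5, 7)
#' @export
quantileNormalize <- function(x) {
    stopifnot(is.matrix(x), is.numeric(x), ncol(x) >= 1L)
    m <- nrow(x)
    srt <- apply(x, 2L, sort, method = "radix")
    ref <- rowMeans(srt)
    out <- x
    for (j in seq_len(ncol(x))) {
        o <- order(x[, j], method = "radix")
        xs <- x[o, j]
        if (anyDuplicated(xs)) {
            # run-length groups of equal values share the mean reference
            # value over their rank span
            g <- cumsum(c(TRUE, xs[-1L] != xs[-m]))
            out[o, j] <- (rowsum(ref, g) / tabulate(g))[g]
        } else {
            out[o, j] <- ref
        }
    }
    out
}

#' Baseline (median-scaling) normalization
#'
#' Shifts each column additively (the log2-scale analogue of scaling) so
#' that its median equals a common baseline, defined as the median of all
#' column medians.
#'
#' @param x numeric genes-by-samples matrix on the log2 scale.
#' @return a matrix of the same shape.
#' @export
baselineNormalize <- function(x) {
    stopifnot(is.matrix(x), is.numeric(x), ncol(x) >= 1L)
    med <- apply(x, 2L, stats::median)
    baseline <- stats::median(med)
    sweep(x, 2L, med - baseline)
}

#' Cyclic loess normalization
#'
#' Pairwise M-A loess scheme: for each pair of arrays a local regression of
#' M = x_a - x_b on A = (x_a + x_b)/2 is fitted and half the fitted M is
#' subtracted from one array and added to the other, sweeping all pairs for
#' the configured number of iterations.  Delegates to
#' \code{\link[limma]{normalizeCyclicLoess}} with \code{method = "pairs"}.
#'
#' @param x numeric genes-by-samples matrix, at least two columns.
#' @param span loess span as a fraction of the data (default 2/3).
#' @param iterations number of sweeps over all pairs (default 1).
#' @return a matrix of the same shape.
#' @export
loessNormalize <- function(x, span = 2/3, iterations = 1L) {
    stopifnot(is.matrix(x), is.numeric(x))
    if (ncol(x) < 2L)
        stop("loess normalization needs at least 2 columns")
    out <- limma::normalizeCyclicLoess(x, span = span,
                                       iterations = iterations,
                                       method = "pairs")
    dimnames(out) <- dimnames(x)
    out
}

# Resolve a base-normalizer name to a plain matrix -> matrix function.
# Cross-normalization variants must wrap a non-cross base.
resolveBaseNormalizer <- function(base, ...) {
    if (is.function(base)) return(base)
    base <- match.arg(base, c("quantile", "baseline", "loess"))
    switch(base,
        quantile = quantileNormalize,
        baseline = baselineNormalize,
        loess = function(x) loessNormalize(x, ...))
}

#' Apply a named normalization method to an expression matrix
#'
#' Dispatch helper used by the benchmark sweep and the command-line
#' interface: \code{"quantile"}, \code{"baseline"} and \code{"loess"} operate
#' column-wise on the whole matrix; \code{"crossnorm_pairwise"} and
#' \code{"crossnorm_general"} require a \code{\linkS4class{StudyDesign}} and
#' delegate to \code{\link{crossNorm}}; \code{"raw"} returns the input.
#'
#' @param x numeric genes-by-samples matrix.
#' @param method one of \code{"raw"}, \code{"quantile"}, \code{"baseline"},
#'   \code{"loess"}, \code{"crossnorm_pairwise"}, \code{"crossnorm_general"}.
#' @param design a \code{StudyDesign}; required for the crossnorm methods.
#' @param base base normalizer for the crossnorm methods (default
#'   \code{"quantile"}).
#' @param ... further arguments to the underlying normalizer (e.g.
#'   \code{span}).
#' @return the normalized matrix, samples in input order.
#' @export
applyNormalization <- function(x, method, design = NULL, base = "quantile",
                               ...) {
    method <- match.arg(method, c("raw", "quantile", "baseline", "loess",
                                  "crossnorm_pairwise", "crossnorm_general"))
    if (startsWith(method, "crossnorm")) {
        if (is.null(design))
            stop("method '", method, "' requires a StudyDesign")
        variant <- sub("crossnorm_", "", method)
        crossNorm(x, design, variant = variant, base = base, ...)
    } else {
        switch(method,
            raw = x,
            quantile = quantileNormalize(x),
            baseline = baselineNormalize(x),
            loess = loessNormalize(x, ...))
    }
}
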