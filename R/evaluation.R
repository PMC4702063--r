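#' Cross-tabulate a predicted DEG set against a truth set
#'
#' Standard 2x2 classification counts over a fixed gene universe: TP are
#' predicted DEGs in the truth set, FP predicted DEGs outside it, FN truth
#' genes not predicted, TN the rest of the universe.
#'
#' @param predicted character vector of predicted DEG ids, or a DEG table
#'   from \code{\link{identifyDEGs}}.
#' @param truth character vector of true DEG ids.
#' @param universe character vector of all evaluable gene ids; both sets
#'   must be contained in it.
#' @return a \code{\linkS4class{ConfusionCounts}}.
#' @export
confusionCounts <- function(predicted, truth, universe) {
    predicted <- unique(degSetFrom(predicted))
    truth <- unique(truth)
    universe <- unique(universe)
    if (length(setdiff(predicted, universe)))
        stop("predicted set is not contained in the universe")
    if (length(setdiff(truth, universe)))
        stop("truth set is not contained in the universe")
    isPred <- universe %in% predicted
    isTrue <- universe %in% truth
    new("ConfusionCounts",
        TP = sum(isPred & isTrue), FP = sum(isPred & !isTrue),
        TN = sum(!isPred & !isTrue), FN = sum(!isPred & isTrue))
}

#' Benchmarking metrics from confusion counts
#'
#' Computes precision TP/(TP+FP), recall TP/(TP+FN), false positive rate
#' FP/(FP+TN), the F1 score 2PR/(P+R), and the Matthews correlation
#' coefficient
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' MCC ranges over [-1, 1] with 1 for perfect, 0 for random and -1 for
#' totally inverted prediction; it remains informative when the DE/non-DE
#' classes are highly skewed, which is why it is preferred here over ROC
#' summaries.  Any metric whose denominator is zero is reported as 0 with a
#' warning (for MCC this is the random-prediction value).
#'
#' @param x a \code{\linkS4class{ConfusionCounts}}, or a named numeric
#'   vector with elements TP, FP, TN, FN.
#' @return named numeric vector with elements \code{precision},
#'   \code{recall}, \code{fpr}, \code{f1}, \code{mcc}.
#' @examples
#' confusionMetrics(c(TP = 50, FP = 5, TN = 935, FN = 10))
#' @export
confusionMetrics <- function(x) {
    if (is(x, "ConfusionCounts")) {
        tp <- x@TP; fp <- x@FP; tn <- x@TN; fn <- x@FN
    } else {
        stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(x)))
        tp <- x[["TP"]]; fp <- x[["FP"]]; tn <- x[["TN"]]; fn <- x[["FN"]]
    }
    safeRatio <- function(num, den, what) {
        if (den == 0) {
            warning(what, " denominator is zero; reporting 0", call. = FALSE)
            return(0)
        }
        num / den
    }
    precision <- safeRatio(tp, tp + fp, "precision")
    recall <- safeRatio(tp, tp + fn, "recall")
    fpr <- safeRatio(fp, fp + tn, "FPR")
    f1 <- if (precision + recall == 0) {
        warning("F1 denominator is zero; reporting 0", call. = FALSE)
        0
    } else 2 * precision * recall / (precision + recall)
    den2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    mcc <- if (den2 == 0) {
        warning("MCC denominator is zero; reporting 0", call. = FALSE)
        0
    } else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den2)
    c(precision = precision, recall = recall, fpr = fpr, f1 = f1, mcc = mcc)
}

#' Format a count ratio as a percentage
#'
#' The percentage formatter used by the package's reports: a numerator and
#' denominator become a percentage rounded to \code{digits} decimals (e.g.
#' 1790/2272 prints as 78.79).
#'
#' @param numerator,denominator counts.
#' @param digits decimals to keep (default 2).
#' @return the rounded percentage as a number.
#' @seealso \code{\link{percentLabel}} for the string form.
#' @export
formatPercent <- function(numerator, denominator, digits = 2) {
    if (denominator == 0) stop("denominator is zero")
    round(100 * numerator / denominator, digits)
}

#' @rdname formatPercent
#' @param x a fraction in [0, 1].
#' @return \code{percentLabel}: the percentage as a string with a trailing
#'   percent sign, e.g. \code{"99.14\%"}.
#' @export
percentLabel <- function(x, digits = 2) {
    sprintf(paste0("%.", digits, "f%%"), round(100 * x, digits))
}
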