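#' @import methods
NULL

#' StudyDesign: sample-to-group assignments with optional pairing
#'
#' A \code{StudyDesign} records which samples of an expression matrix belong
#' to the control group and which to the disease group, and optionally a
#' perfect matching between the two groups (e.g. tumour and adjacent normal
#' tissue from the same patient).  Pairing is required by
#' \code{\link{crossNorm}} with \code{variant = "pairwise"} and by the paired
#' t-test option of \code{\link{identifyDEGs}}.
#'
#' @slot group named factor with levels \code{control} and \code{disease};
#'   names are sample identifiers, each appearing exactly once.
#' @slot pairs data.frame with character columns \code{control} and
#'   \code{disease}.  Zero rows means the design is unpaired.  When present,
#'   the rows form a perfect matching: every control sample and every disease
#'   sample occurs in exactly one pair (which forces equal group sizes).
#'
#' @seealso \code{\link{StudyDesign}} (constructor),
#'   \code{\link{readStudyDesign}}
#' @name StudyDesign-class
#' @exportClass StudyDesign
setClass("StudyDesign",
    representation(group = "factor", pairs = "data.frame"))

setValidity("StudyDesign", function(object) {
    g <- object@group
    msg <- character()
    if (!identical(levels(g), c("control", "disease")))
        msg <- c(msg, "group levels must be exactly c('control', 'disease')")
    if (is.null(names(g)) || anyNA(names(g)) || any(names(g) == ""))
        msg <- c(msg, "every sample must be named")
    if (anyDuplicated(names(g)))
        msg <- c(msg, sprintf("duplicated sample ids: %s",
            paste(unique(names(g)[duplicated(names(g))]), collapse = ", ")))
    if (anyNA(g))
        msg <- c(msg, "every sample must be assigned to exactly one group")
    if (sum(g == "control") < 1L || sum(g == "disease") < 1L)
        msg <- c(msg, "both groups need at least one sample")
    p <- object@pairs
    if (!identical(colnames(p), c("control", "disease")))
        msg <- c(msg, "pairs must have columns 'control' and 'disease'")
    if (nrow(p) > 0L) {
        ctrl <- names(g)[g == "control"]
        dis <- names(g)[g == "disease"]
        if (!setequal(p$control, ctrl) || anyDuplicated(p$control) ||
            !setequal(p$disease, dis) || anyDuplicated(p$disease))
            msg <- c(msg, paste0("pairs must form a perfect matching: each ",
                "control and each disease sample in exactly one pair"))
    }
    if (length(msg)) msg else TRUE
})

#' TitrationLayout: four-mixture titration group assignments
#'
#' Assigns each array of a titration experiment to one of the four mixture
#' groups \code{L} (pure tissue A), \code{M1} (75/25 mixture), \code{M2}
#' (25/75 mixture) and \code{K} (pure tissue B), in titration order.  Adjacent
#' group differences (M1-L, M2-M1, K-M2) are the unit of the trend-shape
#' analysis in \code{\link{trendCategorize}}.
#'
#' @slot group named factor with levels \code{L}, \code{M1}, \code{M2},
#'   \code{K}; names are array identifiers.  All four groups must have the
#'   same number of arrays and at least two each (the per-step t-tests need
#'   within-group variance).
#'
#' @seealso \code{\link{TitrationLayout}} (constructor),
#'   \code{\link{trendCategorize}}
#' @name TitrationLayout-class
#' @exportClass TitrationLayout
setClass("TitrationLayout", representation(group = "factor"))

setValidity("TitrationLayout", function(object) {
    g <- object@group
    msg <- character()
    if (!identical(levels(g), c("L", "M1", "M2", "K")))
        msg <- c(msg, "group levels must be exactly c('L', 'M1', 'M2', 'K')")
    if (is.null(names(g)) || anyDuplicated(names(g)))
        msg <- c(msg, "arrays must have unique names")
    counts <- table(g)
    if (any(counts < 2L))
        msg <- c(msg, "every mixture group needs at least 2 arrays")
    if (length(unique(counts)) != 1L)
        msg <- c(msg, "mixture groups must have equal replicate counts")
    if (length(msg)) msg else TRUE
})

#' ConfusionCounts: 2x2 classification counts against a truth set
#'
#' Holds the true/false positive/negative counts of a differential-expression
#' call set evaluated against a known truth set over a fixed gene universe.
#'
#' @slot TP,FP,TN,FN single non-negative integers; their sum is the number of
#'   evaluable genes.
#'
#' @seealso \code{\link{confusionCounts}}, \code{\link{confusionMetrics}}
#' @name ConfusionCounts-class
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
    representation(TP = "integer", FP = "integer",
                   TN = "integer", FN = "integer"))

setValidity("ConfusionCounts", function(object) {
    v <- c(object@TP, object@FP, object@TN, object@FN)
    if (length(v) != 4L || anyNA(v) || any(v < 0L))
        "TP, FP, TN, FN must each be a single non-negative count"
    else TRUE
})

#' @describeIn StudyDesign-class compact display of group sizes and pairing
#' @param object a \code{StudyDesign}
#' @export
setMethod("show", "StudyDesign", function(object) {
    cat(sprintf("StudyDesign: %d control, %d disease sample(s)%s\n",
        sum(object@group == "control"), sum(object@group == "disease"),
        if (nrow(object@pairs)) sprintf(", %d pairs", nrow(object@pairs))
        else ", unpaired"))
})

#' @describeIn TitrationLayout-class compact display of replicate counts
#' @param object a \code{TitrationLayout}
#' @export
setMethod("show", "TitrationLayout", function(object) {
    counts <- table(object@group)
    cat(sprintf("TitrationLayout: %s arrays per group (L, M1, M2, K)\n",
        paste(counts, collapse = "/")))
})

#' @describeIn ConfusionCounts-class display the 2x2 table
#' @param object a \code{ConfusionCounts}
#' @export
setMethod("show", "ConfusionCounts", function(object) {
    cat("ConfusionCounts\n")
    m <- matrix(c(object@TP, object@FN, object@FP, object@TN), 2, 2,
        dimnames = list(truth = c("DE", "non-DE"),
                        predicted = c("DE", "non-DE")))
    print(m)
})
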