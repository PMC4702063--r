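#' Identify differentially expressed genes by fold change and t-test
#'
#' Calls DEGs with the dual criterion used throughout this package:
#' \code{|log2FC| >= fcThreshold} and t-test \code{p < pThreshold}, where
#' log2FC is mean(disease) - mean(control) on the log2 scale.  The default
#' thresholds are 0.8 log2 units and 0.01, and no multiple-testing
#' correction is applied by default (an optional BH adjustment is available
#' via \code{adjust}).  The t-test is Welch's unequal-variance two-sample
#' test; \code{paired = TRUE} switches to a paired t-test over the design's
#' pairs.
#'
#' Degenerate genes are handled by convention: when the standard error is
#' zero and the group means are equal, \code{t = 0} and \code{p = 1}; when
#' the standard error is zero but the means differ, \code{p = 0}.
#'
#' @param x numeric genes-by-samples matrix on the log2 scale, or a
#'   \code{SummarizedExperiment}.
#' @param design a \code{\linkS4class{StudyDesign}}; both groups need at
#'   least two samples.
#' @param fcThreshold absolute log2 fold-change threshold (inclusive).
#' @param pThreshold p-value threshold (exclusive).
#' @param paired use a paired t-test over the design's pairs.
#' @param adjust \code{"none"} (default) or \code{"BH"}; the adjusted value
#'   replaces \code{pValue} for calling when \code{"BH"} is selected.
#' @return a \code{\link[S4Vectors]{DataFrame}} with one row per gene and
#'   columns \code{log2FC}, \code{t}, \code{pValue}, \code{direction}
#'   (\code{up}/\code{down}/\code{none}) and \code{isDE}; thresholds are
#'   recorded in \code{metadata()}.
#' @examples
#' sim <- simulatePairedDataset(synthBaseMatrix(200, 6, seed = 1),
#'                              deRatio = 0.3, seed = 1)
#' deg <- identifyDEGs(sim$exprs, sim$design)
#' table(deg$direction)
#' @export
setGeneric("identifyDEGs", function(x, design, fcThreshold = 0.8,
                                    pThreshold = 0.01, paired = FALSE,
                                    adjust = c("none", "BH"))
    standardGeneric("identifyDEGs"))

#' @rdname identifyDEGs
#' @export
setMethod("identifyDEGs", "matrix",
function(x, design, fcThreshold = 0.8, pThreshold = 0.01, paired = FALSE,
         adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    checkDesignCoversMatrix(x, design)
    ctrl <- x[, controlSamples(design), drop = FALSE]
    dis <- x[, diseaseSamples(design), drop = FALSE]
    if (ncol(ctrl) < 2L || ncol(dis) < 2L)
        stop("the t-test needs at least 2 samples per group")
    if (paired) {
        if (!isPaired(design))
            stop("paired = TRUE requires a paired design")
        p <- samplePairs(design)
        d <- x[, p$disease, drop = FALSE] - x[, p$control, drop = FALSE]
        res <- rowPairedT(d)
        log2FC <- rowMeans(d)
    } else {
        res <- rowWelchT(ctrl, dis)
        log2FC <- rowMeans(dis) - rowMeans(ctrl)
    }
    pv <- res$p
    if (adjust == "BH") pv <- stats::p.adjust(pv, method = "BH")
    isDE <- abs(log2FC) >= fcThreshold & pv < pThreshold
    direction <- factor(ifelse(isDE, ifelse(log2FC > 0, "up", "down"),
                               "none"),
                        levels = c("up", "down", "none"))
    out <- S4Vectors::DataFrame(log2FC = unname(log2FC), t = unname(res$t),
                                pValue = unname(pv), direction = direction,
                                isDE = unname(isDE),
                                row.names = rownames(x))
    S4Vectors::metadata(out) <- list(fcThreshold = fcThreshold,
                                     pThreshold = pThreshold,
                                     test = if (paired) "paired" else "welch",
                                     adjust = adjust)
    out
})

#' @rdname identifyDEGs
#' @export
setMethod("identifyDEGs", "SummarizedExperiment",
function(x, design, fcThreshold = 0.8, pThreshold = 0.01, paired = FALSE,
         adjust = c("none", "BH")) {
    if (missing(design))
        design <- designFromColData(x)
    identifyDEGs(SummarizedExperiment::assay(x), design,
                 fcThreshold = fcThreshold, pThreshold = pThreshold,
                 paired = paired, adjust = adjust)
})

# Vectorized Welch two-sample t-test across rows.
rowWelchT <- function(x1, x2) {
    n1 <- ncol(x1)
    n2 <- ncol(x2)
    m1 <- rowMeans(x1)
    m2 <- rowMeans(x2)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
    p <- 2 * stats::pt(-abs(tstat), df)
    zero <- se2 == 0
    if (any(zero)) {
        eq <- zero & (m1 == m2)
        tstat[eq] <- 0
        p[eq] <- 1
        p[zero & !eq] <- 0
    }
    list(t = tstat, p = p)
}

# Vectorized one-sample t-test on row-wise paired differences.
rowPairedT <- function(d) {
    n <- ncol(d)
    m <- rowMeans(d)
    v <- rowSums((d - m)^2) / (n - 1L)
    tstat <- m / sqrt(v / n)
    p <- 2 * stats::pt(-abs(tstat), n - 1L)
    zero <- v == 0
    if (any(zero)) {
        eq <- zero & (m == 0)
        tstat[eq] <- 0
        p[eq] <- 1
        p[zero & !eq] <- 0
    }
    list(t = tstat, p = p)
}

#' Overlap coefficient between two gene sets
#'
#' Dice-form overlap, \code{2 |X intersect Y| / (|X| + |Y|)}: the agreement
#' between two DEG lists.  When both sets are empty the coefficient is 1 by
#' convention (the lists agree vacuously).
#'
#' @param x,y character vectors of gene identifiers (duplicates removed), or
#'   DEG tables from \code{\link{identifyDEGs}} (their \code{isDE} rows are
#'   used).
#' @return a fraction in [0, 1].
#' @examples
#' overlapCoefficient(c("a", "b", "c"), c("b", "c", "d"))  # 2*2/6
#' @export
overlapCoefficient <- function(x, y) {
    x <- unique(degSetFrom(x))
    y <- unique(degSetFrom(y))
    if (length(x) == 0L && length(y) == 0L) return(1)
    2 * length(intersect(x, y)) / (length(x) + length(y))
}

#' @rdname overlapCoefficient
#' @param sizeX,sizeY,sizeIntersect printed set sizes and intersection size,
#'   for recomputing the coefficient from reported counts.
#' @export
overlapCoefficientCounts <- function(sizeX, sizeY, sizeIntersect) {
    if (sizeIntersect > min(sizeX, sizeY) || min(sizeX, sizeY) < 0)
        stop("inconsistent set sizes")
    if (sizeX + sizeY == 0) return(1)
    2 * sizeIntersect / (sizeX + sizeY)
}

degSetFrom <- function(x) {
    if (is.character(x)) return(x)
    if (is(x, "DataFrame") || is.data.frame(x)) {
        if (!all(c("isDE") %in% colnames(x)))
            stop("DEG table input must have an 'isDE' column")
        return(rownames(x)[x$isDE])
    }
    stop("expected a character vector of gene ids or a DEG table")
}

#' Direction overlap coefficients between two DEG tables
#'
#' DOC1 is the fraction of the DEGs called in table \code{a} whose
#' regulation direction (sign of log2FC) agrees with the direction the same
#' gene shows in table \code{b}'s source data; DOC2 is the symmetric
#' quantity for table \code{b}'s DEGs against \code{a}.  A gene absent from
#' the other table cannot match.  An empty DEG set gives a coefficient of 1
#' by the vacuous-agreement convention.
#'
#' @param a,b DEG tables from \code{\link{identifyDEGs}} computed on the
#'   same genes under two processing routes.
#' @return named numeric vector \code{c(doc1 = ..., doc2 = ...)}.
#' @export
directionOverlap <- function(a, b) {
    c(doc1 = directionAgreement(a, b), doc2 = directionAgreement(b, a))
}

directionAgreement <- function(from, against) {
    genes <- rownames(from)[from$isDE]
    if (length(genes) == 0L) return(1)
    present <- genes %in% rownames(against)
    sFrom <- sign(from[genes[present], "log2FC"])
    sAgainst <- sign(against[genes[present], "log2FC"])
    if (anyNA(sFrom) || anyNA(sAgainst))
        stop("missing direction for shared gene(s)")
    # genes absent from the other table cannot match
    sum(sFrom == sAgainst & sFrom != 0) / length(genes)
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of observing at least \code{hitsInSet} successes when drawing
#' \code{setSize} genes without replacement from a background of
#' \code{backgroundSize} genes containing \code{hitsInBackground} successes.
#' Used e.g. to ask whether a DEG list is enriched for known cancer genes.
#'
#' @param hitsInSet observed successes in the drawn set.
#' @param setSize size of the drawn set.
#' @param hitsInBackground successes in the background.
#' @param backgroundSize background size.
#' @return the upper-tail p-value \code{P(K >= hitsInSet)}.
#' @examples
#' hypergeometricEnrichment(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeometricEnrichment <- function(hitsInSet, setSize, hitsInBackground,
                                     backgroundSize) {
    if (hitsInSet < 0 || hitsInSet > setSize || setSize > backgroundSize ||
        hitsInSet > hitsInBackground || hitsInBackground > backgroundSize)
        stop("inconsistent counts for the hypergeometric test")
    stats::phyper(hitsInSet - 1, m = hitsInBackground,
                  n = backgroundSize - hitsInBackground, k = setSize,
                  lower.tail = FALSE)
}

#' Compare two DEG tables
#'
#' Cross-tabulates two DEG tables the way normalization methods are compared
#' in practice: per-direction DEG counts, common and exclusive genes, the
#' overlap coefficient and both direction overlap coefficients.
#'
#' @param a,b DEG tables from \code{\link{identifyDEGs}}.
#' @return a list with elements \code{nA}, \code{nB}, \code{nCommon},
#'   \code{exclusiveA}, \code{exclusiveB}, \code{upA}, \code{downA},
#'   \code{upB}, \code{downB}, \code{oc}, \code{doc1}, \code{doc2}.
#' @export
compareDegSets <- function(a, b) {
    sa <- rownames(a)[a$isDE]
    sb <- rownames(b)[b$isDE]
    doc <- directionOverlap(a, b)
    list(nA = length(sa), nB = length(sb),
         nCommon = length(intersect(sa, sb)),
         exclusiveA = length(setdiff(sa, sb)),
         exclusiveB = length(setdiff(sb, sa)),
         upA = sum(a$direction == "up"), downA = sum(a$direction == "down"),
         upB = sum(b$direction == "up"), downB = sum(b$direction == "down"),
         oc = overlapCoefficient(sa, sb),
         doc1 = unname(doc["doc1"]), doc2 = unname(doc["doc2"]))
}
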