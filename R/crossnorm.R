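#' Cross normalization for two-condition expression matrices
#'
#' Cross normalization preserves condition-wide (global) expression shifts
#' that column-wise normalizers flatten.  Instead of normalizing each sample
#' column against all others, it concatenates a control profile C and a
#' disease profile D into a single cross-column of length 2m, normalizes the
#' cross-columns jointly with a base normalizer (quantile by default), and
#' splits each normalized cross-column back into its two halves.  Because
#' the base normalizer acts monotonically within each cross-column, the sign
#' of every within-pair difference D[g] - C[g] is preserved.
#'
#' Two variants are provided:
#' \describe{
#'   \item{\code{pairwise}}{requires a paired design (n1 = n2): one
#'     cross-column \code{[C_i; D_i]} per matched pair.}
#'   \item{\code{general}}{for unpaired designs: all n1 x n2 cross-columns
#'     \code{[C_i; D_j]} are formed and normalized; each control sample is
#'     then averaged over the n2 normalized copies containing it, and each
#'     disease sample over its n1 copies.}
#' }
#'
#' @param x a numeric genes-by-samples matrix (log2 scale by convention) or
#'   a \code{SummarizedExperiment} whose first assay is such a matrix.
#' @param design a \code{\linkS4class{StudyDesign}} covering every column of
#'   \code{x}.  For a \code{SummarizedExperiment} the design may be omitted
#'   and is then built from the colData columns \code{group} and (optional)
#'   \code{pair_id}.
#' @param variant \code{"pairwise"} (needs pairs) or \code{"general"}.
#' @param base base normalizer applied to the cross-columns: a name
#'   (\code{"quantile"}, \code{"baseline"}, \code{"loess"}) or a
#'   matrix-to-matrix function.
#' @param ... passed to the base normalizer.
#' @return an object of the same class as \code{x} with normalized values;
#'   sample order equals input order.
#' @references Cross-normalization wraps, rather than replaces, the base
#'   method: with a single pair the pairwise variant is exactly the base
#'   normalizer applied to one 2m-vector.
#' @examples
#' x <- matrix(rnorm(40, 8), 10, 4,
#'             dimnames = list(paste0("g", 1:10), c("N1", "N2", "T1", "T2")))
#' x[, c("T1", "T2")] <- x[, c("T1", "T2")] + 1  # global shift
#' d <- StudyDesign(c(N1 = "control", N2 = "control",
#'                    T1 = "disease", T2 = "disease"),
#'                  pairs = data.frame(control = c("N1", "N2"),
#'                                     disease = c("T1", "T2")))
#' xn <- crossNorm(x, d)
#' # the global shift survives:
#' mean(xn[, c("T1", "T2")]) - mean(xn[, c("N1", "N2")])
#' @export
setGeneric("crossNorm", function(x, design, variant = c("pairwise", "general"),
                                 base = "quantile", ...)
    standardGeneric("crossNorm"))

#' @rdname crossNorm
#' @export
setMethod("crossNorm", "matrix",
function(x, design, variant = c("pairwise", "general"), base = "quantile",
         ...) {
    variant <- match.arg(variant)
    checkDesignCoversMatrix(x, design)
    normalizer <- resolveBaseNormalizer(base, ...)
    if (variant == "pairwise")
        crossNormPairwise(x, design, normalizer)
    else
        crossNormGeneral(x, design, normalizer)
})

#' @rdname crossNorm
#' @export
setMethod("crossNorm", "SummarizedExperiment",
function(x, design, variant = c("pairwise", "general"), base = "quantile",
         ...) {
    if (missing(design))
        design <- designFromColData(x)
    mat <- SummarizedExperiment::assay(x)
    out <- crossNorm(mat, design, variant = variant, base = base, ...)
    SummarizedExperiment::assay(x) <- out
    x
})

checkDesignCoversMatrix <- function(x, design) {
    if (!is(design, "StudyDesign"))
        stop("'design' must be a StudyDesign")
    missing <- setdiff(colnames(x), names(design@group))
    if (length(missing))
        stop("sample(s) not in design: ", paste(missing, collapse = ", "))
    extra <- setdiff(names(design@group), colnames(x))
    if (length(extra))
        stop("design sample(s) not in matrix: ", paste(extra, collapse = ", "))
    invisible(TRUE)
}

designFromColData <- function(se) {
    cd <- SummarizedExperiment::colData(se)
    if (!"group" %in% colnames(cd))
        stop("colData needs a 'group' column to derive a StudyDesign")
    g <- stats::setNames(as.character(cd$group), colnames(se))
    pairs <- NULL
    if ("pair_id" %in% colnames(cd)) {
        pid <- as.character(cd$pair_id)
        sp <- split(seq_along(pid), pid)
        pairs <- do.call(rbind, lapply(sp, function(i)
            data.frame(control = colnames(se)[i][g[i] == "control"],
                       disease = colnames(se)[i][g[i] == "disease"])))
    }
    StudyDesign(g, pairs)
}

crossNormPairwise <- function(x, design, normalizer) {
    if (!isPaired(design))
        stop("pairwise cross normalization requires a paired design; ",
             "use variant = 'general' for unpaired data")
    pairs <- samplePairs(design)
    m <- nrow(x)
    # one cross-column [C_i; D_i] per pair
    cross <- rbind(x[, pairs$control, drop = FALSE],
                   x[, pairs$disease, drop = FALSE])
    norm <- normalizer(cross)
    out <- x
    out[, pairs$control] <- norm[seq_len(m), , drop = FALSE]
    out[, pairs$disease] <- norm[m + seq_len(m), , drop = FALSE]
    out
}

crossNormGeneral <- function(x, design, normalizer) {
    ctrl <- controlSamples(design)
    dis <- diseaseSamples(design)
    n1 <- length(ctrl)
    n2 <- length(dis)
    m <- nrow(x)
    # all n1*n2 cross-columns [C_i; D_j], i fastest
    ci <- rep(seq_len(n1), times = n2)
    dj <- rep(seq_len(n2), each = n1)
    cross <- rbind(x[, ctrl[ci], drop = FALSE], x[, dis[dj], drop = FALSE])
    norm <- normalizer(cross)
    top <- norm[seq_len(m), , drop = FALSE]
    bot <- norm[m + seq_len(m), , drop = FALSE]
    out <- x
    for (i in seq_len(n1))
        out[, ctrl[i]] <- rowMeans(top[, ci == i, drop = FALSE])
    for (j in seq_len(n2))
        out[, dis[j]] <- rowMeans(bot[, dj == j, drop = FALSE])
    out
}
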