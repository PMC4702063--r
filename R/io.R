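#' Read a genes-by-samples expression matrix
#'
#' Reads a tab-separated expression table whose header row holds sample ids
#' and whose first column (header \code{gene_id}) holds gene or probe ids.
#' Values are expected on the log2 scale; raw intensities can be transformed
#' at load time with \code{log2Transform}, which applies
#' \code{log2(v + 1)} elementwise.
#'
#' The matrix is validated on load: duplicated gene or sample ids, missing
#' cells and non-finite values are errors (this package never imputes), and
#' at least two genes and one sample are required.
#'
#' @param path path to the expression TSV.
#' @param log2Transform logical; transform raw intensities via
#'   \code{log2(v + 1)}.
#' @return a numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @seealso \code{\link{writeExpressionMatrix}}, \code{\link{collapseProbes}}
#' @export
readExpressionMatrix <- function(path, log2Transform = FALSE) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("expression table needs a gene_id column and >= 1 sample column")
    ids <- as.character(df[[1L]])
    x <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(x)) {
        bad <- which(!vapply(df[-1L], is.numeric, TRUE))
        stop("non-numeric expression column(s): ",
             paste(colnames(df)[-1L][bad], collapse = ", "))
    }
    rownames(x) <- ids
    if (log2Transform) x <- log2(x + 1)
    validateExpressionMatrix(x)
    x
}

#' Write an expression matrix as TSV
#'
#' Inverse of \code{\link{readExpressionMatrix}}: writes a tab-separated
#' table with a \code{gene_id} first column and one column per sample, at
#' full double precision so a read/write/read cycle round-trips.
#'
#' @param x numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
    validateExpressionMatrix(x)
    df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

# Shared invariants for the genes x samples container.
validateExpressionMatrix <- function(x) {
    if (!is.matrix(x) || !is.numeric(x))
        stop("expression data must be a numeric matrix")
    if (is.null(rownames(x)) || is.null(colnames(x)))
        stop("expression matrix needs gene rownames and sample colnames")
    if (anyDuplicated(rownames(x)))
        stop("duplicated gene id(s): ",
             paste(unique(rownames(x)[duplicated(rownames(x))]),
                   collapse = ", "))
    if (anyDuplicated(colnames(x)))
        stop("duplicated sample id(s): ",
             paste(unique(colnames(x)[duplicated(colnames(x))]),
                   collapse = ", "))
    if (any(!is.finite(x))) {
        idx <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
        stop(sprintf("missing or non-finite value at gene '%s', sample '%s'",
                     rownames(x)[idx[1L]], colnames(x)[idx[2L]]))
    }
    if (nrow(x) < 2L || ncol(x) < 1L)
        stop("expression matrix needs >= 2 genes and >= 1 sample")
    invisible(TRUE)
}

#' Read a probe-to-gene mapping table
#'
#' Tab-separated table with columns \code{probe_id} and \code{gene_symbol};
#' many probes may map to one gene, but each probe to exactly one gene.
#'
#' @param path path to the mapping TSV.
#' @return a named character vector, probe id -> gene symbol.
#' @export
readProbeMap <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!all(c("probe_id", "gene_symbol") %in% colnames(df)))
        stop("probe map needs columns: probe_id, gene_symbol")
    if (anyDuplicated(df$probe_id))
        stop("probe(s) mapped more than once: ",
             paste(unique(df$probe_id[duplicated(df$probe_id)]),
                   collapse = ", "))
    stats::setNames(df$gene_symbol, df$probe_id)
}

#' Collapse probe-level rows to gene-level rows
#'
#' Replaces the probe rows of an expression matrix by one row per gene
#' symbol, taking the arithmetic mean of the mapped probes' values within
#' each sample (on whatever scale the matrix is stored on, conventionally
#' log2).  Output rows are ordered lexicographically by gene symbol so the
#' operation is deterministic.
#'
#' @param x numeric expression matrix with probe ids as rownames.
#' @param map named character vector (probe id -> gene symbol), e.g. from
#'   \code{\link{readProbeMap}}.  Every row of \code{x} must be mapped.
#' @return a gene-by-sample matrix with one row per distinct gene symbol.
#' @examples
#' x <- matrix(c(2, 4, 6), 3, 1,
#'             dimnames = list(c("p1", "p2", "p3"), "s1"))
#' collapseProbes(x, c(p1 = "A", p2 = "A", p3 = "B"))  # A = mean(2, 4) = 3
#' @export
collapseProbes <- function(x, map) {
    validateExpressionMatrix(x)
    missing <- setdiff(rownames(x), names(map))
    if (length(missing))
        stop("unmapped probe id(s): ", paste(missing, collapse = ", "))
    sym <- map[rownames(x)]
    out <- rowsum(x, group = sym) / as.vector(table(sym)[sort(unique(sym))])
    out <- out[sort(rownames(out)), , drop = FALSE]
    out
}
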