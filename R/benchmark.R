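#' Benchmark normalization methods on simulated paired data
#'
#' Runs the full simulate -> normalize -> call-DEGs -> score pipeline over a
#' grid of assigned DE ratios and normalization methods.  For every
#' (deRatio, method, seed) cell a paired dataset is simulated from a fresh
#' synthetic base matrix, normalized, DEGs are called at the package's
#' (0.8, 0.01) criteria, and precision, recall, FPR, F1 and MCC are computed
#' against the injected truth set.
#'
#' @param deRatios numeric vector of assigned DE ratios.
#' @param methods character vector of methods understood by
#'   \code{\link{applyNormalization}} (plus \code{"raw"}).
#' @param m,n genes and samples per group for the synthetic base.
#' @param seeds integer vector; one simulation per seed, metrics reported
#'   per (deRatio, method, seed) row.
#' @param fcThreshold,pThreshold DEG calling criteria.
#' @param ... further simulation parameters passed to
#'   \code{\link{simulatePairedDataset}} (e.g. \code{globalShift}).
#' @return a data.frame with columns \code{de_ratio}, \code{method},
#'   \code{seed}, \code{n_deg}, \code{precision}, \code{recall}, \code{fpr},
#'   \code{f1}, \code{mcc}.
#' @export
runBenchmarkSweep <- function(deRatios, methods, m = 2000L, n = 10L,
                              seeds = 1L, fcThreshold = 0.8,
                              pThreshold = 0.01, ...) {
    rows <- list()
    for (seed in seeds) {
        base <- synthBaseMatrix(m, n, seed = seed)
        for (deRatio in deRatios) {
            sim <- simulatePairedDataset(base, deRatio = deRatio,
                                         seed = seed + 1L, ...)
            universe <- rownames(sim$exprs)
            truth <- rownames(sim$truth)
            for (method in methods) {
                norm <- applyNormalization(sim$exprs, method,
                                           design = sim$design)
                deg <- identifyDEGs(norm, sim$design,
                                    fcThreshold = fcThreshold,
                                    pThreshold = pThreshold)
                met <- suppressWarnings(confusionMetrics(
                    confusionCounts(deg, truth, universe)))
                rows[[length(rows) + 1L]] <- data.frame(
                    de_ratio = deRatio, method = method, seed = seed,
                    n_deg = sum(deg$isDE),
                    precision = met[["precision"]],
                    recall = met[["recall"]], fpr = met[["fpr"]],
                    f1 = met[["f1"]], mcc = met[["mcc"]])
            }
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write a DEG table as TSV
#'
#' @param deg a DEG table from \code{\link{identifyDEGs}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDegTable <- function(deg, path) {
    df <- data.frame(gene_id = rownames(deg), as.data.frame(deg),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a DEG table written by \code{\link{writeDegTable}}
#'
#' @param path path to the TSV.
#' @return a \code{DataFrame} in the \code{\link{identifyDEGs}} layout.
#' @export
readDegTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    out <- S4Vectors::DataFrame(
        log2FC = df$log2FC, t = df$t, pValue = df$pValue,
        direction = factor(df$direction, levels = c("up", "down", "none")),
        isDE = as.logical(df$isDE), row.names = df$gene_id)
    out
}
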