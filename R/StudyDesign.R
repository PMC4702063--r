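#' Construct a StudyDesign
#'
#' @param group a named character vector or factor assigning each sample id
#'   to \code{"control"} or \code{"disease"}.
#' @param pairs optional pairing, either a data.frame with columns
#'   \code{control} and \code{disease} or a list of length-2 character
#'   vectors \code{c(control_id, disease_id)}.  Must form a perfect matching
#'   between the two groups.
#' @return a validated \code{\linkS4class{StudyDesign}}.
#' @examples
#' design <- StudyDesign(
#'   c(N1 = "control", N2 = "control", T1 = "disease", T2 = "disease"),
#'   pairs = data.frame(control = c("N1", "N2"), disease = c("T1", "T2")))
#' isPaired(design)
#' @export
StudyDesign <- function(group, pairs = NULL) {
    if (is.null(names(group)))
        stop("'group' must be named by sample id")
    bad <- setdiff(unique(as.character(group)), c("control", "disease"))
    if (length(bad))
        stop("unknown group label(s): ", paste(bad, collapse = ", "),
             " (expected 'control' or 'disease')")
    g <- factor(as.character(group), levels = c("control", "disease"))
    names(g) <- names(group)
    if (is.null(pairs)) {
        pairs <- data.frame(control = character(), disease = character(),
                            stringsAsFactors = FALSE)
    } else if (is.list(pairs) && !is.data.frame(pairs)) {
        pairs <- data.frame(control = vapply(pairs, `[`, "", 1L),
                            disease = vapply(pairs, `[`, "", 2L),
                            stringsAsFactors = FALSE)
    }
    pairs$control <- as.character(pairs$control)
    pairs$disease <- as.character(pairs$disease)
    new("StudyDesign", group = g, pairs = pairs[c("control", "disease")])
}

#' @rdname StudyDesign
#' @param x a \code{StudyDesign}
#' @export
controlSamples <- function(x) names(x@group)[x@group == "control"]

#' @rdname StudyDesign
#' @export
diseaseSamples <- function(x) names(x@group)[x@group == "disease"]

#' @rdname StudyDesign
#' @export
groupAssignments <- function(x) x@group

#' @rdname StudyDesign
#' @export
samplePairs <- function(x) x@pairs

#' @rdname StudyDesign
#' @export
isPaired <- function(x) nrow(x@pairs) > 0L

#' Read a study design table
#'
#' Reads a tab-separated design table with columns \code{sample_id},
#' \code{group} and optionally \code{pair_id}.  A blank or absent
#' \code{pair_id} column yields an unpaired design; otherwise every pair id
#' must be shared by exactly one control and one disease sample.
#'
#' @param path path to the design TSV.
#' @return a \code{\linkS4class{StudyDesign}}.
#' @seealso \code{\link{StudyDesign}}
#' @export
readStudyDesign <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    req <- c("sample_id", "group")
    if (!all(req %in% colnames(df)))
        stop("design table needs columns: ", paste(req, collapse = ", "))
    g <- stats::setNames(df$group, df$sample_id)
    pairs <- NULL
    if ("pair_id" %in% colnames(df)) {
        pid <- trimws(df$pair_id)
        keep <- !is.na(pid) & pid != ""
        if (any(keep)) {
            if (!all(keep))
                stop("pair_id must be given for all samples or none")
            sp <- split(seq_len(nrow(df)), pid)
            rows <- lapply(sp, function(i) {
                gi <- df$group[i]
                if (length(i) != 2L || !setequal(gi, c("control", "disease")))
                    stop("pair id '", pid[i[1L]],
                         "' must join exactly one control and one disease sample")
                data.frame(control = df$sample_id[i][gi == "control"],
                           disease = df$sample_id[i][gi == "disease"],
                           stringsAsFactors = FALSE)
            })
            pairs <- do.call(rbind, rows)
        }
    }
    StudyDesign(g, pairs)
}

#' Construct a TitrationLayout
#'
#' @param mixture a named character vector or factor assigning each array id
#'   to one of the mixture groups \code{L}, \code{M1}, \code{M2}, \code{K}.
#' @return a validated \code{\linkS4class{TitrationLayout}}.
#' @examples
#' arrays <- paste0("a", 1:8)
#' TitrationLayout(setNames(rep(c("L", "M1", "M2", "K"), each = 2), arrays))
#' @export
TitrationLayout <- function(mixture) {
    if (is.null(names(mixture)))
        stop("'mixture' must be named by array id")
    bad <- setdiff(unique(as.character(mixture)), c("L", "M1", "M2", "K"))
    if (length(bad))
        stop("unknown mixture label(s): ", paste(bad, collapse = ", "))
    g <- factor(as.character(mixture), levels = c("L", "M1", "M2", "K"))
    names(g) <- names(mixture)
    new("TitrationLayout", group = g)
}

#' @rdname TitrationLayout
#' @param x a \code{TitrationLayout}
#' @export
mixtureGroups <- function(x) x@group

#' Read a titration layout table
#'
#' Tab-separated table with columns \code{sample_id} and \code{mixture}
#' (values L, M1, M2, K).
#'
#' @param path path to the layout TSV.
#' @return a \code{\linkS4class{TitrationLayout}}.
#' @export
readTitrationLayout <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!all(c("sample_id", "mixture") %in% colnames(df)))
        stop("layout table needs columns: sample_id, mixture")
    TitrationLayout(stats::setNames(df$mixture, df$sample_id))
}
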