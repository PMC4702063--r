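# Shared fixtures, all built in code.

# Small paired two-group matrix: n controls then n diseases, disease shifted
# by `shift` at every gene, plus seeded Gaussian noise.
pairedFixture <- function(m = 20, n = 3, shift = 0, sd = 0.3, seed = 42) {
    set.seed(seed)
    mu <- runif(m, 5, 12)
    ctrl <- matrix(rnorm(m * n, mu, sd), m, n)
    dis <- matrix(rnorm(m * n, mu + shift, sd), m, n)
    x <- cbind(ctrl, dis)
    dimnames(x) <- list(paste0("g", seq_len(m)),
                        c(paste0("N", seq_len(n)), paste0("T", seq_len(n))))
    design <- StudyDesign(
        setNames(rep(c("control", "disease"), each = n), colnames(x)),
        pairs = data.frame(control = paste0("N", seq_len(n)),
                           disease = paste0("T", seq_len(n))))
    list(exprs = x, design = design)
}

unpairedDesign <- function(design) {
    StudyDesign(groupAssignments(design))
}

# Write a matrix as an expression TSV in a tempfile.
writeExprTmp <- function(x) {
    path <- withr::local_tempfile(fileext = ".tsv",
                                  .local_envir = parent.frame())
    writeExpressionMatrix(x, path)
    path
}

# Independent brute-force quantile normalization used as an oracle on
# tie-free inputs (rank-map each column onto the mean sorted profile).
oracleQuantile <- function(x) {
    ref <- rowMeans(apply(x, 2, sort))
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- ref[rank(x[, j])]
    out
}
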