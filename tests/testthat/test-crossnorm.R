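test_that("pairwise cross normalization equals the literal concatenate/normalize/split recipe", {
    fx <- pairedFixture(m = 3, n = 2, shift = 0.7, seed = 9)
    out <- crossNorm(fx$exprs, fx$design, variant = "pairwise")
    # oracle: concatenate each pair into a 6-row matrix, quantile normalize
    # with an independent implementation, split back
    p <- samplePairs(fx$design)
    cross <- rbind(fx$exprs[, p$control], fx$exprs[, p$disease])
    norm <- oracleQuantile(cross)
    expect_equal(out[, p$control], norm[1:3, ], ignore_attr = TRUE)
    expect_equal(out[, p$disease], norm[4:6, ], ignore_attr = TRUE)
})

test_that("general cross normalization equals the enumerate-and-average oracle", {
    fx <- pairedFixture(m = 4, n = 2, shift = 0.5, seed = 10)
    design <- unpairedDesign(fx$design)
    out <- crossNorm(fx$exprs, design, variant = "general")
    ctrl <- controlSamples(design)
    dis <- diseaseSamples(design)
    # brute force: all 4 cross-columns, normalize, average halves explicitly
    cols <- list()
    for (j in dis) for (i in ctrl)
        cols[[paste(i, j)]] <- c(fx$exprs[, i], fx$exprs[, j])
    norm <- oracleQuantile(do.call(cbind, cols))
    m <- 4
    for (i in ctrl) {
        copies <- norm[1:m, grep(paste0("^", i, " "), colnames(norm)),
                       drop = FALSE]
        expect_equal(unname(out[, i]), unname(rowMeans(copies)))
    }
    for (j in dis) {
        copies <- norm[(m + 1):(2 * m),
                       grep(paste0(" ", j, "$"), colnames(norm)),
                       drop = FALSE]
        expect_equal(unname(out[, j]), unname(rowMeans(copies)))
    }
})

test_that("general variant with one sample per group reduces to pairwise", {
    fx <- pairedFixture(m = 10, n = 1, shift = 0.4, seed = 12)
    pw <- crossNorm(fx$exprs, fx$design, variant = "pairwise")
    gen <- crossNorm(fx$exprs, unpairedDesign(fx$design),
                     variant = "general")
    expect_equal(pw, gen)
})

test_that("identical halves stay identical and symmetric designs stay symmetric", {
    fx <- pairedFixture(m = 15, n = 2, seed = 13)
    x <- fx$exprs
    x[, diseaseSamples(fx$design)] <- x[, controlSamples(fx$design)]
    out <- crossNorm(x, fx$design, variant = "pairwise")
    expect_equal(out[, controlSamples(fx$design)],
                 out[, diseaseSamples(fx$design)], ignore_attr = TRUE)

    # all controls identical + all diseases identical => outputs identical
    y <- fx$exprs
    y[, c("N2")] <- y[, "N1"]
    y[, c("T2")] <- y[, "T1"]
    outg <- crossNorm(y, unpairedDesign(fx$design), variant = "general")
    expect_equal(outg[, "N1"], outg[, "N2"], ignore_attr = TRUE)
    expect_equal(outg[, "T1"], outg[, "T2"], ignore_attr = TRUE)
})

test_that("cross normalization preserves within-pair difference signs", {
    fx <- pairedFixture(m = 60, n = 4, shift = 0.6, seed = 14)
    out <- crossNorm(fx$exprs, fx$design, variant = "pairwise")
    p <- samplePairs(fx$design)
    for (k in seq_len(nrow(p))) {
        before <- sign(fx$exprs[, p$disease[k]] - fx$exprs[, p$control[k]])
        after <- sign(out[, p$disease[k]] - out[, p$control[k]])
        # monotone map within one cross-column: strict signs never flip
        expect_true(all(after[before > 0] >= 0))
        expect_true(all(after[before < 0] <= 0))
    }
})

test_that("pairwise cross normalization is equivariant under pair reordering", {
    fx <- pairedFixture(m = 25, n = 3, shift = 0.5, seed = 15)
    out1 <- crossNorm(fx$exprs, fx$design, variant = "pairwise")
    p <- samplePairs(fx$design)[c(3, 1, 2), ]
    design2 <- StudyDesign(groupAssignments(fx$design), pairs = p)
    out2 <- crossNorm(fx$exprs, design2, variant = "pairwise")
    expect_equal(out1, out2)
})

test_that("cross-columns share one sorted profile after pairwise crossnorm", {
    fx <- pairedFixture(m = 30, n = 3, shift = 0.5, seed = 16)
    out <- crossNorm(fx$exprs, fx$design, variant = "pairwise")
    p <- samplePairs(fx$design)
    sorted <- sapply(seq_len(nrow(p)), function(k)
        sort(c(out[, p$control[k]], out[, p$disease[k]])))
    expect_equal(sorted[, 2], sorted[, 1])
    expect_equal(sorted[, 3], sorted[, 1])
})

test_that("group-mean gap survives crossnorm but not plain quantile", {
    fx <- pairedFixture(m = 80, n = 4, shift = 1.0, seed = 17)
    ctrl <- controlSamples(fx$design)
    dis <- diseaseSamples(fx$design)
    cn <- crossNorm(fx$exprs, fx$design, variant = "pairwise")
    qn <- quantileNormalize(fx$exprs)
    expect_gt(mean(cn[, dis]) - mean(cn[, ctrl]), 0.5)
    expect_lt(abs(mean(qn[, dis]) - mean(qn[, ctrl])), 0.05)
})

test_that("unpaired designs are rejected by the pairwise variant with guidance", {
    fx <- pairedFixture(m = 10, n = 2, seed = 18)
    expect_error(crossNorm(fx$exprs, unpairedDesign(fx$design),
                           variant = "pairwise"), "general")
})

test_that("SummarizedExperiment round-trip uses colData design", {
    fx <- pairedFixture(m = 12, n = 2, shift = 0.5, seed = 19)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = fx$exprs),
        colData = S4Vectors::DataFrame(
            group = rep(c("control", "disease"), each = 2),
            pair_id = rep(c("p1", "p2"), 2),
            row.names = colnames(fx$exprs)))
    out <- crossNorm(se)
    expect_s4_class(out, "SummarizedExperiment")
    expect_equal(SummarizedExperiment::assay(out),
                 crossNorm(fx$exprs, fx$design, variant = "pairwise"))
})
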