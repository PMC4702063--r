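test_that("DEG calling applies both criteria with a closed-form Welch t", {
    x <- rbind(
        g1 = c(5.0, 5.0, 5.1, 4.9, 6.0, 6.0, 6.1, 5.9),  # clean 1.0 shift
        g2 = c(5, 5, 5, 5, 5, 5, 5, 5),                  # constant
        g3 = c(8, 9, 8, 9, 8, 9, 8, 9))                  # no shift
    colnames(x) <- c(paste0("N", 1:4), paste0("T", 1:4))
    d <- StudyDesign(setNames(rep(c("control", "disease"), each = 4),
                              colnames(x)))
    deg <- identifyDEGs(x, d)
    expect_equal(deg["g1", "log2FC"], 1.0)
    expect_identical(as.character(deg["g1", "direction"]), "up")
    # closed-form Welch t for g1
    v1 <- var(x["g1", 1:4]); v2 <- var(x["g1", 5:8])
    expect_equal(deg["g1", "t"], 1 / sqrt(v1 / 4 + v2 / 4))
    expect_lt(deg["g1", "pValue"], 0.01)
    # zero variance, equal means convention
    expect_equal(deg["g2", "t"], 0)
    expect_equal(deg["g2", "pValue"], 1)
    expect_false(deg["g3", "isDE"])
})

test_that("row-wise Welch test agrees with stats::t.test", {
    fx <- pairedFixture(m = 30, n = 5, shift = 0.3, seed = 21)
    deg <- identifyDEGs(fx$exprs, fx$design)
    for (g in sample(rownames(fx$exprs), 5)) {
        tt <- t.test(fx$exprs[g, 6:10], fx$exprs[g, 1:5])
        expect_equal(deg[g, "t"], unname(tt$statistic), tolerance = 1e-10)
        expect_equal(deg[g, "pValue"], tt$p.value, tolerance = 1e-10)
    }
    # paired option agrees with paired t.test
    degp <- identifyDEGs(fx$exprs, fx$design, paired = TRUE)
    g <- rownames(fx$exprs)[1]
    tt <- t.test(fx$exprs[g, 6:10], fx$exprs[g, 1:5], paired = TRUE)
    expect_equal(degp[g, "pValue"], tt$p.value, tolerance = 1e-10)
})

test_that("fold-change threshold is inclusive at 0.8 and p exclusive at 0.01", {
    # a gene with log2FC just below 0.8 is never a DEG however small its p
    n <- 50
    x <- rbind(g1 = c(rep(5, n), rep(5.79, n)),
               g2 = c(rep(5, n), rep(5.85, n)))
    x <- x + matrix(rnorm(2 * 2 * n, 0, 1e-3), 2)
    colnames(x) <- c(paste0("N", 1:n), paste0("T", 1:n))
    d <- StudyDesign(setNames(rep(c("control", "disease"), each = n),
                              colnames(x)))
    deg <- identifyDEGs(x, d)
    expect_lt(deg["g1", "pValue"], 1e-9)
    expect_false(deg["g1", "isDE"])
    expect_true(deg["g2", "isDE"])
})

test_that("identical groups yield no DEGs and calling is permutation-invariant", {
    fx <- pairedFixture(m = 40, n = 4, shift = 0, seed = 22)
    x <- fx$exprs
    x[, 5:8] <- x[, 1:4]
    expect_equal(sum(identifyDEGs(x, fx$design)$isDE), 0L)

    deg1 <- identifyDEGs(fx$exprs, fx$design)
    perm <- fx$exprs[, c(3, 1, 4, 2, 7, 5, 8, 6)]
    deg2 <- identifyDEGs(perm, fx$design)
    expect_equal(deg1$log2FC, deg2$log2FC)
    expect_equal(deg1$pValue, deg2$pValue)
})

test_that("DEG count is monotone in the thresholds", {
    fx <- pairedFixture(m = 150, n = 5, shift = 0.5, seed = 23)
    counts <- sapply(c(0.4, 0.6, 0.8), function(fc)
        sum(identifyDEGs(fx$exprs, fx$design, fcThreshold = fc)$isDE))
    expect_true(all(diff(counts) <= 0))
    counts2 <- sapply(c(0.001, 0.01, 0.1), function(p)
        sum(identifyDEGs(fx$exprs, fx$design, pThreshold = p)$isDE))
    expect_true(all(diff(counts2) >= 0))
})

test_that("overlap coefficient is the Dice form with the empty convention", {
    # printed-count spot checks
    expect_equal(formatPercent(2 * 2074, 2087 + 2097), 99.14)
    expect_equal(formatPercent(2 * 3111, 3120 + 3145), 99.31)
    expect_equal(overlapCoefficient(letters[1:5], letters[1:5]), 1)
    expect_equal(overlapCoefficient(letters[1:3], letters[4:6]), 0)
    expect_equal(overlapCoefficient(character(), character()), 1)
    # symmetry
    x <- letters[1:6]; y <- letters[4:9]
    expect_equal(overlapCoefficient(x, y), overlapCoefficient(y, x))
})

test_that("direction overlap counts sign agreement against the other source", {
    mk <- function(fc, de) {
        S4Vectors::DataFrame(
            log2FC = fc, t = fc, pValue = ifelse(de, 0.001, 0.5),
            direction = factor(ifelse(de, ifelse(fc > 0, "up", "down"),
                                      "none"),
                               levels = c("up", "down", "none")),
            isDE = de, row.names = paste0("g", seq_along(fc)))
    }
    a <- mk(c(1, 1, -1), c(TRUE, TRUE, FALSE))    # DEGs: g1 up, g2 up
    b <- mk(c(1, -1, -1), c(TRUE, TRUE, TRUE))    # g2 down in b's source
    doc <- directionOverlap(a, b)
    expect_equal(unname(doc["doc1"]), 0.5)
    # identical tables agree fully; empty set is vacuously 1
    expect_equal(unname(directionOverlap(a, a)), c(1, 1))
    none <- mk(c(0.1, 0.1, 0.1), rep(FALSE, 3))
    expect_equal(unname(directionOverlap(none, b)["doc1"]), 1)
    # a DEG absent from the other table cannot match
    a2 <- a[1:2, ]
    b2 <- b[1, , drop = FALSE]
    expect_equal(unname(directionOverlap(a2, b2)["doc1"]), 0.5)
})

test_that("hypergeometric enrichment matches closed-form combinatorics", {
    expect_equal(hypergeometricEnrichment(5, 5, 5, 10), 1 / choose(10, 5))
    expect_equal(hypergeometricEnrichment(0, 5, 5, 10), 1)
    # drawing the whole background is certain
    expect_equal(hypergeometricEnrichment(5, 10, 5, 10), 1)
    expect_error(hypergeometricEnrichment(6, 5, 5, 10), "inconsistent")
    # small-case enumeration oracle: P(K >= 2), draw 3 from 8 with 4 hits
    enum <- sum(sapply(2:3, function(k)
        choose(4, k) * choose(4, 3 - k))) / choose(8, 3)
    expect_equal(hypergeometricEnrichment(2, 3, 4, 8), enum)
})

test_that("DEG table round-trips through TSV and set comparison is coherent", {
    fx <- pairedFixture(m = 50, n = 4, shift = 0.6, seed = 24)
    deg <- identifyDEGs(fx$exprs, fx$design)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeDegTable(deg, path)
    back <- readDegTable(path)
    expect_equal(back$isDE, deg$isDE)
    expect_equal(back$log2FC, deg$log2FC, tolerance = 1e-6)
    cmp <- compareDegSets(deg, deg)
    expect_equal(cmp$oc, 1)
    expect_equal(cmp$nCommon, cmp$nA)
    expect_equal(cmp$exclusiveA, 0)
})
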