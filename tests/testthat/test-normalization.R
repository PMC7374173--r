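test_that("size factors match the hand-computed pseudo-reference example", {
    sf <- computeSizeFactors(handCounts())
    expect_equal(geneFactors(sf), c(g1 = 8, g2 = 3), tolerance = 1e-12)
    expect_equal(sampleFactors(sf), c(s1 = 1.75, s2 = 7 / 6),
                 tolerance = 1e-12)

    norm <- normalizeCounts(handCounts())
    expect_equal(exprState(norm), "size_normalized")
    expect_equal(exprValues(norm),
                 matrix(c(0.5 / 1.75, 2 / (7 / 6), 3 / 1.75,
                          (1 / 3) / (7 / 6)),
                        nrow = 2, byrow = TRUE,
                        dimnames = list(c("g1", "g2"), c("s1", "s2"))),
                 tolerance = 1e-12)
})

test_that("a constant count matrix normalizes to all ones", {
    m <- matrix(7, nrow = 3, ncol = 4,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
    em <- ExpressionMatrix(m, "raw_counts")
    sf <- computeSizeFactors(em)
    expect_equal(unname(sampleFactors(sf)), rep(1, 4))
    expect_true(all(abs(exprValues(normalizeCounts(em)) - 1) < 1e-12))
})

test_that("normalization is equivariant under sample and gene permutation", {
    set.seed(3)
    m <- matrix(rpois(60, 50) + 1, nrow = 6,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
    em <- ExpressionMatrix(m, "raw_counts")
    base <- exprValues(normalizeCounts(em))
    ps <- sample(10); pg <- sample(6)
    perm <- ExpressionMatrix(m[pg, ps], "raw_counts")
    expect_equal(exprValues(normalizeCounts(perm)), base[pg, ps],
                 tolerance = 1e-12)
    # sample factors permute identically
    expect_equal(unname(sampleFactors(computeSizeFactors(perm))),
                 unname(sampleFactors(computeSizeFactors(em))[ps]),
                 tolerance = 1e-12)
})

test_that("retained genes have geometric mean exactly 1 after gene scaling", {
    set.seed(4)
    m <- matrix(rpois(80, 30) + 1, nrow = 8,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
    sf <- computeSizeFactors(ExpressionMatrix(m, "raw_counts"))
    scaled <- m[sf@retainedGenes, ] / geneFactors(sf)
    expect_equal(unname(exp(rowMeans(log(scaled)))),
                 rep(1, length(sf@retainedGenes)), tolerance = 1e-12)
})

test_that("doubling all counts preserves per-sample rank order", {
    set.seed(5)
    m <- matrix(rpois(50, 40) + 1, nrow = 5,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
    a <- exprValues(normalizeCounts(ExpressionMatrix(m, "raw_counts")))
    b <- exprValues(normalizeCounts(ExpressionMatrix(2 * m, "raw_counts")))
    for (j in 1:10) expect_equal(order(a[, j]), order(b[, j]))
})

test_that("genes with zero counts are excluded from the reference but still normalized", {
    m <- matrix(c(4, 16, 9, 1, 0, 5), nrow = 3, byrow = TRUE,
                dimnames = list(c("g1", "g2", "gz"), c("s1", "s2")))
    em <- ExpressionMatrix(m, "raw_counts")
    sf <- computeSizeFactors(em)
    expect_setequal(sf@retainedGenes, c("g1", "g2"))
    # medians over the retained genes only, so identical to the 2x2 case
    expect_equal(sampleFactors(sf), c(s1 = 1.75, s2 = 7 / 6),
                 tolerance = 1e-12)
    norm <- exprValues(normalizeCounts(em))
    # excluded gene scaled by its pseudocounted geometric mean
    gm <- exp(mean(log(c(0, 5) + 1)))
    expect_equal(unname(norm["gz", ]),
                 c(0 / gm / 1.75, 5 / gm / (7 / 6)), tolerance = 1e-12)
})

test_that("the conventional variant divides raw counts by the sample factor", {
    em <- handCounts()
    sf <- computeSizeFactors(em)
    norm <- exprValues(normalizeCounts(em, conventional = TRUE))
    expect_equal(norm, sweep(exprValues(em), 2, sampleFactors(sf), "/"),
                 tolerance = 1e-12)
})

test_that("normalization refuses wrong states and degenerate cohorts", {
    norm <- normalizeCounts(handCounts())
    expect_error(normalizeCounts(norm), "state 'raw_counts'")
    expect_error(computeSizeFactors(norm), "state 'raw_counts'")
    one <- ExpressionMatrix(matrix(1:2, ncol = 1,
                                   dimnames = list(c("g1", "g2"), "s1")),
                            "raw_counts")
    expect_error(computeSizeFactors(one), "at least 2 samples")
    zeros <- ExpressionMatrix(
        matrix(c(0, 1, 2, 0), nrow = 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2"))),
        "raw_counts")
    expect_error(computeSizeFactors(zeros), "no reference genes")
})

test_that("log2 transform is exact, monotone, and names offending cells", {
    norm <- ExpressionMatrix(
        matrix(c(1, 3, 0.5, 7), nrow = 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("s1", "s2"))),
        "size_normalized")
    lg0 <- log2Transform(norm, pseudocount = 0)
    expect_equal(exprValues(lg0)["g1", "s1"], 0)
    lg1 <- log2Transform(norm, pseudocount = 1)
    expect_equal(exprValues(lg1)["g1", "s2"], 2)
    expect_equal(exprState(lg1), "log2_normalized")
    # monotone within gene
    expect_true(all(diff(exprValues(lg1)["g2", order(exprValues(norm)["g2", ])]) > 0))
    badm <- ExpressionMatrix(
        matrix(c(1, 0, 2, 3), nrow = 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("s1", "s2"))),
        "size_normalized")
    expect_error(log2Transform(badm, pseudocount = 0),
                 "gene 'g1', sample 's2'")
})

test_that("raw-count matrices reject negative or non-finite values", {
    m <- matrix(c(-1, 2, 3, 4), nrow = 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
    expect_error(ExpressionMatrix(m, "raw_counts"), "finite and >= 0")
})
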