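test_that("the linear-model p-value equals the pooled-variance t-test", {
    set.seed(40)
    for (rep in 1:10) {
        n <- sample(10:60, 1)
        memb <- runif(n) < 0.5
        if (!any(memb) || all(memb)) next
        risk <- runif(n)
        p <- rankRiskScore(risk, memb)
        oracle <- t.test(risk[memb], risk[!memb], var.equal = TRUE)$p.value
        expect_equal(p, oracle, tolerance = 1e-10)
        expect_equal(rankRiskScore(risk, !memb), p, tolerance = 1e-10)
    }
})

test_that("identical groups give p = 1 and separated groups p < 0.001", {
    expect_equal(rankRiskScore(c(0.5, 0.7, 0.5, 0.7),
                               c(TRUE, TRUE, FALSE, FALSE)), 1,
                 tolerance = 1e-12)
    expect_lt(rankRiskScore(c(0.9, 0.8, 0.95, 0.1, 0.2, 0.15),
                            c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
              0.001)
    expect_error(rankRiskScore(runif(5), rep(TRUE, 5)), "both groups")
})

test_that("triplet ranking orders by mean rank with deterministic ties", {
    # one cohort: ordering equals the p-value ordering
    one <- list(A = c(g1 = 0.5, g2 = 0.01, g3 = 0.2))
    expect_equal(rankTriplets(one)$geneId, c("g2", "g3", "g1"))
    # rank 1 everywhere comes first
    three <- list(A = c(g1 = 1e-6, g2 = 0.5, g3 = 0.9),
                  B = c(g1 = 1e-4, g2 = 0.2, g3 = 0.8),
                  C = c(g1 = 1e-5, g2 = 0.3, g3 = 0.7))
    rt <- rankTriplets(three)
    expect_equal(rt$geneId[1], "g1")
    expect_equal(rt$meanRank[1], 1)
    # mean-rank tie {1,4,1} vs {2,2,2} broken by best single-cohort rank
    tie <- list(A = c(gX = 0.01, gY = 0.02, gZ = 0.5, gW = 0.6),
                B = c(gX = 0.9, gY = 0.1, gZ = 0.05, gW = 0.5),
                C = c(gX = 0.01, gY = 0.02, gZ = 0.5, gW = 0.6))
    rtt <- rankTriplets(tie)
    expect_equal(rtt$meanRank[rtt$geneId == "gX"], 2)
    expect_equal(rtt$meanRank[rtt$geneId == "gY"], 2)
    expect_lt(which(rtt$geneId == "gX"), which(rtt$geneId == "gY"))
    # genes missing from a cohort are excluded with a warning
    expect_warning(out <- rankTriplets(list(A = c(g1 = 0.1, g2 = 0.2),
                                            B = c(g1 = 0.3))),
                   "excluded")
    expect_equal(out$geneId, "g1")
})

test_that("the printed per-size AUC table selects the 10-gene panel", {
    auc <- rbind("5"  = c(0.95, 0.88, 0.97),
                 "7"  = c(0.96, 0.89, 0.97),
                 "10" = c(0.98, 0.91, 0.98),
                 "15" = c(0.98, 0.95, 0.98),
                 "20" = c(0.98, 0.97, 0.98))
    colnames(auc) <- c("A", "B", "C")
    sel <- selectPanelSize(auc, aucFloor = 0.90)
    expect_equal(sel$size, 10L)
    expect_false(sel$flagged)
})

test_that("panel-size selection edge rules and monotonicity hold", {
    perfect <- matrix(1, nrow = 3, ncol = 2,
                      dimnames = list(c("5", "7", "10"), NULL))
    expect_equal(selectPanelSize(perfect)$size, 5L)
    low <- matrix(c(0.6, 0.7, 0.85, 0.5, 0.8, 0.7), nrow = 3,
                  dimnames = list(c("5", "7", "10"), NULL))
    sel <- selectPanelSize(low, aucFloor = 0.9)
    expect_true(sel$flagged)
    expect_equal(sel$size, 7L)   # best minimum AUC (0.7 > 0.6, 0.5)
    # raising the floor never shrinks the selected size
    set.seed(41)
    for (rep in 1:20) {
        auc <- matrix(cummax(runif(4)), nrow = 4, ncol = 3,
                      dimnames = list(c("5", "7", "10", "15"), NULL)) *
            matrix(runif(12, 0.9, 1), nrow = 4)
        auc <- apply(auc, 2, cummax)
        rownames(auc) <- c("5", "7", "10", "15")
        floors <- sort(runif(2, 0.3, 0.99))
        k1 <- selectPanelSize(auc, aucFloor = floors[1])
        k2 <- selectPanelSize(auc, aucFloor = floors[2])
        if (!k1$flagged && !k2$flagged) expect_gte(k2$size, k1$size)
    }
    expect_error(selectPanelSize(matrix(1, 0, 2), integer(0)), "candidate")
})

test_that("selectPanel measures MRS AUC per cohort and respects the floor", {
    set.seed(42)
    n <- 80
    memb <- rep(c(FALSE, TRUE), each = n / 2)   # members hold high indices
    # per-gene model: sample i's risk is rank(v_i)/n, monotone in its
    # expression; informative genes order samples by index (so members get
    # high risk), noise genes order them randomly
    mk <- function(gene, informative) {
        v <- if (informative) as.numeric(seq_len(n)) else
            as.numeric(sample(n))
        directRiskModel(0.5, trainValues = setNames(v, paste0("s", 1:n)),
                        trainRisk = rank(v) / n, gene = gene)
    }
    genes <- paste0("g", 1:4)
    rms <- setNames(Map(mk, genes, c(TRUE, TRUE, FALSE, FALSE)), genes)
    ranked <- rankTriplets(list(A = setNames(c(1e-8, 1e-7, 0.5, 0.9),
                                             genes)))
    cohorts <- list(A = list(riskModels = rms, membership = memb))
    sel <- selectPanel(ranked, cohorts, candidateSizes = c(2L, 4L),
                       aucFloor = 0.70)
    expect_equal(sel$size, 2L)
    expect_equal(sel$genes, c("g1", "g2"))
    expect_equal(dim(sel$auc), c(2L, 1L))
    expect_gt(sel$auc["2", "A"], sel$auc["4", "A"])  # noise dilutes the panel
})

test_that("duplicate features collapse to the maximal-IQR row", {
    m <- matrix(c(1, 2, 3, 4,
                  0, 10, 20, 40,
                  5, 5, 5, 6), nrow = 3, byrow = TRUE,
                dimnames = list(c("p1", "p2", "p3"), paste0("s", 1:4)))
    em <- ExpressionMatrix(m, "log2_normalized")
    ann <- c(p1 = "GENE1", p2 = "GENE1", p3 = "GENE2")
    out <- collapseFeatures(em, ann)
    expect_setequal(geneIds(out), c("GENE1", "GENE2"))
    # p2 has the larger IQR, so GENE1 keeps p2's values
    expect_equal(unname(exprValues(out)["GENE1", ]), c(0, 10, 20, 40))
    expect_error(collapseFeatures(em, c(zz = "X")), "no features")
})
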