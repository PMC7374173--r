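# brute-force O(n^2) PPV oracle used against the implementation
bruteForcePPV <- function(r, membership) {
    vapply(seq_along(r), function(i) {
        V <- r >= r[i]
        sum(membership & V) / sum(V)
    }, numeric(1))
}

test_that("mean risk is the arithmetic panel mean and checks coverage", {
    panel <- list(
        directRiskModel(1, trainValues = c(x = 0), trainRisk = 0.2,
                        gene = "gA"),
        directRiskModel(1, trainValues = c(x = 0), trainRisk = 0.4,
                        gene = "gB"),
        directRiskModel(1, trainValues = c(x = 0), trainRisk = 0.9,
                        gene = "gC"))
    expr <- c(gA = 0, gB = 0, gC = 0)
    expect_equal(meanRisk(panel, expr), 0.5)
    expect_equal(meanRisk(rev(panel), expr), 0.5)   # order-invariant
    allSame <- lapply(panel, function(m) { m@trainRisk[] <- 0.6; m })
    expect_equal(meanRisk(allSame, expr), 0.6)
    expect_error(meanRisk(panel, c(gA = 0)), "gB, gC")
})

test_that("the PPV curve reproduces the six-sample worked example", {
    r <- c(0.4, 0.5, 0.6, 0.7, 0.8, 0.9)
    memb <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
    expect_equal(ColoType:::.rawPPV(r, memb),
                 c(3 / 6, 3 / 5, 3 / 4, 2 / 3, 1, 1), tolerance = 1e-12)
    fake <- directRiskModel(c(0.05, 0.15),
                            trainValues = setNames(r, paste0("t", 1:6)),
                            trainRisk = r)
    mrs <- fitMRS("CMS1", list(fake), membership = memb)
    expect_equal(unname(trainScore(mrs)),
                 c(0.5, 0.6, 17 / 24, 17 / 24, 1, 1), tolerance = 1e-12)
    # lookup at r = 0.62: nearest training mean risk is 0.6
    expect_equal(evaluateMRS(mrs, 0.62), 17 / 24, tolerance = 1e-12)
    # identity and clamping
    expect_equal(evaluateMRS(mrs, 0.8), 1)
    expect_equal(evaluateMRS(mrs, 5), 1)
    expect_equal(evaluateMRS(mrs, -5), 0.5)
})

test_that("raw PPV matches the O(n^2) counting oracle exactly, with ties", {
    set.seed(30)
    for (rep in 1:10) {
        n <- sample(10:50, 1)
        r <- round(runif(n), 2)              # rounding forces ties
        memb <- runif(n) < 0.4
        if (!any(memb) || all(memb)) next
        expect_identical(ColoType:::.rawPPV(r, memb),
                         bruteForcePPV(r, memb))
    }
})

test_that("PPV at the top-risk member is 1 and separation saturates the curve", {
    set.seed(31)
    r <- runif(40)
    memb <- rank(r) > 32          # members hold the top 8 risks
    ppv <- ColoType:::.rawPPV(r, memb)
    expect_equal(ppv[which.max(r)], 1)
    fake <- directRiskModel(c(0.5), trainValues = setNames(r, paste0("t", 1:40)),
                            trainRisk = r)
    mrs <- fitMRS("CMS2", list(fake), membership = memb)
    expect_equal(max(trainScore(mrs)), 1)
    expect_true(all(trainScore(mrs)[memb][r[memb] >= min(r[memb])] >= 0.99))
})

test_that("membership independent of risk gives a curve near prevalence", {
    set.seed(32)
    n <- 400
    r <- runif(n)
    memb <- runif(n) < 0.3
    fake <- directRiskModel(0.5, trainValues = setNames(r, paste0("t", 1:n)),
                            trainRisk = r)
    mrs <- fitMRS("CMS3", list(fake), membership = memb)
    mid <- trainScore(mrs)[r > 0.1 & r < 0.9]
    expect_lt(max(abs(mid - mean(memb))), 0.15)
})

test_that("the fitted curve is non-decreasing and scoring the training set is the identity", {
    fx <- smallTrainedModel()
    model <- fx$model
    expr <- normalizeToLog2(fx$cohort$expr)
    for (st in names(mrsModels(model))) {
        mrs <- mrsModels(model)[[st]]
        cur <- mrsCurve(mrs)
        expect_true(all(diff(cur$score) >= 0))
        expect_true(all(cur$score >= 0 & cur$score <= 1))
        # non-decreasing in r everywhere, not only on the grid
        grid <- seq(min(cur$meanRisk) - 0.1, max(cur$meanRisk) + 0.1,
                    length.out = 200)
        expect_true(all(diff(evaluateMRS(mrs, grid)) >= -1e-12))
        # reference scoring of the training cohort reproduces training scores
        expect_equal(scoreCohort(mrs, expr), trainScore(mrs),
                     tolerance = 1e-12)
    }
})

test_that("a one-sample matrix scores identically to the vector path", {
    fx <- smallTrainedModel()
    expr <- normalizeToLog2(fx$cohort$expr)
    one <- ExpressionMatrix(exprValues(expr)[, 3, drop = FALSE],
                            "log2_normalized")
    mrs <- mrsModels(fx$model)[["CMS1"]]
    expect_identical(unname(scoreCohort(mrs, one)),
                     unname(evaluateMRS(mrs, meanRisk(mrs@panel,
                                                      exprValues(expr)[, 3]))))
})

test_that("degenerate memberships are rejected", {
    fake <- directRiskModel(0.5, trainValues = setNames(runif(30),
                                                        paste0("t", 1:30)))
    expect_error(fitMRS("CMS1", list(fake), membership = rep(TRUE, 30)),
                 "2 members and 2 non-members")
    expect_error(fitMRS("CMS1", list(fake), membership = rep(FALSE, 30)),
                 "2 members and 2 non-members")
})
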