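# exhaustive-scan oracle for the Youden threshold
youdenOracle <- function(scores, memb) {
    cand <- sort(unique(scores))
    j <- vapply(cand, function(t)
        mean(scores[memb] >= t) + mean(scores[!memb] < t) - 1, numeric(1))
    cand[which(j == max(j))[1L]]
}

test_that("the Youden threshold maximizes sensitivity + specificity - 1", {
    expect_equal(youdenThreshold(c(0.1, 0.2, 0.8, 0.9),
                                 c(FALSE, FALSE, TRUE, TRUE)), 0.8)
    # perfect separation always reaches J = 1
    set.seed(50)
    for (rep in 1:5) {
        pos <- runif(10, 0.7, 1); neg <- runif(15, 0, 0.5)
        t <- youdenThreshold(c(pos, neg), c(rep(TRUE, 10), rep(FALSE, 15)))
        expect_true(all(pos >= t) && all(neg < t))
    }
    expect_error(youdenThreshold(runif(5), rep(TRUE, 5)), "both classes")
})

test_that("the threshold scan agrees with the exhaustive oracle on random data", {
    set.seed(51)
    for (rep in 1:20) {
        n <- sample(10:80, 1)
        scores <- round(runif(n), 2)
        memb <- runif(n) < 0.5
        if (!any(memb) || all(memb)) next
        expect_identical(youdenThreshold(scores, memb),
                         youdenOracle(scores, memb))
    }
    # fully overlapping classes: smallest maximizer is still returned
    set.seed(52)
    s <- rep(round(runif(10), 1), 2)
    m <- c(rep(TRUE, 10), rep(FALSE, 10))
    expect_identical(youdenThreshold(s, m), youdenOracle(s, m))
})

table3A <- c(CMS1 = 0.751, CMS2 = 0.792, CMS3 = 0.663, CMS4 = 0.684)

test_that("discrete assignment follows positivity and maximality", {
    calls <- assignSubtypes(rbind(
        s1 = c(0.9, 0.3, 0.2, 0.1),
        s2 = c(0.2, 0.85, 0.1, 0.80),
        s3 = c(0.1, 0.2, 0.3, 0.4)) |>
            `colnames<-`(names(table3A)), table3A)
    expect_equal(unname(callLabels(calls)), c("CMS1", "CMS2", "NONE"))
    expect_equal(unname(isMixed(calls)), c(FALSE, TRUE, FALSE))
    expect_equal(unname(positivity(calls)[2, ]),
                 c(FALSE, TRUE, FALSE, TRUE))
    # a label is never assigned below its threshold
    set.seed(53)
    sc <- matrix(runif(400), ncol = 4,
                 dimnames = list(paste0("x", 1:100), names(table3A)))
    cl <- assignSubtypes(sc, table3A)
    lab <- callLabels(cl)
    for (i in which(lab != "NONE"))
        expect_gte(sc[i, lab[i]], table3A[[lab[i]]])
    # exact ties resolve in fixed subtype order and are flagged
    tied <- assignSubtypes(
        matrix(c(0.9, 0.9, 0.1, 0.1), nrow = 1,
               dimnames = list("t", names(table3A))), table3A)
    expect_equal(unname(callLabels(tied)), "CMS1")
    expect_true(tied@tied)
})

test_that("mixed-type tables count positivity patterns and sum to one", {
    sc <- rbind(a = c(0.9, 0.9, 0.1, 0.1),
                b = c(0.9, 0.9, 0.1, 0.1),
                c = c(0.95, 0.2, 0.1, 0.1),
                d = c(0.1, 0.1, 0.1, 0.1))
    colnames(sc) <- names(table3A)
    th <- c(CMS1 = 0.5, CMS2 = 0.5, CMS3 = 0.5, CMS4 = 0.5)
    mt <- mixedTypeTable(assignSubtypes(sc, th))
    expect_equal(sum(mt$patterns$fraction), 1)
    expect_equal(mt$patterns$fraction[mt$patterns$pattern == "CMS1+/CMS2+"],
                 0.5)
    expect_equal(mt$summary$count,  c(1L, 1L, 2L))
    allNone <- mixedTypeTable(assignSubtypes(sc * 0 + 0.1, th))
    expect_equal(allNone$summary$fraction[allNone$summary$category ==
                                          "unclassified"], 1)
})

test_that("single-sample prediction is bit-identical to the batch path", {
    fx <- smallTrainedModel()
    model <- fx$model
    expr <- normalizeToLog2(fx$cohort$expr)
    calls <- classifyCohort(model, fx$cohort$expr)
    v <- exprValues(expr)
    for (j in c(1, 7, 42)) {
        one <- predictSingleSample(model, v[, j])
        expect_identical(unname(callScores(one)[1, ]),
                         unname(callScores(calls)[j, ]))
        expect_identical(unname(callLabels(one)), unname(callLabels(calls)[j]))
    }
    expect_error(predictSingleSample(model, v[1:3, 1]), "missing panel genes")
})

test_that("training samples fed back reproduce their training calls", {
    fx <- smallTrainedModel()
    model <- fx$model
    trainScores <- vapply(mrsModels(model), trainScore,
                          numeric(length(fx$cohort$truth)))
    trainCalls <- assignSubtypes(trainScores,
                                 classificationThresholds(model))
    again <- classifyCohort(model, fx$cohort$expr)
    expect_identical(callScores(again), callScores(trainCalls))
    expect_identical(callLabels(again), callLabels(trainCalls))
})

test_that("a strong single-subtype signature is recovered for a new sample", {
    fx <- smallTrainedModel()
    co <- fx$cohort
    spec <- co$spec
    spec@seed <- 4242L
    fresh <- generateCohort(spec, geneSeed = 7L)
    expr <- normalizeToLog2(fresh$expr)
    idx <- which(fresh$truth == "CMS3" & is.na(fresh$secondary))[1]
    call <- predictSingleSample(fx$model, exprValues(expr)[, idx])
    expect_equal(unname(callLabels(call)), "CMS3")
})

test_that("model transfer keeps reference thresholds and tracks the new platform", {
    fx <- smallTrainedModel()
    spec <- fx$cohort$spec
    spec@seed <- 777L
    spec@locationShift <- 2; spec@scaleFactor <- 1.1
    shifted <- generateCohort(spec, geneSeed = 7L)
    adapted <- adaptModel(fx$model, shifted$expr)
    expect_identical(classificationThresholds(adapted),
                     classificationThresholds(fx$model))
    calls <- classifyCohort(adapted, shifted$expr)
    cs <- confusionStats(callLabels(calls), shifted$truth)
    expect_gt(cs@accuracy, 0.8)
})
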