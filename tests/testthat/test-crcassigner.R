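test_that("derived scores are exact linear arithmetic on the CMS scores", {
    d <- derivedScores(c(CMS1 = 0.3, CMS2 = 0.9, CMS3 = 0.25, CMS4 = 0.8),
                       enterocyte = 0.3)
    expect_equal(d$stem_like, 0.5)
    expect_equal(d$ta, 0.9 - 0.3 - 0.8)
    expect_equal(d$inflammatory, 0.3)
    expect_equal(d$goblet_like, 0.25)
    # zero enterocyte collapses to the plain CMS arithmetic
    d0 <- derivedScores(c(CMS1 = 0.1, CMS2 = 0.9, CMS3 = 0.2, CMS4 = 0.2),
                        enterocyte = 0)
    expect_equal(d0$stem_like, 0.2)
    expect_equal(d0$ta, 0.7)
    # closed form at random inputs, and the documented ranges
    set.seed(70)
    sc <- matrix(runif(40), ncol = 4,
                 dimnames = list(NULL, paste0("CMS", 1:4)))
    ent <- runif(10)
    dd <- derivedScores(sc, ent)
    expect_equal(dd$ta, sc[, "CMS2"] - ent - sc[, "CMS4"], tolerance = 1e-15)
    expect_equal(dd$stem_like, sc[, "CMS4"] - ent, tolerance = 1e-15)
    expect_true(all(dd$ta >= -2 & dd$ta <= 1))
    expect_true(all(dd$stem_like >= -1 & dd$stem_like <= 1))
    expect_error(derivedScores(c(CMS1 = 2, CMS2 = 0, CMS3 = 0, CMS4 = 0),
                               0.5), "\\[0,1\\]")
})

test_that("the simplified five-class rule maps CMS calls as documented", {
    th <- c(CMS1 = 0.5, CMS2 = 0.5, CMS3 = 0.5, CMS4 = 0.5)
    sc <- rbind(a = c(0.9, 0.1, 0.1, 0.1),   # CMS1 -> Inflammatory
                b = c(0.1, 0.9, 0.1, 0.1),   # CMS2, high ent -> Enterocyte
                c = c(0.1, 0.9, 0.1, 0.1),   # CMS2, low ent -> TA
                d = c(0.1, 0.1, 0.9, 0.1),   # CMS3 -> Goblet-like
                e = c(0.1, 0.1, 0.1, 0.9),   # CMS4, low ent -> Stem-like
                f = c(0.1, 0.1, 0.1, 0.1))   # NONE -> NONE
    colnames(sc) <- names(th)
    calls <- assignSubtypes(sc, th)
    ent <- c(0.2, 0.9, 0.1, 0.3, 0.2, 0.9)
    d <- derivedScores(sc, ent)
    out <- callCRCAssigner(calls, d, entThreshold = 0.5)
    expect_equal(unname(out),
                 c("Inflammatory", "Enterocyte", "TA", "Goblet-like",
                   "Stem-like", "NONE"))
    expect_error(callCRCAssigner(calls, d, entThreshold = 1.5), "\\(0,1\\)")
})

# a cohort with two extra Enterocyte marker genes (CA1/CA2 analogues)
# elevated in an Enterocyte subset drawn from CMS2 and CMS4
enterocyteCohort <- function(seed) {
    spec <- cohortSpec(nSamples = 150L, nMarkerGenesPerSubtype = 3L,
                       nNoiseGenes = 2L, platform = "gaussian_log",
                       mixedFraction = 0, seed = seed)
    co <- generateCohort(spec)
    set.seed(seed + 1L)
    candidates <- which(co$truth %in% c("CMS2", "CMS4"))
    ent <- rep(FALSE, length(co$truth))
    ent[sample(candidates, floor(length(candidates) * 0.4))] <- TRUE
    v <- exprValues(co$expr)
    ca <- matrix(rnorm(2 * ncol(v), mean = 6, sd = 0.5), nrow = 2,
                 dimnames = list(c("CA1", "CA2"), colnames(v)))
    ca[, ent] <- ca[, ent] + 2
    co$expr <- ExpressionMatrix(rbind(v, ca), "log2_normalized")
    co$enterocyte <- ent
    co
}

test_that("the two-gene Enterocyte score separates the Enterocyte subset", {
    co <- enterocyteCohort(71L)
    ent <- trainEnterocyte(co$expr, co$enterocyte, nBoot = 50L, seed = 3L)
    expect_equal(sort(panelGenes(ent)), c("CA1", "CA2"))
    auc <- rocAUC(trainScore(ent), co$enterocyte)
    expect_gte(auc, 0.9)
    expect_error(trainEnterocyte(co$expr, co$enterocyte,
                                 genes = c("CA1", "CA9")), "CA9")
})

test_that("CRCassigner labels are recovered on a consistently generated cohort", {
    co <- enterocyteCohort(72L)
    model <- trainColoType(co$expr, co$truth, co$markerMap, nBoot = 50L,
                           seed = 9L)
    entModel <- trainEnterocyte(co$expr, co$enterocyte, nBoot = 50L,
                                seed = 4L)
    calls <- classifyCohort(model, co$expr)
    entScore <- scoreCohort(entModel, co$expr)
    d <- derivedScores(callScores(calls), entScore)
    out <- callCRCAssigner(calls, d, entThreshold = 0.5)
    truthCRC <- ifelse(co$truth == "CMS1", "Inflammatory",
                ifelse(co$truth == "CMS3", "Goblet-like",
                ifelse(co$truth == "CMS2" & co$enterocyte, "Enterocyte",
                ifelse(co$truth == "CMS2", "TA",
                ifelse(co$truth == "CMS4" & co$enterocyte, "Enterocyte",
                ifelse(co$truth == "CMS4", "Stem-like", "NONE"))))))
    keep <- out != "NONE" & truthCRC != "NONE"
    expect_gte(mean(out[keep] == truthCRC[keep]), 0.85)
})
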