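# shared fixtures, all built in code

# tiny 2x2 count matrix from the size-factor hand calculation
handCounts <- function() {
    ExpressionMatrix(
        matrix(c(4, 16, 9, 1), nrow = 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("s1", "s2"))),
        "raw_counts")
}

# a risk-score model with fully controlled internals (bypasses bootstrap)
directRiskModel <- function(thresholds, trainValues, trainRisk = NULL,
                            orientation = "high_is_1", gene = "g") {
    if (is.null(names(trainValues)))
        names(trainValues) <- paste0("t", seq_along(trainValues))
    m <- new("RiskScoreModel", geneId = gene, orientation = orientation,
             bootThresholds = sort(thresholds), trainValues = trainValues,
             trainRisk = setNames(rep(0, length(trainValues)),
                                  names(trainValues)))
    if (is.null(trainRisk))
        trainRisk <- evaluateRisk(m, trainValues)
    m@trainRisk <- setNames(trainRisk, names(trainValues))
    validObject(m)
    m
}

# bimodal expression values: nLow from N(muLow, sd), nHigh from N(muHigh, sd)
bimodalValues <- function(nLow = 100, nHigh = 100, muLow = 2, muHigh = 8,
                          sd = 1, seed = 42) {
    set.seed(seed)
    v <- c(rnorm(nLow, muLow, sd), rnorm(nHigh, muHigh, sd))
    setNames(v, paste0("s", seq_along(v)))[sample(nLow + nHigh)]
}

# small trained classifier reused across io/classify tests; cached per
# session because training runs the bootstrap
smallModelCache <- new.env(parent = emptyenv())
smallTrainedModel <- function() {
    if (!is.null(smallModelCache$model)) return(smallModelCache$fixture)
    spec <- cohortSpec(nSamples = 120L, nMarkerGenesPerSubtype = 3L,
                       nNoiseGenes = 2L, platform = "gaussian_log",
                       seed = 7L)
    co <- generateCohort(spec)
    model <- trainColoType(co$expr, co$truth, co$markerMap, nBoot = 50L,
                           seed = 19L, referenceId = "small synthetic")
    smallModelCache$model <- model
    smallModelCache$fixture <- list(model = model, cohort = co)
    smallModelCache$fixture
}

# run one full command-line workflow into a directory and return the
# md5 of every file it wrote
runWorkflow <- function(dir) {
    px <- function(f) file.path(dir, f)
    quiet <- function(args) colotypeCLI(c(args, "--log-level", "quiet"))
    quiet(c("simulate", "--n-samples", "60", "--markers", "3", "--noise", "2",
            "--seed", "77", "--out-prefix", px("sim")))
    quiet(c("normalize", "--counts", px("sim.matrix.tsv"),
            "--out", px("norm.tsv"), "--factors", px("factors.json"),
            "--log2"))
    spec <- jsonlite::read_json(px("sim.spec.json"), simplifyVector = TRUE)
    jsonlite::write_json(spec$markerMap, px("panel.json"))
    quiet(c("train", "--expr", px("sim.matrix.tsv"), "--truth",
            px("sim.truth.tsv"), "--panel", px("panel.json"),
            "--n-boot", "50", "--seed", "5", "--out", px("model.json")))
    quiet(c("score", "--model", px("model.json"), "--expr",
            px("sim.matrix.tsv"), "--out", px("scores.tsv")))
    quiet(c("classify", "--model", px("model.json"), "--expr",
            px("sim.matrix.tsv"), "--out", px("calls.tsv")))
    quiet(c("evaluate", "--calls", px("calls.tsv"), "--truth",
            px("sim.truth.tsv"), "--out", px("stats.json")))
    # single-sample prediction from the first column of the normalized matrix
    norm <- readExpressionMatrix(px("norm.tsv"), "log2_normalized")
    df <- data.frame(gene = geneIds(norm), value = exprValues(norm)[, 1])
    write.table(df, px("one.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    quiet(c("predict-one", "--model", px("model.json"), "--sample",
            px("one.tsv"), "--out", px("one.call.tsv")))
    files <- sort(list.files(dir, full.names = TRUE))
    md5 <- tools::md5sum(files)
    names(md5) <- basename(names(md5))
    md5
}

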