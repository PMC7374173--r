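#' Youden-index classification threshold for a continuous score
#'
#' Scans every observed score value as a candidate threshold, predicting
#' positive when score >= t, and returns the candidate maximizing the
#' Youden index J = sensitivity + specificity - 1. Exact ties on J
#' resolve to the smallest such threshold. Using >= means the training
#' sample that defines the optimum is itself called positive, so every
#' candidate J is attainable.
#'
#' @param scores per-sample continuous scores.
#' @param membership per-sample logical membership; both classes must be
#'   present.
#' @return numeric(1) the selected threshold.
#' @examples
#' youdenThreshold(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE))
#' @export
youdenThreshold <- function(scores, membership) {
    membership <- as.logical(membership)
    if (length(scores) != length(membership))
        stop("scores and membership must have equal length", call. = FALSE)
    if (!any(membership) || all(membership))
        stop("both classes must be present", call. = FALSE)
    cand <- sort(unique(scores))
    nPos <- sum(membership); nNeg <- sum(!membership)
    # at threshold t: sens = P(score >= t | member), spec = P(score < t | !member)
    sens <- vapply(cand, function(t) sum(membership & scores >= t),
                   numeric(1)) / nPos
    spec <- vapply(cand, function(t) sum(!membership & scores < t),
                   numeric(1)) / nNeg
    j <- sens + spec - 1
    cand[which.max(j)]   # which.max returns the first (smallest) maximizer
}

#' Assign discrete subtypes from continuous scores
#'
#' A sample is positive for a subtype when its score is at or above that
#' subtype's classification threshold; it is assigned the positive
#' subtype with maximal score, or \code{"NONE"} when no score clears its
#' threshold. Samples positive for two or more subtypes are flagged as
#' mixed type. Exactly tied maximal positive scores resolve by the fixed
#' order CMS1 < CMS2 < CMS3 < CMS4 and are flagged in \code{tied}.
#'
#' @param scores numeric matrix, samples x subtypes, with columns
#'   CMS1..CMS4 (a named numeric vector is treated as one sample).
#' @param thresholds named numeric in (0,1), one per subtype.
#' @return A \linkS4class{SubtypeCalls}.
#' @examples
#' th <- c(CMS1 = 0.751, CMS2 = 0.792, CMS3 = 0.663, CMS4 = 0.684)
#' sc <- rbind(s1 = c(0.9, 0.3, 0.2, 0.1), s2 = c(0.2, 0.85, 0.1, 0.80))
#' colnames(sc) <- names(th)
#' callLabels(assignSubtypes(sc, th))
#' @export
assignSubtypes <- function(scores, thresholds) {
    if (is.null(dim(scores)))
        scores <- matrix(scores, nrow = 1,
                         dimnames = list("sample", names(scores)))
    if (!all(.CMS_SUBTYPES %in% colnames(scores)))
        stop("scores must contain columns ",
             paste(.CMS_SUBTYPES, collapse = ", "), call. = FALSE)
    scores <- scores[, .CMS_SUBTYPES, drop = FALSE]
    if (!all(.CMS_SUBTYPES %in% names(thresholds)))
        stop("thresholds must cover all four subtypes", call. = FALSE)
    thresholds <- thresholds[.CMS_SUBTYPES]
    n <- nrow(scores)
    positive <- scores >= rep(thresholds, each = n)
    label <- character(n)
    tied <- logical(n)
    for (i in seq_len(n)) {
        pos <- which(positive[i, ])
        if (!length(pos)) { label[i] <- "NONE"; next }
        best <- pos[scores[i, pos] == max(scores[i, pos])]
        tied[i] <- length(best) > 1L
        label[i] <- .CMS_SUBTYPES[min(best)]
    }
    new("SubtypeCalls", scores = scores, positive = positive,
        label = label, mixed = rowSums(positive) >= 2L, tied = tied,
        thresholds = thresholds)
}

#' Train a full four-subtype classifier
#'
#' Builds, per subtype: bootstrap risk scores for the subtype's panel
#' genes (orientation chosen so the mean member risk exceeds the mean
#' non-member risk), the MRS positive-predictive-value score, and the
#' Youden-index classification threshold on the training scores. Each
#' gene's bootstrap stream is seeded deterministically from
#' \code{(seed, gene id)}, so retraining with the same inputs is
#' byte-identical.
#'
#' @param trainExpr \linkS4class{ExpressionMatrix}; raw counts are
#'   normalized to the log2 scale first, already-continuous
#'   (\code{"log2_normalized"}) input is used as is.
#' @param labels per-sample subtype labels (CMS1..CMS4 or NONE), aligned
#'   with the samples of \code{trainExpr}.
#' @param panelGenes named list mapping each subtype CMS1..CMS4 to its
#'   panel gene ids (all present in \code{trainExpr}).
#' @param nBoot bootstrap resamples per gene (default 200).
#' @param seed master seed.
#' @param referenceId free-text provenance recorded in the model.
#' @param pseudocount,conventional normalization settings applied when
#'   \code{trainExpr} holds raw counts; recorded in the model.
#' @return A \linkS4class{ColoTypeModel}.
#' @export
trainColoType <- function(trainExpr, labels, panelGenes, nBoot = 200L,
                          seed = 1L, referenceId = "training cohort",
                          pseudocount = 1, conventional = FALSE) {
    if (!identical(sort(names(panelGenes)), .CMS_SUBTYPES))
        stop("panelGenes must name exactly CMS1..CMS4", call. = FALSE)
    expr <- normalizeToLog2(trainExpr, pseudocount = pseudocount,
                            conventional = conventional)
    labels <- as.character(labels)
    if (length(labels) != ncol(expr))
        stop("one label per training sample is required", call. = FALSE)
    v <- exprValues(expr)
    missing <- setdiff(unique(unlist(panelGenes)), rownames(v))
    if (length(missing))
        stop("panel genes absent from training matrix: ",
             paste(missing, collapse = ", "), call. = FALSE)

    models <- list()
    thresholds <- numeric()
    for (st in .CMS_SUBTYPES) {
        member <- labels == st
        panel <- lapply(panelGenes[[st]], function(g) {
            rs <- buildRiskScore(g, v[g, ], orientation = "high_is_1",
                                 nBoot = nBoot,
                                 seed = deriveSeed(seed, g))
            if (mean(rs@trainRisk[member]) < mean(rs@trainRisk[!member]))
                rs <- flipOrientation(rs)
            rs
        })
        mrs <- fitMRS(st, panel, trainExpr = expr, membership = member)
        models[[st]] <- mrs
        # a perfectly separated training set can put the Youden optimum at
        # a score of exactly 0 or 1; nudge into the open interval (the >=
        # positivity rule keeps boundary samples positive)
        thr <- youdenThreshold(trainScore(mrs), member)
        thresholds[[st]] <- min(max(thr, 1e-9), 1 - 1e-9)
    }
    new("ColoTypeModel", mrsModels = models, thresholds = thresholds,
        referenceId = referenceId,
        normalization = list(pseudocount = pseudocount,
                             conventional = conventional),
        seed = as.integer(seed), version = .SCHEMA_VERSION)
}

# reverse a risk score's orientation; bootstrap thresholds are unchanged,
# the risk function becomes its mirror image
flipOrientation <- function(model) {
    model@orientation <- if (model@orientation == "high_is_1")
        "low_is_1" else "high_is_1"
    model@trainRisk <- setNames(evaluateRisk(model, model@trainValues),
                                names(model@trainValues))
    validObject(model)
    model
}

#' Score and classify a cohort with a trained model
#'
#' [scoreCohort()] followed by [assignSubtypes()] with the model's
#' thresholds. When the model was transferred to a different platform
#' (its risk scores rebuilt by [adaptModel()]), the reference cohort's
#' thresholds are kept.
#'
#' @param model a \linkS4class{ColoTypeModel}.
#' @param newExpr \linkS4class{ExpressionMatrix}; counts are normalized
#'   to log2 first.
#' @return A \linkS4class{SubtypeCalls}.
#' @export
classifyCohort <- function(model, newExpr) {
    expr <- normalizeToLog2(newExpr,
                            pseudocount = model@normalization$pseudocount,
                            conventional = model@normalization$conventional)
    assignSubtypes(scoreCohort(model, expr), model@thresholds)
}

#' Predict scores and subtype for a single new sample
#'
#' The single-sample reference-set path: (1) the sample arrives with
#' normalized expression for every panel gene; (2) each gene's risk is
#' the risk of the reference sample with the nearest expression value;
#' (3) per subtype, the panel risks are averaged; (4) the subtype score
#' is the score of the reference sample with the nearest mean risk;
#' (5) the discrete subtype follows from the reference thresholds. The
#' result is identical to running the batch path on a one-sample matrix.
#'
#' @param model a \linkS4class{ColoTypeModel} acting as reference set.
#' @param sampleExpr named numeric vector, gene id -> normalized (log2)
#'   expression, covering all panel genes.
#' @return A \linkS4class{SubtypeCalls} for the one sample.
#' @export
predictSingleSample <- function(model, sampleExpr) {
    genes <- unique(unlist(panelGenes(model)))
    missing <- setdiff(genes, names(sampleExpr))
    if (length(missing))
        stop("missing panel genes: ", paste(missing, collapse = ", "),
             call. = FALSE)
    scores <- vapply(model@mrsModels, function(mrs) {
        r <- meanRisk(mrs@panel, sampleExpr, method = "lookup")
        evaluateMRS(mrs, r)
    }, numeric(1))
    assignSubtypes(scores, model@thresholds)
}

#' Transfer a trained model to a new platform or cohort
#'
#' Rebuilds every panel gene's risk score in the new cohort by quantile
#' matching ([equivalentRiskScore()]), refits each subtype's mean-risk /
#' score lookup on the new cohort's risk values against the reference
#' score curve, and keeps the reference classification thresholds (the
#' convention when a reference cohort anchors classification on another
#' platform). The MRS curves themselves are carried over: a new sample's
#' mean risk is still mapped through the reference curve.
#'
#' @param model reference \linkS4class{ColoTypeModel}.
#' @param newExpr \linkS4class{ExpressionMatrix} of the new cohort (>= 20
#'   samples), counts normalized to log2 first.
#' @return A \linkS4class{ColoTypeModel} whose lookup tables live on the
#'   new platform's scale.
#' @export
adaptModel <- function(model, newExpr) {
    expr <- normalizeToLog2(newExpr,
                            pseudocount = model@normalization$pseudocount,
                            conventional = model@normalization$conventional)
    v <- exprValues(expr)
    out <- model
    for (st in names(model@mrsModels)) {
        mrs <- model@mrsModels[[st]]
        mrs@panel <- lapply(mrs@panel, function(rs) {
            if (!rs@geneId %in% rownames(v))
                stop("gene ", rs@geneId, " absent from new cohort",
                     call. = FALSE)
            equivalentRiskScore(rs, v[rs@geneId, ])
        })
        riskMat <- .panelRiskMatrix(mrs@panel, expr, method = "evaluate")
        r <- rowMeans(riskMat)
        mrs@trainMeanRisk <- setNames(r, colnames(v))
        mrs@trainScore <- setNames(evaluateMRS(model@mrsModels[[st]], r),
                                   colnames(v))
        # lookup grid on the new cohort, scores from the reference curve
        o <- order(r)
        keep <- !duplicated(r[o])
        mrs@curveGrid <- unname(r[o][keep])
        mrs@curveValues <- unname(cummax(mrs@trainScore[o][keep]))
        validObject(mrs)
        out@mrsModels[[st]] <- mrs
    }
    out@referenceId <- paste0(model@referenceId, " (adapted)")
    out
}

#' Frequency table of subtype-positivity patterns
#'
#' Counts each of the 16 positivity patterns over CMS1..CMS4 across a set
#' of calls, plus the single-positive / mixed / unclassified totals used
#' to summarize intratumoral heterogeneity in a cohort.
#'
#' @param calls a \linkS4class{SubtypeCalls}.
#' @return list with a \code{patterns} data.frame (pattern, count,
#'   fraction, over all 16 patterns) and a \code{summary} data.frame
#'   (unclassified / single / mixed counts and fractions).
#' @export
mixedTypeTable <- function(calls) {
    pos <- positivity(calls)
    n <- nrow(pos)
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), 4))[, 4:1]
    colnames(combos) <- .CMS_SUBTYPES
    patName <- apply(combos, 1L, function(z) {
        p <- .CMS_SUBTYPES[as.logical(z)]
        if (!length(p)) "NONE" else paste0(p, "+", collapse = "/")
    })
    key <- apply(pos, 1L, function(z) paste(as.integer(z), collapse = ""))
    comboKey <- apply(combos, 1L, function(z)
        paste(as.integer(z), collapse = ""))
    count <- as.integer(table(factor(key, levels = comboKey)))
    patterns <- data.frame(pattern = patName, count = count,
                           fraction = if (n) count / n else 0,
                           stringsAsFactors = FALSE)
    nPosEach <- rowSums(pos)
    summary <- data.frame(
        category = c("unclassified", "single", "mixed"),
        count = c(sum(nPosEach == 0L), sum(nPosEach == 1L),
                  sum(nPosEach >= 2L)),
        stringsAsFactors = FALSE)
    summary$fraction <- if (n) summary$count / n else 0
    list(patterns = patterns, summary = summary)
}

#' Subtype calls as a plain data.frame
#'
#' One row per sample: the four continuous scores, the four positivity
#' flags, the discrete label and the mixed flag — the layout written by
#' the command-line \code{classify} step.
#'
#' @param calls a \linkS4class{SubtypeCalls}.
#' @return data.frame with a \code{sample} column.
#' @export
callsToFrame <- function(calls) {
    sc <- callScores(calls)
    pos <- positivity(calls)
    colnames(pos) <- paste0(colnames(pos), ".positive")
    data.frame(sample = rownames(sc), sc, pos,
               label = calls@label, mixed = calls@mixed,
               row.names = NULL, stringsAsFactors = FALSE,
               check.names = FALSE)
}
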