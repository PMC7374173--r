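#' Mean panel risk for one sample
#'
#' The arithmetic mean of the per-gene risk values over a panel, the raw
#' consensus statistic underlying an MRS score. Training-cohort values
#' use [evaluateRisk()]; new samples use the reference lookup
#' [lookupRisk()].
#'
#' @param panel list of \linkS4class{RiskScoreModel}.
#' @param sampleExpr named numeric vector, gene id -> expression value;
#'   must contain every panel gene.
#' @param method \code{"lookup"} (nearest reference sample, default, the
#'   new-sample path) or \code{"evaluate"} (bootstrap ECDF, the training
#'   path).
#' @return numeric(1) mean risk in [0,1].
#' @export
meanRisk <- function(panel, sampleExpr, method = c("lookup", "evaluate")) {
    method <- match.arg(method)
    genes <- vapply(panel, geneId, character(1))
    missing <- setdiff(genes, names(sampleExpr))
    if (length(missing))
        stop("missing panel genes: ", paste(missing, collapse = ", "),
             call. = FALSE)
    risks <- vapply(panel, function(m) {
        x <- sampleExpr[[m@geneId]]
        if (method == "lookup") lookupRisk(m, x) else evaluateRisk(m, x)
    }, numeric(1))
    mean(risks)
}

# Raw PPV at every sample: for V = {samples with r >= r(v)},
# ppv(v) = #(members in V) / #V. Ties in r share their PPV because V is
# defined by r >= r(v). O(n log n).
.rawPPV <- function(r, membership) {
    ord <- order(r, decreasing = TRUE)
    cmem <- cumsum(membership[ord])
    cnt <- seq_along(r)
    # index of the last element of each tied group in the descending order
    rDesc <- r[ord]
    lastOfGroup <- rev(!duplicated(rev(rDesc)))
    groupPPV <- (cmem / cnt)[lastOfGroup]
    groupVal <- rDesc[lastOfGroup]
    ppvDesc <- groupPPV[match(rDesc, groupVal)]
    ppv <- numeric(length(r))
    ppv[ord] <- ppvDesc
    ppv
}

#' Fit a multigene risk score (MRS) model for one subtype
#'
#' Calibrates the mean panel risk into a continuous subtype-membership
#' score. For each training sample v, the raw positive predictive value
#' is the fraction of samples with mean risk at least r(v) that truly
#' belong to the subtype (samples tied on r share their PPV). The raw
#' PPV sequence is then made non-decreasing in r by isotonic regression
#' (pool-adjacent-violators, equal weights; samples tied on r receive the
#' average of their pooled fits) and the resulting (mean-risk, score)
#' pairs define a monotone piecewise-linear curve stored alongside the
#' per-sample training scores.
#'
#' @param subtype subtype label, e.g. \code{"CMS1"}.
#' @param panel list of \linkS4class{RiskScoreModel}, one per panel gene,
#'   all trained on the same cohort.
#' @param trainExpr \linkS4class{ExpressionMatrix} of the training cohort
#'   (log2 scale) containing every panel gene, or \code{NULL} to reuse the
#'   per-sample risks stored in the panel models.
#' @param membership logical vector, one per training sample: does the
#'   sample belong to the subtype? At least 2 members and 2 non-members.
#' @return An \linkS4class{MRSModel}.
#' @export
fitMRS <- function(subtype, panel, trainExpr = NULL, membership) {
    riskMat <- .panelRiskMatrix(panel, trainExpr, method = "evaluate")
    if (length(membership) != nrow(riskMat))
        stop("membership must have one entry per training sample",
             call. = FALSE)
    membership <- as.logical(membership)
    if (sum(membership) < 2L || sum(!membership) < 2L)
        stop("need at least 2 members and 2 non-members of the subtype",
             call. = FALSE)
    r <- rowMeans(riskMat)
    ppv <- .rawPPV(r, membership)

    o <- order(r)
    iso <- stats::isoreg(x = seq_along(o), y = ppv[o])$yf
    # average pooled fits within tied mean-risk groups so equal r implies
    # equal score; group means of a monotone sequence stay monotone
    isoAvg <- stats::ave(iso, r[o], FUN = mean)
    score <- numeric(length(r))
    score[o] <- isoAvg
    score <- pmin(pmax(score, 0), 1)

    keep <- !duplicated(r[o])
    model <- new("MRSModel", subtype = subtype, panel = panel,
                 trainMeanRisk = setNames(r, rownames(riskMat)),
                 trainScore = setNames(score, rownames(riskMat)),
                 curveGrid = unname(r[o][keep]),
                 curveValues = unname(score[o][keep]))
    validObject(model)
    model
}

# samples x genes matrix of per-gene risks from a panel; trainExpr NULL
# reuses the risks stored at panel construction
.panelRiskMatrix <- function(panel, expr = NULL, method = "lookup") {
    genes <- vapply(panel, geneId, character(1))
    if (is.null(expr)) {
        samples <- names(panel[[1]]@trainRisk)
        mat <- vapply(panel, function(m) {
            if (!identical(names(m@trainRisk), samples))
                stop("panel models trained on different samples",
                     call. = FALSE)
            unname(m@trainRisk)
        }, numeric(length(samples)))
    } else {
        v <- exprValues(expr)
        missing <- setdiff(genes, rownames(v))
        if (length(missing))
            stop("missing panel genes: ", paste(missing, collapse = ", "),
                 call. = FALSE)
        samples <- colnames(v)
        mat <- vapply(panel, function(m) {
            x <- v[m@geneId, ]
            if (method == "lookup") lookupRisk(m, x) else evaluateRisk(m, x)
        }, numeric(length(samples)))
    }
    mat <- matrix(mat, nrow = length(samples),
                  dimnames = list(samples, genes))
    mat
}

#' Evaluate an MRS model at a mean-risk value
#'
#' Returns the calibrated score of the training sample whose mean risk is
#' nearest r (equidistant ties resolve to the lower mean risk), clamped
#' to [0,1]. Nearest-sample lookup rather than interpolation is used so
#' that batch scoring and single-sample prediction agree exactly.
#'
#' @param model an \linkS4class{MRSModel}.
#' @param r numeric vector of mean-risk values.
#' @return numeric vector of scores in [0,1].
#' @export
evaluateMRS <- function(model, r) {
    idx <- nearestIndexSorted(model@curveGrid, r)
    pmin(pmax(model@curveValues[idx], 0), 1)
}

#' Score a cohort with an MRS or full ColoType model
#'
#' The reference-set scoring path: per sample, each panel gene's risk is
#' looked up from the nearest training sample ([lookupRisk()]), the panel
#' risks are averaged, and the mean is mapped through the training score
#' of the nearest training sample ([evaluateMRS()]). Applied to the
#' training cohort itself this reproduces the training scores exactly.
#'
#' @param model an \linkS4class{MRSModel} or \linkS4class{ColoTypeModel}.
#' @param newExpr \linkS4class{ExpressionMatrix} (log2 scale) containing
#'   all panel genes.
#' @return For an \code{MRSModel}, a named numeric vector of per-sample
#'   scores; for a \code{ColoTypeModel}, a samples x 4 matrix with
#'   columns CMS1..CMS4.
#' @export
setGeneric("scoreCohort", function(model, newExpr)
    standardGeneric("scoreCohort"))

#' @rdname scoreCohort
#' @export
setMethod("scoreCohort", "MRSModel", function(model, newExpr) {
    riskMat <- .panelRiskMatrix(model@panel, newExpr, method = "lookup")
    r <- rowMeans(riskMat)
    setNames(evaluateMRS(model, r), rownames(riskMat))
})

#' @rdname scoreCohort
#' @export
setMethod("scoreCohort", "ColoTypeModel", function(model, newExpr) {
    scores <- vapply(model@mrsModels, scoreCohort,
                     numeric(ncol(newExpr)), newExpr = newExpr)
    matrix(scores, ncol = length(model@mrsModels),
           dimnames = list(sampleIds(newExpr), names(model@mrsModels)))
})
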