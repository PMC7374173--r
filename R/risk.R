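#' Build a bootstrap risk-score model for one gene
#'
#' Fits the two-component mixture on the full training values, then
#' refits it on \code{nBoot} bootstrap resamples (each anchored to the
#' full-data boundary through \code{boundaryHint}) and records the
#' boundary of every refit. The risk score of an expression value x is
#' the fraction of recorded boundaries at or below x
#' (orientation \code{"high_is_1"}) or at or above x
#' (\code{"low_is_1"}): an S-shaped (or mirrored) step function rising
#' near the threshold between the low and high modes, whose slope widens
#' with the bootstrap uncertainty in that threshold. Resamples whose
#' mixture fit fails are redrawn up to 5 times; a gene whose fits fail
#' more than 20\% of the time is rejected as unstable.
#'
#' @param geneIdent gene identifier stored in the model.
#' @param values named numeric vector of training expression values (log2
#'   scale), names = sample ids.
#' @param orientation \code{"high_is_1"} (risk rises with expression) or
#'   \code{"low_is_1"} (mirror image).
#' @param nBoot number of bootstrap resamples, at least 50 (default 200).
#' @param seed integer seed for the resampling stream.
#' @return A \linkS4class{RiskScoreModel}.
#' @examples
#' set.seed(7)
#' x <- setNames(c(rnorm(60, 2), rnorm(60, 8)), paste0("s", 1:120))
#' rs <- buildRiskScore("GENE1", x, "high_is_1", nBoot = 50, seed = 42)
#' evaluateRisk(rs, c(0, 5, 10))
#' @export
buildRiskScore <- function(geneIdent, values,
                           orientation = c("high_is_1", "low_is_1"),
                           nBoot = 200L, seed = 1L) {
    orientation <- match.arg(orientation)
    if (nBoot < 50L)
        stop("nBoot must be at least 50", call. = FALSE)
    vals <- values[is.finite(values)]
    full <- fitMixture(vals)   # errors propagate (unimodal / too few values)

    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(seed)

    n <- length(vals)
    thresholds <- rep(NA_real_, nBoot)
    nFailed <- 0L
    maxFailed <- floor(0.2 * nBoot)
    # all resamples are refit in one vectorized EM; failed slots are
    # redrawn in up to 5 further rounds
    for (round in 1:6) {
        open <- which(is.na(thresholds))
        if (!length(open)) break
        if (round == 6L)
            stop(sprintf("unstable gene '%s': bootstrap fit failed after bounded redraws",
                         geneIdent), call. = FALSE)
        X <- matrix(vals[sample.int(n, n * length(open), replace = TRUE)],
                    nrow = n)
        bd <- .bootstrapBoundaries(X, full)
        thresholds[open] <- bd
        nFailed <- nFailed + sum(is.na(bd))
        if (nFailed > maxFailed)
            stop(sprintf("unstable gene '%s': more than 20%% of bootstrap mixture fits failed",
                         geneIdent), call. = FALSE)
    }
    thresholds <- sort(thresholds)

    model <- new("RiskScoreModel", geneId = geneIdent,
                 orientation = orientation,
                 bootThresholds = thresholds,
                 trainValues = vals, trainRisk = setNames(numeric(length(vals)),
                                                          names(vals)))
    model@trainRisk <- setNames(evaluateRisk(model, vals), names(vals))
    validObject(model)
    model
}

#' Evaluate a risk score at expression values
#'
#' The empirical CDF (orientation \code{"high_is_1"}) or survival
#' function (\code{"low_is_1"}) of the model's bootstrap thresholds,
#' giving a value in [0,1] that is monotone in expression.
#'
#' @param model a \linkS4class{RiskScoreModel}.
#' @param x numeric vector of expression values.
#' @return Numeric vector of risk values in [0,1].
#' @export
evaluateRisk <- function(model, x) {
    thr <- model@bootThresholds
    nb <- length(thr)
    if (model@orientation == "high_is_1") {
        findInterval(x, thr) / nb                     # #(thr <= x) / nb
    } else {
        (nb - findInterval(x, thr, left.open = TRUE)) / nb  # #(thr >= x) / nb
    }
}

#' Look up the risk value of the nearest training sample
#'
#' Reference-set evaluation for new samples: returns the stored training
#' risk of the training sample whose expression value is closest to x.
#' Equidistant ties resolve to the lower expression value, a
#' deterministic rule independent of orientation.
#'
#' @inheritParams evaluateRisk
#' @return Numeric vector of risk values in [0,1].
#' @examples
#' rs <- new("RiskScoreModel", geneId = "g", orientation = "high_is_1",
#'           bootThresholds = c(5.5, 6.5), trainValues = c(5, 6, 9),
#'           trainRisk = c(0, 0.5, 1))
#' lookupRisk(rs, 6.2)   # 0.5 (nearest training value is 6)
#' @export
lookupRisk <- function(model, x) {
    if (!length(model@trainValues))
        stop("model has no training values for lookup", call. = FALSE)
    unname(nearestLookup(model@trainValues, model@trainRisk, x))
}

#' Transfer a risk score to a new cohort by quantile matching
#'
#' Builds in a new cohort a risk score equivalent to a reference model of
#' the same gene, assuming the cohorts draw from comparable populations
#' but were measured on platforms with different location/scale. Each
#' bootstrap threshold t of the reference maps to the q-th quantile of
#' the new cohort's values, where q is the empirical quantile of t among
#' the reference training values (inverse-ECDF quantiles, so a transfer
#' onto the reference cohort itself returns the original thresholds).
#' Training values and risks are recomputed on the new cohort;
#' orientation is preserved.
#'
#' @param refModel reference \linkS4class{RiskScoreModel}.
#' @param newValues named numeric vector (>= 20 values, nonzero variance)
#'   of the gene's expression in the new cohort.
#' @return A \linkS4class{RiskScoreModel} for the new cohort.
#' @seealso [riskEquivalence()] for the distributional check.
#' @export
equivalentRiskScore <- function(refModel, newValues) {
    vals <- newValues[is.finite(newValues)]
    if (length(vals) < 20L)
        stop("new cohort must provide at least 20 values", call. = FALSE)
    if (stats::var(vals) == 0)
        stop("new cohort values are constant", call. = FALSE)
    q <- ecdf(refModel@trainValues)(refModel@bootThresholds)
    thr <- sort(unname(quantile(vals, q, type = 1)))
    model <- new("RiskScoreModel", geneId = refModel@geneId,
                 orientation = refModel@orientation,
                 bootThresholds = thr, trainValues = vals,
                 trainRisk = setNames(numeric(length(vals)), names(vals)))
    model@trainRisk <- setNames(evaluateRisk(model, vals), names(vals))
    validObject(model)
    model
}

#' Kolmogorov-Smirnov distance between two risk-value distributions
#'
#' The distributional half of the risk-score equivalence criterion: two
#' risk scores of the same gene are considered equivalent when the
#' empirical distributions of their training risk values are within KS
#' distance \code{tol} (default 0.1), as happens when the cohorts sample
#' the same patient population.
#'
#' @param a,b \linkS4class{RiskScoreModel}s of the same gene.
#' @param tol equivalence tolerance on the KS distance.
#' @return A list with the KS \code{distance} and logical
#'   \code{equivalent}.
#' @export
riskEquivalence <- function(a, b, tol = 0.1) {
    if (!identical(a@geneId, b@geneId))
        stop("risk scores model different genes: ", a@geneId, " vs ",
             b@geneId, call. = FALSE)
    ra <- a@trainRisk; rb <- b@trainRisk
    grid <- sort(unique(c(ra, rb)))
    d <- max(abs(ecdf(ra)(grid) - ecdf(rb)(grid)))
    list(distance = d, equivalent = d <= tol)
}
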