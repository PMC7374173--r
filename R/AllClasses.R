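#' @importFrom methods new validObject is setClass setGeneric setMethod
#'   setValidity slot show callNextMethod
#' @importFrom stats median quantile ecdf lm coef dnorm rnorm rbinom rnbinom
#'   runif kmeans pt setNames binom.test
#' @importFrom utils read.delim write.table
#' @import SummarizedExperiment
#' @import S4Vectors
NULL

.EXPR_STATES <- c("raw_counts", "size_normalized", "log2_normalized")
.CMS_SUBTYPES <- c("CMS1", "CMS2", "CMS3", "CMS4")

#' Gene-by-sample expression matrix with a declared normalization state
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' (\code{"expr"}) of gene-by-sample values together with a declared state:
#' \code{"raw_counts"} (non-negative integers straight from feature
#' counting), \code{"size_normalized"} (after pseudo-reference size-factor
#' normalization) or \code{"log2_normalized"} (log2 of normalized values,
#' or array-style data that is already continuous). Functions that care
#' about the state refuse matrices in the wrong one, so the
#' counts -> size-factor -> log2 pipeline can only be run forwards.
#'
#' @slot state character(1), one of \code{"raw_counts"},
#'   \code{"size_normalized"}, \code{"log2_normalized"} (stored in
#'   \code{metadata()}).
#' @seealso [ExpressionMatrix()], [normalizeCounts()], [log2Transform()]
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
    msg <- character()
    st <- S4Vectors::metadata(object)$state
    if (is.null(st) || length(st) != 1L || !st %in% .EXPR_STATES)
        msg <- c(msg, sprintf("state must be one of: %s",
                              paste(.EXPR_STATES, collapse = ", ")))
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    v <- SummarizedExperiment::assay(object)
    if (!is.numeric(v))
        msg <- c(msg, "expression values must be numeric")
    if (identical(st, "raw_counts") &&
        (any(!is.finite(v)) || any(v < 0)))
        msg <- c(msg, "raw counts must be finite and >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids).
#' @param state declared normalization state; see
#'   \linkS4class{ExpressionMatrix}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rpois(6, 10), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' em <- ExpressionMatrix(m, "raw_counts")
#' exprState(em)
#' @export
ExpressionMatrix <- function(values,
                             state = c("raw_counts", "size_normalized",
                                       "log2_normalized")) {
    state <- match.arg(state)
    values <- as.matrix(values)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = values),
        metadata = list(state = state))
    new("ExpressionMatrix", se)
}

#' Size factors for pseudo-reference count normalization
#'
#' Per-gene geometric means (the pseudo-reference) for the genes retained
#' in the reference (those with strictly positive counts in every sample),
#' and per-sample medians of the gene-scaled counts.
#'
#' @slot geneFactors named numeric, geometric mean of raw counts per
#'   retained gene.
#' @slot sampleFactors named numeric, one per sample, all > 0.
#' @slot retainedGenes character, ids of genes entering the pseudo-reference.
#' @aliases SizeFactors-class
#' @seealso [computeSizeFactors()]
#' @exportClass SizeFactors
setClass("SizeFactors",
         representation(geneFactors = "numeric",
                        sampleFactors = "numeric",
                        retainedGenes = "character"))

setValidity("SizeFactors", function(object) {
    msg <- character()
    if (any(object@geneFactors <= 0))
        msg <- c(msg, "all retained gene factors must be > 0")
    if (any(object@sampleFactors <= 0))
        msg <- c(msg, "all sample factors must be > 0")
    if (length(object@geneFactors) != length(object@retainedGenes))
        msg <- c(msg, "one gene factor per retained gene")
    if (length(msg)) msg else TRUE
})

#' Two-component univariate Gaussian mixture fit
#'
#' The result of an EM fit of a two-component Gaussian mixture with
#' unequal variances, ordered so component 1 is the low mode and
#' component 2 the high mode, together with the boundary: the expression
#' value between the two component means at which the posterior
#' probability of the high component is exactly 1/2.
#'
#' @slot means numeric(2), component means (ascending).
#' @slot sds numeric(2), component standard deviations.
#' @slot weights numeric(2), mixing proportions in (0,1) summing to 1.
#' @slot boundary numeric(1), equal-posterior point between the means.
#' @slot logLik numeric(1) final log-likelihood.
#' @slot nIter integer(1) EM iterations used.
#' @aliases MixtureFit-class
#' @seealso [fitMixture()]
#' @exportClass MixtureFit
setClass("MixtureFit",
         representation(means = "numeric", sds = "numeric",
                        weights = "numeric", boundary = "numeric",
                        logLik = "numeric", nIter = "integer"))

setValidity("MixtureFit", function(object) {
    msg <- character()
    if (length(object@means) != 2L || length(object@sds) != 2L ||
        length(object@weights) != 2L)
        msg <- c(msg, "means, sds, weights must each have length 2")
    if (any(object@weights <= 0) || any(object@weights >= 1) ||
        abs(sum(object@weights) - 1) > 1e-8)
        msg <- c(msg, "weights must lie in (0,1) and sum to 1")
    if (any(object@sds <= 0))
        msg <- c(msg, "component sds must be > 0")
    b <- object@boundary
    if (b < min(object@means) || b > max(object@means))
        msg <- c(msg, "boundary must lie between the component means")
    if (!length(msg)) {
        post <- .posteriorHigh(b, object@means, object@sds, object@weights)
        if (abs(post - 0.5) > 1e-6)
            msg <- c(msg, "posterior of the high component at the boundary must be 0.5")
    }
    if (length(msg)) msg else TRUE
})

#' Per-gene bootstrap risk-score model
#'
#' A monotone step function of expression into [0,1] encoding the
#' probability that a sample lies in the high (orientation
#' \code{"high_is_1"}) or low (\code{"low_is_1"}) mixture component of a
#' bimodally expressed gene. The function is the empirical CDF (or
#' survival function) of the mixture boundaries refit on bootstrap
#' resamples of the training cohort, so its steepness reflects the
#' uncertainty in the threshold between the two modes. The training
#' expression values and their risk values are retained as a lookup table
#' for scoring new samples by nearest expression value.
#'
#' @slot geneId character(1).
#' @slot orientation \code{"high_is_1"} or \code{"low_is_1"}.
#' @slot bootThresholds sorted numeric, one boundary per bootstrap.
#' @slot trainValues named numeric, training expression values.
#' @slot trainRisk named numeric in [0,1], risk value per training sample.
#' @aliases RiskScoreModel-class
#' @seealso [buildRiskScore()], [evaluateRisk()], [lookupRisk()]
#' @exportClass RiskScoreModel
setClass("RiskScoreModel",
         representation(geneId = "character", orientation = "character",
                        bootThresholds = "numeric", trainValues = "numeric",
                        trainRisk = "numeric"))

setValidity("RiskScoreModel", function(object) {
    msg <- character()
    if (!object@orientation %in% c("high_is_1", "low_is_1"))
        msg <- c(msg, "orientation must be 'high_is_1' or 'low_is_1'")
    if (is.unsorted(object@bootThresholds))
        msg <- c(msg, "bootThresholds must be sorted ascending")
    if (length(object@trainRisk) != length(object@trainValues))
        msg <- c(msg, "trainRisk and trainValues must have equal length")
    if (any(object@trainRisk < 0 | object@trainRisk > 1))
        msg <- c(msg, "trainRisk values must lie in [0,1]")
    if (length(object@trainValues) > 1L) {
        o <- order(object@trainValues)
        r <- object@trainRisk[o]
        mono <- if (object@orientation == "high_is_1") !is.unsorted(r)
                else !is.unsorted(rev(r))
        if (!mono)
            msg <- c(msg, "trainRisk must be monotone in trainValues per orientation")
    }
    if (length(msg)) msg else TRUE
})

#' Multigene risk score (MRS) model for one subtype
#'
#' A panel of per-gene \linkS4class{RiskScoreModel}s whose mean risk is
#' calibrated into a continuous subtype-membership score through a
#' monotone positive-predictive-value (PPV) curve fitted on the training
#' cohort: the raw PPV at each training sample (fraction of samples with
#' at least that mean risk that truly belong to the subtype) is made
#' non-decreasing by isotonic regression and joined by monotone
#' piecewise-linear interpolation.
#'
#' @slot subtype character(1) label, e.g. "CMS1".
#' @slot panel list of \linkS4class{RiskScoreModel}, one per panel gene.
#' @slot trainMeanRisk named numeric, mean panel risk per training sample.
#' @slot trainScore named numeric in [0,1], calibrated score per training
#'   sample.
#' @slot curveGrid numeric, sorted unique mean-risk grid.
#' @slot curveValues numeric in [0,1], non-decreasing along curveGrid.
#' @aliases MRSModel-class
#' @seealso [fitMRS()], [evaluateMRS()], [scoreCohort()]
#' @exportClass MRSModel
setClass("MRSModel",
         representation(subtype = "character", panel = "list",
                        trainMeanRisk = "numeric", trainScore = "numeric",
                        curveGrid = "numeric", curveValues = "numeric"))

setValidity("MRSModel", function(object) {
    msg <- character()
    if (!all(vapply(object@panel, is, logical(1), "RiskScoreModel")))
        msg <- c(msg, "panel must be a list of RiskScoreModel")
    if (is.unsorted(object@curveGrid, strictly = TRUE) &&
        length(object@curveGrid) > 1L && is.unsorted(object@curveGrid))
        msg <- c(msg, "curveGrid must be sorted ascending")
    if (length(object@curveGrid) != length(object@curveValues))
        msg <- c(msg, "curveGrid and curveValues must have equal length")
    if (is.unsorted(object@curveValues))
        msg <- c(msg, "curveValues must be non-decreasing")
    if (any(object@curveValues < 0 | object@curveValues > 1))
        msg <- c(msg, "curveValues must lie in [0,1]")
    if (length(object@trainMeanRisk) &&
        (min(object@curveGrid) > min(object@trainMeanRisk) ||
         max(object@curveGrid) < max(object@trainMeanRisk)))
        msg <- c(msg, "curveGrid must cover the range of trainMeanRisk")
    if (length(object@trainScore) != length(object@trainMeanRisk))
        msg <- c(msg, "trainScore and trainMeanRisk must have equal length")
    if (length(msg)) msg else TRUE
})

#' Full four-subtype classifier with reference metadata
#'
#' One \linkS4class{MRSModel} per consensus molecular subtype (CMS1-4),
#' the per-subtype Youden-index classification thresholds selected on the
#' training cohort, and provenance needed to use the object as a
#' serialized reference set for single-sample prediction: the
#' normalization settings the training expression went through, the seed,
#' and a schema version for the JSON serialization.
#'
#' @slot mrsModels named list of \linkS4class{MRSModel} (CMS1..CMS4).
#' @slot thresholds named numeric in (0,1), one per subtype.
#' @slot referenceId character(1) free-text provenance of the reference
#'   cohort.
#' @slot normalization list with elements \code{pseudocount} and
#'   \code{conventional} describing how training counts were normalized.
#' @slot seed integer(1) master seed used in training.
#' @slot version character(1) serialization schema version.
#' @aliases ColoTypeModel-class
#' @seealso [trainColoType()], [classifyCohort()], [predictSingleSample()],
#'   [saveModel()]
#' @exportClass ColoTypeModel
setClass("ColoTypeModel",
         representation(mrsModels = "list", thresholds = "numeric",
                        referenceId = "character", normalization = "list",
                        seed = "integer", version = "character"))

setValidity("ColoTypeModel", function(object) {
    msg <- character()
    if (!identical(sort(names(object@mrsModels)), .CMS_SUBTYPES))
        msg <- c(msg, "mrsModels must contain exactly CMS1..CMS4")
    if (!identical(sort(names(object@thresholds)), .CMS_SUBTYPES))
        msg <- c(msg, "thresholds must contain exactly CMS1..CMS4")
    if (any(object@thresholds <= 0 | object@thresholds >= 1))
        msg <- c(msg, "thresholds must lie in (0,1)")
    if (length(msg)) msg else TRUE
})

#' Per-sample subtype calls
#'
#' Continuous subtype scores, per-subtype positivity (score at or above
#' the classification threshold), the assigned discrete label (the
#' positive subtype with maximal score, or \code{"NONE"} when no score
#' clears its threshold), and the mixed-type flag (two or more subtypes
#' positive). \code{tied} marks samples whose label was resolved by the
#' fixed CMS1 < CMS2 < CMS3 < CMS4 order among exactly tied maximal
#' positive scores.
#'
#' @slot scores numeric matrix, samples x subtypes (CMS1..CMS4).
#' @slot positive logical matrix, same shape.
#' @slot label character, one of CMS1..CMS4 or "NONE" per sample.
#' @slot mixed logical per sample.
#' @slot tied logical per sample.
#' @slot thresholds named numeric used for positivity.
#' @aliases SubtypeCalls-class
#' @seealso [assignSubtypes()], [mixedTypeTable()], [callsToFrame()]
#' @exportClass SubtypeCalls
setClass("SubtypeCalls",
         representation(scores = "matrix", positive = "matrix",
                        label = "character", mixed = "logical",
                        tied = "logical", thresholds = "numeric"))

setValidity("SubtypeCalls", function(object) {
    msg <- character()
    n <- nrow(object@scores)
    if (!identical(colnames(object@scores), .CMS_SUBTYPES))
        msg <- c(msg, "score columns must be CMS1..CMS4")
    if (!identical(dim(object@positive), dim(object@scores)))
        msg <- c(msg, "positive must match scores in shape")
    if (length(object@label) != n || length(object@mixed) != n)
        msg <- c(msg, "label and mixed must have one entry per sample")
    ok <- object@label %in% c(.CMS_SUBTYPES, "NONE")
    if (!all(ok))
        msg <- c(msg, "labels must be CMS1..CMS4 or NONE")
    if (!length(msg) && n) {
        if (!identical(object@positive,
                       object@scores >= rep(object@thresholds[colnames(object@scores)],
                                            each = n)))
            msg <- c(msg, "positive[k] must equal scores[k] >= thresholds[k]")
        if (any(object@mixed != (rowSums(object@positive) >= 2L)))
            msg <- c(msg, "mixed must flag samples with >= 2 positives")
        lab <- object@label
        idx <- which(lab != "NONE")
        if (length(idx)) {
            cells <- cbind(idx, match(lab[idx], colnames(object@positive)))
            if (any(!object@positive[cells]))
                msg <- c(msg, "assigned label must be positive")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Multiclass agreement statistics
#'
#' A predicted-by-truth contingency table over the retained class set
#' with overall accuracy (and Clopper-Pearson 95\% CI), Cohen's kappa and
#' one-vs-rest sensitivity/specificity per class. \code{nExcluded}
#' records how many samples were dropped because either side was
#' unclassified.
#'
#' @slot table integer matrix, predicted (rows) x truth (columns).
#' @slot accuracy numeric(1).
#' @slot accuracyCI numeric(2) 95\% Clopper-Pearson interval.
#' @slot kappa numeric(1).
#' @slot sensitivity named numeric per class.
#' @slot specificity named numeric per class.
#' @slot nExcluded integer(1).
#' @aliases ConfusionStats-class
#' @seealso [confusionStats()]
#' @exportClass ConfusionStats
setClass("ConfusionStats",
         representation(table = "matrix", accuracy = "numeric",
                        accuracyCI = "numeric", kappa = "numeric",
                        sensitivity = "numeric", specificity = "numeric",
                        nExcluded = "integer"))

setValidity("ConfusionStats", function(object) {
    msg <- character()
    if (any(object@table < 0))
        msg <- c(msg, "table entries must be >= 0")
    if (object@accuracy < 0 || object@accuracy > 1)
        msg <- c(msg, "accuracy must lie in [0,1]")
    if (object@kappa > 1)
        msg <- c(msg, "kappa cannot exceed 1")
    if (any(object@sensitivity < 0 | object@sensitivity > 1, na.rm = TRUE) ||
        any(object@specificity < 0 | object@specificity > 1, na.rm = TRUE))
        msg <- c(msg, "sensitivity/specificity must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Specification of one synthetic cohort
#'
#' Parameters of the seeded generator that emulates a multi-platform
#' colorectal-cancer expression cohort with known subtype structure:
#' subtype mixing proportions, per-subtype bimodal marker genes whose high
#' mode is shifted by \code{effectSize} within-component standard
#' deviations, subtype-independent noise genes, an output platform
#' (negative-binomial integer counts or continuous log2-scale values) and
#' a fraction of mixed-type samples carrying a second subtype's marker
#' elevation at reduced magnitude.
#'
#' @slot nSamples integer(1) >= 40.
#' @slot proportions named numeric over CMS1..CMS4 and NONE, summing to 1.
#' @slot nMarkerGenesPerSubtype integer(1).
#' @slot nNoiseGenes integer(1).
#' @slot effectSize numeric(1) > 0, separation in sd units.
#' @slot platform \code{"counts_nb"} or \code{"gaussian_log"}.
#' @slot mixedFraction numeric(1) in [0,1).
#' @slot dispersion numeric(1) negative-binomial dispersion.
#' @slot librarySdLog numeric(1) sd of log-normal library-size factors.
#' @slot locationShift,scaleFactor numeric(1) platform-specific affine
#'   shift applied on the log2 scale.
#' @slot seed integer(1).
#' @aliases CohortSpec-class
#' @seealso [cohortSpec()], [generateCohort()]
#' @exportClass CohortSpec
setClass("CohortSpec",
         representation(nSamples = "integer", proportions = "numeric",
                        nMarkerGenesPerSubtype = "integer",
                        nNoiseGenes = "integer", effectSize = "numeric",
                        platform = "character", mixedFraction = "numeric",
                        dispersion = "numeric", librarySdLog = "numeric",
                        locationShift = "numeric", scaleFactor = "numeric",
                        seed = "integer"))

setValidity("CohortSpec", function(object) {
    msg <- character()
    if (object@nSamples < 40L)
        msg <- c(msg, "nSamples must be >= 40")
    p <- object@proportions
    if (!identical(sort(names(p)), sort(c(.CMS_SUBTYPES, "NONE"))) ||
        any(p < 0) || abs(sum(p) - 1) > 1e-8)
        msg <- c(msg, "proportions must cover CMS1..CMS4 and NONE, be >= 0 and sum to 1")
    if (object@effectSize < 0)
        msg <- c(msg, "effectSize must be >= 0")
    if (!object@platform %in% c("counts_nb", "gaussian_log"))
        msg <- c(msg, "platform must be 'counts_nb' or 'gaussian_log'")
    if (object@mixedFraction < 0 || object@mixedFraction >= 1)
        msg <- c(msg, "mixedFraction must lie in [0,1)")
    if (length(msg)) msg else TRUE
})
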