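#' Accessors for ColoType objects
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{exprState} returns the declared normalization state of an
#' \linkS4class{ExpressionMatrix}; \code{exprValues} its numeric matrix;
#' \code{geneIds} / \code{sampleIds} its dimnames. \code{geneFactors} and
#' \code{sampleFactors} read a \linkS4class{SizeFactors};
#' \code{bootThresholds}, \code{riskOrientation}, \code{trainValues} and
#' \code{trainRisk} read a \linkS4class{RiskScoreModel};
#' \code{panelGenes}, \code{trainMeanRisk}, \code{trainScore} and
#' \code{mrsCurve} read an \linkS4class{MRSModel}; \code{mrsModels} and
#' \code{classificationThresholds} read a \linkS4class{ColoTypeModel};
#' \code{callLabels}, \code{callScores}, \code{positivity} and
#' \code{isMixed} read a \linkS4class{SubtypeCalls}.
#'
#' @param x the object.
#' @return The corresponding component.
#' @name accessors
#' @aliases exprState exprValues geneIds sampleIds geneFactors
#'   sampleFactors bootThresholds riskOrientation trainValues trainRisk
#'   panelGenes trainMeanRisk trainScore mrsCurve mrsModels
#'   classificationThresholds callLabels callScores positivity isMixed
#' @examples
#' m <- matrix(1:6, nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' em <- ExpressionMatrix(m, "raw_counts")
#' exprState(em)
#' geneIds(em)
NULL

#' @rdname accessors
#' @export
setGeneric("exprState", function(x) standardGeneric("exprState"))
#' @rdname accessors
#' @export
setMethod("exprState", "ExpressionMatrix",
          function(x) S4Vectors::metadata(x)$state)

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix",
          function(x) SummarizedExperiment::assay(x, "expr"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setGeneric("geneFactors", function(x) standardGeneric("geneFactors"))
#' @rdname accessors
#' @export
setMethod("geneFactors", "SizeFactors", function(x) x@geneFactors)

#' @rdname accessors
#' @export
setGeneric("sampleFactors", function(x) standardGeneric("sampleFactors"))
#' @rdname accessors
#' @export
setMethod("sampleFactors", "SizeFactors", function(x) x@sampleFactors)

#' @rdname accessors
#' @export
setGeneric("bootThresholds", function(x) standardGeneric("bootThresholds"))
#' @rdname accessors
#' @export
setMethod("bootThresholds", "RiskScoreModel", function(x) x@bootThresholds)

#' @rdname accessors
#' @export
setGeneric("riskOrientation", function(x) standardGeneric("riskOrientation"))
#' @rdname accessors
#' @export
setMethod("riskOrientation", "RiskScoreModel", function(x) x@orientation)

#' @rdname accessors
#' @export
setGeneric("trainValues", function(x) standardGeneric("trainValues"))
#' @rdname accessors
#' @export
setMethod("trainValues", "RiskScoreModel", function(x) x@trainValues)

#' @rdname accessors
#' @export
setGeneric("trainRisk", function(x) standardGeneric("trainRisk"))
#' @rdname accessors
#' @export
setMethod("trainRisk", "RiskScoreModel", function(x) x@trainRisk)

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setMethod("geneId", "RiskScoreModel", function(x) x@geneId)

#' @rdname accessors
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))
#' @rdname accessors
#' @export
setMethod("panelGenes", "MRSModel",
          function(x) vapply(x@panel, geneId, character(1)))
#' @rdname accessors
#' @export
setMethod("panelGenes", "ColoTypeModel",
          function(x) lapply(x@mrsModels, panelGenes))

#' @rdname accessors
#' @export
setGeneric("trainMeanRisk", function(x) standardGeneric("trainMeanRisk"))
#' @rdname accessors
#' @export
setMethod("trainMeanRisk", "MRSModel", function(x) x@trainMeanRisk)

#' @rdname accessors
#' @export
setGeneric("trainScore", function(x) standardGeneric("trainScore"))
#' @rdname accessors
#' @export
setMethod("trainScore", "MRSModel", function(x) x@trainScore)

#' @rdname accessors
#' @export
setGeneric("mrsCurve", function(x) standardGeneric("mrsCurve"))
#' @rdname accessors
#' @export
setMethod("mrsCurve", "MRSModel",
          function(x) data.frame(meanRisk = x@curveGrid, score = x@curveValues))

#' @rdname accessors
#' @export
setGeneric("mrsModels", function(x) standardGeneric("mrsModels"))
#' @rdname accessors
#' @export
setMethod("mrsModels", "ColoTypeModel", function(x) x@mrsModels)

#' @rdname accessors
#' @export
setGeneric("classificationThresholds",
           function(x) standardGeneric("classificationThresholds"))
#' @rdname accessors
#' @export
setMethod("classificationThresholds", "ColoTypeModel",
          function(x) x@thresholds)
#' @rdname accessors
#' @export
setMethod("classificationThresholds", "SubtypeCalls",
          function(x) x@thresholds)

#' @rdname accessors
#' @export
setGeneric("callLabels", function(x) standardGeneric("callLabels"))
#' @rdname accessors
#' @export
setMethod("callLabels", "SubtypeCalls",
          function(x) setNames(x@label, rownames(x@scores)))

#' @rdname accessors
#' @export
setGeneric("callScores", function(x) standardGeneric("callScores"))
#' @rdname accessors
#' @export
setMethod("callScores", "SubtypeCalls", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("positivity", function(x) standardGeneric("positivity"))
#' @rdname accessors
#' @export
setMethod("positivity", "SubtypeCalls", function(x) x@positive)

#' @rdname accessors
#' @export
setGeneric("isMixed", function(x) standardGeneric("isMixed"))
#' @rdname accessors
#' @export
setMethod("isMixed", "SubtypeCalls",
          function(x) setNames(x@mixed, rownames(x@scores)))

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
                nrow(object), ncol(object), exprState(object)))
})

setMethod("show", "SizeFactors", function(object) {
    cat(sprintf("SizeFactors: %d reference genes, %d samples\n",
                length(object@geneFactors), length(object@sampleFactors)))
    cat("  sample factors: ",
        paste(sprintf("%.3g", head(object@sampleFactors, 5)), collapse = ", "),
        if (length(object@sampleFactors) > 5) ", ..." else "", "\n", sep = "")
})

setMethod("show", "MixtureFit", function(object) {
    cat(sprintf(
        "MixtureFit: means %.3g/%.3g, sds %.3g/%.3g, weights %.2f/%.2f\n",
        object@means[1], object@means[2], object@sds[1], object@sds[2],
        object@weights[1], object@weights[2]))
    cat(sprintf("  boundary %.4g (logLik %.4g, %d EM iterations)\n",
                object@boundary, object@logLik, object@nIter))
})

setMethod("show", "RiskScoreModel", function(object) {
    cat(sprintf("RiskScoreModel for %s [%s]: %d bootstrap thresholds in [%.3g, %.3g], %d training samples\n",
                object@geneId, object@orientation,
                length(object@bootThresholds),
                min(object@bootThresholds), max(object@bootThresholds),
                length(object@trainValues)))
})

setMethod("show", "MRSModel", function(object) {
    cat(sprintf("MRSModel for %s: %d panel genes (%s), %d training samples\n",
                object@subtype, length(object@panel),
                paste(head(panelGenes(object), 4), collapse = ", "),
                length(object@trainMeanRisk)))
})

setMethod("show", "ColoTypeModel", function(object) {
    cat(sprintf("ColoTypeModel (reference: %s)\n", object@referenceId))
    for (s in names(object@mrsModels))
        cat(sprintf("  %s: %2d genes, threshold %.3f\n", s,
                    length(object@mrsModels[[s]]@panel),
                    object@thresholds[[s]]))
})

setMethod("show", "SubtypeCalls", function(object) {
    n <- length(object@label)
    cat(sprintf("SubtypeCalls for %d samples\n", n))
    tab <- table(factor(object@label, levels = c(.CMS_SUBTYPES, "NONE")))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "  "), "\n")
    cat(sprintf("  mixed type: %d (%.1f%%)\n", sum(object@mixed),
                100 * mean(object@mixed)))
})

setMethod("show", "ConfusionStats", function(object) {
    cat(sprintf("ConfusionStats (%d samples retained, %d excluded)\n",
                sum(object@table), object@nExcluded))
    cat(sprintf("  accuracy %.3f (95%% CI %.3f-%.3f), kappa %.3f\n",
                object@accuracy, object@accuracyCI[1], object@accuracyCI[2],
                object@kappa))
    print(object@table)
})

setMethod("show", "CohortSpec", function(object) {
    cat(sprintf("CohortSpec: %d samples, %d markers/subtype + %d noise genes, effect %.2g sd, platform %s, seed %d\n",
                object@nSamples, object@nMarkerGenesPerSubtype,
                object@nNoiseGenes, object@effectSize, object@platform,
                object@seed))
})
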