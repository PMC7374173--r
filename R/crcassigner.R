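#' Train the two-gene Enterocyte MRS score
#'
#' The Enterocyte subtype of the five-class CRCassigner taxonomy is not
#' separable by the four CMS scores alone; it is predicted by a dedicated
#' MRS score built from the carbonic anhydrase genes CA1 and CA2. This is
#' an ordinary two-gene MRS model: bootstrap risk scores for both genes
#' (orientation chosen from membership) calibrated through the PPV curve.
#'
#' @param trainExpr \linkS4class{ExpressionMatrix} (counts are normalized
#'   to log2 first) containing both genes.
#' @param membership logical per sample: is the sample Enterocyte?
#' @param genes the two marker genes (default \code{c("CA1", "CA2")}).
#' @param nBoot,seed bootstrap settings as in [buildRiskScore()].
#' @return An \linkS4class{MRSModel} with subtype \code{"Enterocyte"}.
#' @export
trainEnterocyte <- function(trainExpr, membership,
                            genes = c("CA1", "CA2"), nBoot = 200L,
                            seed = 1L) {
    expr <- normalizeToLog2(trainExpr)
    v <- exprValues(expr)
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
        stop("missing genes: ", paste(missing, collapse = ", "),
             call. = FALSE)
    membership <- as.logical(membership)
    panel <- lapply(genes, function(g) {
        rs <- buildRiskScore(g, v[g, ], orientation = "high_is_1",
                             nBoot = nBoot, seed = deriveSeed(seed, g))
        if (mean(rs@trainRisk[membership]) < mean(rs@trainRisk[!membership]))
            rs <- flipOrientation(rs)
        rs
    })
    fitMRS("Enterocyte", panel, trainExpr = expr, membership = membership)
}

#' CRCassigner-style scores derived from the CMS scores
#'
#' Arithmetic on the four CMS scores and the Enterocyte score:
#' Inflammatory = CMS1; Goblet-like = CMS3;
#' Stem-like = CMS4 - Enterocyte (removing the Enterocyte admixture of
#' the mesenchymal class); TA = CMS2 - Enterocyte - CMS4 (the canonical
#' class minus its Enterocyte and mesenchymal components). Inflammatory,
#' Goblet-like and Enterocyte stay in [0,1]; Stem-like lies in [-1,1] and
#' TA in [-2,1].
#'
#' @param cmsScores named numeric vector or samples x 4 matrix of CMS
#'   scores (CMS1..CMS4) in [0,1].
#' @param enterocyte numeric Enterocyte score(s) in [0,1].
#' @return data.frame with columns inflammatory, ta, goblet_like,
#'   stem_like, enterocyte.
#' @examples
#' derivedScores(c(CMS1 = 0.1, CMS2 = 0.9, CMS3 = 0.2, CMS4 = 0.2),
#'               enterocyte = 0.1)
#' @export
derivedScores <- function(cmsScores, enterocyte) {
    if (is.null(dim(cmsScores)))
        cmsScores <- matrix(cmsScores, nrow = 1,
                            dimnames = list(NULL, names(cmsScores)))
    if (!all(.CMS_SUBTYPES %in% colnames(cmsScores)))
        stop("cmsScores must contain CMS1..CMS4", call. = FALSE)
    if (any(cmsScores < 0 | cmsScores > 1) ||
        any(enterocyte < 0 | enterocyte > 1))
        stop("all input scores must lie in [0,1]", call. = FALSE)
    if (length(enterocyte) != nrow(cmsScores))
        stop("one enterocyte score per sample is required", call. = FALSE)
    data.frame(
        inflammatory = cmsScores[, "CMS1"],
        ta = cmsScores[, "CMS2"] - enterocyte - cmsScores[, "CMS4"],
        goblet_like = cmsScores[, "CMS3"],
        stem_like = cmsScores[, "CMS4"] - enterocyte,
        enterocyte = enterocyte,
        row.names = rownames(cmsScores))
}

#' Discrete CRCassigner-style call from a CMS call
#'
#' A deliberately simple, documented decision rule mapping each discrete
#' CMS call to a five-class label: CMS1 -> Inflammatory; CMS3 ->
#' Goblet-like; CMS2 and CMS4 -> Enterocyte when the Enterocyte score is
#' at or above \code{entThreshold}, otherwise TA (from CMS2) or Stem-like
#' (from CMS4); unclassified stays unclassified. \code{cms4Threshold} is
#' accepted for interface stability but unused by this simplified rule
#' (a finer tree would additionally condition the Enterocyte/Stem-like
#' split on the CMS4 score).
#'
#' @param calls a \linkS4class{SubtypeCalls}.
#' @param scores data.frame from [derivedScores()] aligned with the
#'   calls.
#' @param entThreshold,cms4Threshold thresholds in (0,1), defaults 0.5.
#' @return character vector of labels in \{Inflammatory, Enterocyte, TA,
#'   Goblet-like, Stem-like, NONE\}.
#' @export
callCRCAssigner <- function(calls, scores, entThreshold = 0.5,
                            cms4Threshold = 0.5) {
    if (entThreshold <= 0 || entThreshold >= 1 ||
        cms4Threshold <= 0 || cms4Threshold >= 1)
        stop("thresholds must lie in (0,1)", call. = FALSE)
    cms <- callLabels(calls)
    if (length(cms) != nrow(scores))
        stop("calls and scores must cover the same samples", call. = FALSE)
    ent <- scores$enterocyte
    out <- character(length(cms))
    for (i in seq_along(cms)) {
        out[i] <- switch(cms[[i]],
            CMS1 = "Inflammatory",
            CMS3 = "Goblet-like",
            CMS2 = if (ent[i] >= entThreshold) "Enterocyte" else "TA",
            CMS4 = if (ent[i] >= entThreshold) "Enterocyte" else "Stem-like",
            "NONE")
    }
    setNames(out, names(cms))
}
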