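#' Significance of a risk score as a predictor of subtype membership
#'
#' Ordinary least squares of the risk value on a 0/1 membership
#' indicator, returning the two-sided p-value of the indicator
#' coefficient. With a single binary covariate this is exactly the
#' pooled-variance two-sample t-test, so the resulting gene ordering is
#' the classical differential-risk ordering.
#'
#' @param riskValues per-sample risk values.
#' @param membership per-sample logical membership.
#' @return numeric(1) two-sided p-value.
#' @export
rankRiskScore <- function(riskValues, membership) {
    membership <- as.logical(membership)
    if (length(riskValues) != length(membership))
        stop("riskValues and membership must have equal length",
             call. = FALSE)
    if (!any(membership) || all(membership))
        stop("both groups must be non-empty", call. = FALSE)
    if (stats::var(riskValues) == 0 && length(riskValues) > 2L)
        return(1)
    if (length(riskValues) < 3L)
        stop("zero residual degrees of freedom", call. = FALSE)
    fit <- lm(riskValues ~ membership)
    sm <- summary(fit)$coefficients
    if (nrow(sm) < 2L || is.na(sm[2L, 4L])) 1 else unname(sm[2L, 4L])
}

#' Consensus ranking of genes across cohorts by triplet mean rank
#'
#' Each gene's risk score is ranked within every cohort by the p-value of
#' [rankRiskScore()] (ascending, average ranks for ties); the triplet of a
#' gene's per-cohort ranks is summarized by its mean, and genes are
#' ordered by mean rank, lowest (most consistently significant) first.
#' Mean-rank ties break by the best single-cohort rank, then gene id, so
#' the ordering is deterministic. Genes absent from any cohort cannot
#' form a complete triplet and are excluded with a warning.
#'
#' @param perCohort named list (one element per cohort) of named numeric
#'   vectors mapping gene id -> p-value.
#' @return data.frame sorted by \code{meanRank} with one row per gene:
#'   per-cohort p-values and ranks, \code{meanRank}, \code{bestRank}.
#' @export
rankTriplets <- function(perCohort) {
    if (!length(perCohort))
        stop("at least one cohort is required", call. = FALSE)
    common <- Reduce(intersect, lapply(perCohort, names))
    all <- unique(unlist(lapply(perCohort, names)))
    dropped <- setdiff(all, common)
    if (length(dropped))
        warning(length(dropped),
                " gene(s) missing from at least one cohort were excluded: ",
                paste(head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ..." else "")
    if (!length(common))
        stop("no gene is present in every cohort", call. = FALSE)
    pv <- vapply(perCohort, function(p) p[common],
                 numeric(length(common)))
    pv <- matrix(pv, nrow = length(common),
                 dimnames = list(common, names(perCohort)))
    rk <- apply(pv, 2L, rank, ties.method = "average")
    rk <- matrix(rk, nrow = length(common),
                 dimnames = dimnames(pv))
    meanRank <- rowMeans(rk)
    bestRank <- apply(rk, 1L, min)
    out <- data.frame(geneId = common, meanRank = meanRank,
                      bestRank = bestRank, row.names = NULL,
                      stringsAsFactors = FALSE)
    for (co in names(perCohort)) {
        out[[paste0("pvalue.", co)]] <- pv[, co]
        out[[paste0("rank.", co)]] <- rk[, co]
    }
    out[order(out$meanRank, out$bestRank, out$geneId), , drop = FALSE]
}

#' Smallest panel size whose AUC clears a floor in every cohort
#'
#' The panel-size decision rule: given the AUC of the candidate MRS score
#' at each panel size in each training cohort, return the smallest size
#' whose AUC exceeds \code{aucFloor} in all cohorts. When no size
#' qualifies, the size with the highest minimum AUC across cohorts is
#' returned and flagged.
#'
#' @param auc numeric matrix, candidate sizes (rows, rownames = sizes) x
#'   cohorts (columns).
#' @param sizes integer vector of candidate sizes, ascending; defaults to
#'   \code{as.integer(rownames(auc))}.
#' @param aucFloor the AUC floor (default 0.90).
#' @return list with \code{size}, logical \code{flagged}, and the
#'   \code{auc} matrix.
#' @examples
#' auc <- rbind("5"  = c(0.95, 0.88, 0.97), "7"  = c(0.96, 0.89, 0.97),
#'              "10" = c(0.98, 0.91, 0.98), "15" = c(0.98, 0.95, 0.98),
#'              "20" = c(0.98, 0.97, 0.98))
#' selectPanelSize(auc)$size   # 10
#' @export
selectPanelSize <- function(auc, sizes = as.integer(rownames(auc)),
                            aucFloor = 0.90) {
    auc <- as.matrix(auc)
    if (!length(sizes) || nrow(auc) != length(sizes))
        stop("one row of AUC values per candidate size is required",
             call. = FALSE)
    if (is.unsorted(sizes, strictly = TRUE))
        stop("candidate sizes must be strictly ascending", call. = FALSE)
    clears <- apply(auc > aucFloor, 1L, all)
    if (any(clears)) {
        k <- which(clears)[1L]
        list(size = sizes[k], flagged = FALSE, auc = auc)
    } else {
        k <- which.max(apply(auc, 1L, min))
        list(size = sizes[k], flagged = TRUE, auc = auc)
    }
}

#' Select a gene panel from a consensus ranking by AUC floor
#'
#' For each candidate size k, builds the MRS score from the top-k ranked
#' genes in every cohort's training set, measures its AUC against
#' membership, and applies [selectPanelSize()]. Raising the floor can
#' only keep or enlarge the returned panel.
#'
#' @param ranked data.frame from [rankTriplets()] (ordered best first).
#' @param cohorts named list; each element a list with \code{riskModels}
#'   (named list of \linkS4class{RiskScoreModel} covering the ranked
#'   genes) and \code{membership} (logical per training sample).
#' @param candidateSizes ascending candidate panel sizes.
#' @param aucFloor the AUC floor (default 0.90).
#' @return list with \code{size}, \code{genes} (the selected top genes),
#'   \code{flagged}, and the size x cohort \code{auc} matrix.
#' @export
selectPanel <- function(ranked, cohorts,
                        candidateSizes = c(5L, 7L, 10L, 15L, 20L),
                        aucFloor = 0.90) {
    if (!length(candidateSizes))
        stop("candidateSizes must be non-empty", call. = FALSE)
    candidateSizes <- as.integer(sort(candidateSizes))
    if (max(candidateSizes) > nrow(ranked))
        stop("largest candidate size exceeds the number of ranked genes",
             call. = FALSE)
    auc <- matrix(NA_real_, nrow = length(candidateSizes),
                  ncol = length(cohorts),
                  dimnames = list(as.character(candidateSizes),
                                  names(cohorts)))
    for (i in seq_along(candidateSizes)) {
        genes <- ranked$geneId[seq_len(candidateSizes[i])]
        for (co in seq_along(cohorts)) {
            panel <- cohorts[[co]]$riskModels[genes]
            if (any(vapply(panel, is.null, logical(1))))
                stop("cohort '", names(cohorts)[co],
                     "' lacks risk models for some ranked genes",
                     call. = FALSE)
            mrs <- fitMRS("panel", panel, trainExpr = NULL,
                          membership = cohorts[[co]]$membership)
            auc[i, co] <- rocAUC(trainScore(mrs),
                                 cohorts[[co]]$membership)
        }
    }
    sel <- selectPanelSize(auc, candidateSizes, aucFloor)
    list(size = sel$size, genes = ranked$geneId[seq_len(sel$size)],
         flagged = sel$flagged, auc = auc)
}

#' Collapse duplicate features to one row per gene by maximal IQR
#'
#' Array platforms measure a gene with several features; for coordinated
#' multi-cohort ranking each gene must have a unique expression value.
#' Among all features annotated to the same gene, the one with maximal
#' interquartile range in this (training) matrix is retained and the row
#' is renamed to the gene id.
#'
#' @param em an \linkS4class{ExpressionMatrix} whose rownames are feature
#'   ids.
#' @param annotation named character vector mapping feature id -> gene
#'   id; features without an annotation are dropped.
#' @return \linkS4class{ExpressionMatrix} with one row per gene.
#' @export
collapseFeatures <- function(em, annotation) {
    v <- exprValues(em)
    feats <- intersect(rownames(v), names(annotation))
    if (!length(feats))
        stop("no features in the matrix are covered by the annotation",
             call. = FALSE)
    v <- v[feats, , drop = FALSE]
    gene <- annotation[feats]
    iqr <- apply(v, 1L, stats::IQR)
    ord <- order(gene, -iqr, feats)   # per gene: best IQR first
    pick <- ord[!duplicated(gene[ord])]
    out <- v[pick, , drop = FALSE]
    rownames(out) <- gene[pick]
    ExpressionMatrix(out, exprState(em))
}

#' Run the multi-cohort discovery pipeline
#'
#' The full panel-discovery procedure over a set of training cohorts
#' measured on different platforms: per cohort, every shared gene gets a
#' bootstrap risk score (genes whose mixture fit fails anywhere are
#' dropped from candidacy — they are not reliably dichotomizable); per
#' subtype, risk scores are oriented by membership, ranked by the linear
#' model p-value in each cohort, aggregated by triplet mean rank, and a
#' panel size is selected by the AUC floor.
#'
#' @param cohorts named list; each element a list with \code{expr} (an
#'   \linkS4class{ExpressionMatrix}; counts are normalized to log2) and
#'   \code{truth} (per-sample labels CMS1..CMS4/NONE).
#' @param nBoot,seed bootstrap settings; each gene/cohort stream is
#'   derived from \code{seed}.
#' @param candidateSizes,aucFloor passed to [selectPanel()].
#' @param subtypes subtype labels to build panels for.
#' @return list with \code{panels} (subtype -> selected gene ids),
#'   \code{selection} (per subtype, the [selectPanel()] result),
#'   \code{riskModels} (cohort -> gene -> \linkS4class{RiskScoreModel}),
#'   \code{exprs} (the normalized cohort matrices) and \code{dropped}
#'   (genes without a risk score in every cohort).
#' @export
discoverPanels <- function(cohorts, nBoot = 200L, seed = 1L,
                           candidateSizes = c(5L, 7L, 10L, 15L, 20L),
                           aucFloor = 0.90,
                           subtypes = c("CMS1", "CMS2", "CMS3", "CMS4")) {
    if (is.null(names(cohorts)))
        stop("cohorts must be a named list", call. = FALSE)
    exprs <- lapply(cohorts, function(co) normalizeToLog2(co$expr))
    genes <- Reduce(intersect, lapply(exprs, function(e) geneIds(e)))
    riskModels <- lapply(names(exprs), function(nm) {
        v <- exprValues(exprs[[nm]])
        setNames(lapply(genes, function(g)
            tryCatch(buildRiskScore(g, v[g, ], orientation = "high_is_1",
                                    nBoot = nBoot,
                                    seed = deriveSeed(seed,
                                                      paste0(nm, "/", g))),
                     error = function(e) NULL)), genes)
    })
    names(riskModels) <- names(exprs)
    ok <- genes[vapply(genes, function(g)
        all(vapply(riskModels, function(l) !is.null(l[[g]]), logical(1))),
        logical(1))]
    dropped <- setdiff(genes, ok)
    if (!length(ok))
        stop("no gene has a stable risk score in every cohort",
             call. = FALSE)

    panels <- list(); selection <- list()
    for (st in subtypes) {
        oriented <- lapply(names(exprs), function(nm) {
            memb <- cohorts[[nm]]$truth[sampleIds(exprs[[nm]])] == st
            rms <- lapply(ok, function(g) {
                m <- riskModels[[nm]][[g]]
                if (mean(m@trainRisk[memb]) < mean(m@trainRisk[!memb]))
                    m <- flipOrientation(m)
                m
            })
            list(riskModels = setNames(rms, ok), membership = memb)
        })
        names(oriented) <- names(exprs)
        perCohort <- lapply(oriented, function(co)
            vapply(co$riskModels, function(m)
                rankRiskScore(m@trainRisk, co$membership), numeric(1)))
        ranked <- rankTriplets(perCohort)
        sel <- selectPanel(ranked, oriented,
                           candidateSizes = candidateSizes,
                           aucFloor = aucFloor)
        panels[[st]] <- sel$genes
        selection[[st]] <- sel
    }
    list(panels = panels, selection = selection, riskModels = riskModels,
         exprs = exprs, dropped = dropped)
}
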