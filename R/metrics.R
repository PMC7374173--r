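#' Area under the ROC curve
#'
#' Rank-statistic AUC: the probability that a randomly chosen positive
#' sample scores higher than a randomly chosen negative one, counting
#' ties as 1/2. Equals the trapezoidal area under the
#' (1 - specificity, sensitivity) curve traced over all thresholds.
#'
#' @param scores numeric vector of continuous scores.
#' @param labels logical (or coercible) vector: is the sample a positive?
#' @return numeric(1) AUC in [0,1].
#' @examples
#' rocAUC(c(0.8, 0.3, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
#' @export
rocAUC <- function(scores, labels) {
    labels <- as.logical(labels)
    if (length(scores) != length(labels))
        stop("scores and labels must have equal length", call. = FALSE)
    ok <- is.finite(scores) & !is.na(labels)
    scores <- scores[ok]; labels <- labels[ok]
    n1 <- sum(labels); n0 <- sum(!labels)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present to compute AUC", call. = FALSE)
    r <- rank(scores)   # midranks handle ties as 1/2
    (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiclass agreement statistics with unclassified exclusion
#'
#' Cross-tabulates predicted against true labels and reports overall
#' accuracy (with Clopper-Pearson 95\% CI), Cohen's kappa (expected
#' agreement from the row/column marginals of the retained table) and
#' one-vs-rest sensitivity and specificity per class. With
#' \code{excludeUnclassified = TRUE} (default) samples whose predicted
#' or true label equals \code{"NONE"} are dropped before anything is
#' computed, the convention used when comparing two classifiers that can
#' each abstain.
#'
#' @param predicted,truth equal-length label vectors, possibly containing
#'   \code{"NONE"}.
#' @param excludeUnclassified drop samples with \code{"NONE"} on either
#'   side before computing statistics.
#' @param classes optional class order for the table; defaults to the
#'   sorted union of retained labels.
#' @return A \linkS4class{ConfusionStats}.
#' @examples
#' p <- c("CMS1", "CMS2", "CMS2", "NONE")
#' t <- c("CMS1", "CMS2", "CMS1", "CMS2")
#' confusionStats(p, t)
#' @export
confusionStats <- function(predicted, truth, excludeUnclassified = TRUE,
                           classes = NULL) {
    predicted <- as.character(predicted)
    truth <- as.character(truth)
    if (length(predicted) != length(truth))
        stop("predicted and truth must have equal length", call. = FALSE)
    nExcluded <- 0L
    if (excludeUnclassified) {
        keep <- predicted != "NONE" & truth != "NONE"
        nExcluded <- sum(!keep)
        predicted <- predicted[keep]
        truth <- truth[keep]
    }
    if (!length(predicted))
        stop("no samples left after excluding unclassified", call. = FALSE)
    if (is.null(classes))
        classes <- sort(unique(c(predicted, truth)))
    tab <- table(factor(predicted, levels = classes),
                 factor(truth, levels = classes))
    tab <- matrix(as.integer(tab), nrow = length(classes),
                  dimnames = list(predicted = classes, truth = classes))
    n <- sum(tab)
    po <- sum(diag(tab)) / n
    pe <- sum(rowSums(tab) * colSums(tab)) / n^2
    kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
    ci <- as.numeric(binom.test(sum(diag(tab)), n)$conf.int)
    sens <- diag(tab) / colSums(tab)
    spec <- vapply(seq_along(classes), function(k) {
        tn <- sum(tab[-k, -k]); fp <- sum(tab[k, -k])
        tn / (tn + fp)
    }, numeric(1))
    new("ConfusionStats", table = tab, accuracy = po, accuracyCI = ci,
        kappa = kappa,
        sensitivity = setNames(as.numeric(sens), classes),
        specificity = setNames(spec, classes),
        nExcluded = nExcluded)
}

#' Expand a contingency table into label vectors
#'
#' Utility for feeding published predicted-by-truth count tables through
#' [confusionStats()]: repeats each (predicted, truth) pair by its cell
#' count.
#'
#' @param tab integer matrix, predicted (rows) x truth (columns), with
#'   dimnames.
#' @return list with \code{predicted} and \code{truth} character vectors.
#' @export
expandConfusionTable <- function(tab) {
    stopifnot(!is.null(rownames(tab)), !is.null(colnames(tab)))
    idx <- which(tab > 0, arr.ind = TRUE)
    reps <- tab[idx]
    list(predicted = rep(rownames(tab)[idx[, 1]], reps),
         truth = rep(colnames(tab)[idx[, 2]], reps))
}
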