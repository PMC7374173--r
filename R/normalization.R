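#' Pseudo-reference size factors for a count matrix
#'
#' Computes the two layers of size factors used to normalize targeted or
#' whole-genome RNA-seq counts without gene-length or total-read
#' normalization. The size factor of gene i is the geometric mean of its
#' raw counts over all samples (the pseudo-reference); the size factor of
#' sample j is the median over genes of the counts scaled by their gene
#' factors. Genes with a zero count in any sample are excluded from the
#' pseudo-reference and from the medians (the geometric mean would be 0),
#' but stay in the matrix and are still normalized by
#' [normalizeCounts()].
#'
#' @param counts an \linkS4class{ExpressionMatrix} with state
#'   \code{"raw_counts"} and at least two samples.
#' @return A \linkS4class{SizeFactors} object.
#' @examples
#' m <- matrix(c(4, 16, 9, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' sf <- computeSizeFactors(ExpressionMatrix(m, "raw_counts"))
#' geneFactors(sf)    # 8, 3
#' sampleFactors(sf)  # 1.75, 7/6
#' @export
computeSizeFactors <- function(counts) {
    stopifnotState(counts, "raw_counts", "computeSizeFactors")
    v <- exprValues(counts)
    if (ncol(v) < 2L)
        stop("size factors need a cohort: at least 2 samples required",
             call. = FALSE)
    retained <- rownames(v)[apply(v > 0, 1L, all)]
    if (!length(retained))
        stop("no reference genes: no gene has strictly positive counts in all samples",
             call. = FALSE)
    vr <- v[retained, , drop = FALSE]
    gf <- exp(rowMeans(log(vr)))
    scaled <- vr / gf
    sf <- apply(scaled, 2L, median)
    new("SizeFactors", geneFactors = gf, sampleFactors = sf,
        retainedGenes = retained)
}

#' Size-factor normalize a count matrix
#'
#' Normalizes raw counts with the pseudo-reference procedure of
#' [computeSizeFactors()]. By default each count is first scaled by its
#' gene's geometric mean and then divided by the sample factor (so every
#' retained gene has geometric mean 1 across samples before the
#' per-sample division); with \code{conventional = TRUE} the raw counts
#' are divided by the sample factor only, the median-of-ratios convention
#' of count-based differential-expression tools. Genes excluded from the
#' pseudo-reference because of zero counts are scaled by a
#' pseudocounted geometric mean, \code{exp(mean(log(counts + 1)))}, so
#' targeted panels keep all their genes.
#'
#' @param counts \linkS4class{ExpressionMatrix} with state
#'   \code{"raw_counts"}.
#' @param sizeFactors optional precomputed \linkS4class{SizeFactors};
#'   computed from \code{counts} when missing.
#' @param conventional logical(1); \code{FALSE} (default) divides the
#'   gene-scaled counts by the sample factor, \code{TRUE} divides the raw
#'   counts.
#' @return An \linkS4class{ExpressionMatrix} with state
#'   \code{"size_normalized"}.
#' @examples
#' m <- matrix(c(4, 16, 9, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' norm <- normalizeCounts(ExpressionMatrix(m, "raw_counts"))
#' exprValues(norm)
#' @export
normalizeCounts <- function(counts, sizeFactors = NULL,
                            conventional = FALSE) {
    stopifnotState(counts, "raw_counts", "normalizeCounts")
    if (is.null(sizeFactors))
        sizeFactors <- computeSizeFactors(counts)
    v <- exprValues(counts)
    sf <- sizeFactors@sampleFactors[colnames(v)]
    if (anyNA(sf))
        stop("size factors missing for some samples", call. = FALSE)
    if (conventional) {
        out <- sweep(v, 2L, sf, "/")
    } else {
        gfAll <- setNames(exp(rowMeans(log(v + 1))), rownames(v))
        gfAll[sizeFactors@retainedGenes] <-
            sizeFactors@geneFactors[sizeFactors@retainedGenes]
        out <- sweep(v / gfAll, 2L, sf, "/")
    }
    ExpressionMatrix(out, "size_normalized")
}

#' Log2 transform normalized expression values
#'
#' @param m \linkS4class{ExpressionMatrix} with state
#'   \code{"size_normalized"}.
#' @param pseudocount non-negative offset added before taking log2;
#'   default 1, appropriate for count-derived values (use 0 only when all
#'   values are strictly positive).
#' @return An \linkS4class{ExpressionMatrix} with state
#'   \code{"log2_normalized"}.
#' @examples
#' m <- matrix(c(4, 16, 9, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' em <- log2Transform(normalizeCounts(ExpressionMatrix(m, "raw_counts")))
#' exprState(em)
#' @export
log2Transform <- function(m, pseudocount = 1) {
    stopifnotState(m, "size_normalized", "log2Transform")
    if (length(pseudocount) != 1L || pseudocount < 0)
        stop("pseudocount must be a single number >= 0", call. = FALSE)
    v <- exprValues(m)
    bad <- which(v + pseudocount <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
        stop(sprintf("nonpositive value at gene '%s', sample '%s' with pseudocount %g",
                     rownames(v)[bad[1L, 1L]], colnames(v)[bad[1L, 2L]],
                     pseudocount), call. = FALSE)
    }
    ExpressionMatrix(log2(v + pseudocount), "log2_normalized")
}

#' Normalize counts end-to-end to the log2 scale
#'
#' Convenience wrapper: [computeSizeFactors()], [normalizeCounts()] and
#' [log2Transform()] in sequence. Matrices that are already continuous
#' (state \code{"log2_normalized"}) pass through unchanged so the same
#' code path handles counts and array-style inputs.
#'
#' @inheritParams normalizeCounts
#' @inheritParams log2Transform
#' @return \linkS4class{ExpressionMatrix} with state
#'   \code{"log2_normalized"}.
#' @export
normalizeToLog2 <- function(counts, pseudocount = 1, conventional = FALSE) {
    if (identical(exprState(counts), "log2_normalized"))
        return(counts)
    log2Transform(normalizeCounts(counts, conventional = conventional),
                  pseudocount = pseudocount)
}
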