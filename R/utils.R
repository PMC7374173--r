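# internal helpers shared across modules

# Deterministic per-key seed derivation so each gene's bootstrap stream is
# reproducible from (masterSeed, geneId) alone. Kept below 2^31 - 1.
deriveSeed <- function(seed, key) {
    h <- 0
    for (ch in utf8ToInt(as.character(key)))
        h <- (h * 31 + ch) %% 2147483647
    as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

# Index of the element of `sorted` (ascending) nearest to each x.
# Equidistant ties resolve to the smaller value.
nearestIndexSorted <- function(sorted, x) {
    n <- length(sorted)
    lo <- findInterval(x, sorted)          # 0..n, sorted[lo] <= x
    lo[lo == 0L] <- 1L
    hi <- pmin(lo + 1L, n)
    dlo <- abs(x - sorted[lo])
    dhi <- abs(sorted[hi] - x)
    ifelse(dhi < dlo, hi, lo)              # tie (dlo == dhi) -> lower value
}

# Nearest-value lookup into unsorted reference values: returns ref[k] of the
# lookup table `out` where ref value is nearest x; ties -> lower ref value.
nearestLookup <- function(refValues, out, x) {
    o <- order(refValues)
    idx <- nearestIndexSorted(refValues[o], x)
    out[o][idx]
}

stopifnotState <- function(em, state, what) {
    if (!methods::is(em, "ExpressionMatrix"))
        stop(what, " requires an ExpressionMatrix", call. = FALSE)
    if (!identical(exprState(em), state))
        stop(sprintf("%s requires state '%s' but input has state '%s'",
                     what, state, exprState(em)), call. = FALSE)
    invisible(TRUE)
}
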