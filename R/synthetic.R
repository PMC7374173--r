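#' Construct a synthetic cohort specification
#'
#' Defaults emulate one training cohort of the multi-platform colorectal
#' study domain: 400 samples with subtype mixing proportions close to
#' those observed in large CRC collections (CMS2 the largest class,
#' roughly 9\% unclassified), 10 bimodal marker genes per subtype (the
#' selected panel size) plus 20 subtype-independent noise genes, high
#' modes separated by 4 within-component standard deviations (the clean
#' bimodality panel markers are selected for), negative-binomial counts with dispersion 0.1 and
#' log-normal(0, 0.3) library-size factors so size-factor normalization
#' is genuinely exercised, and 10\% mixed-type samples carrying a second
#' subtype's marker elevation at 60\% magnitude.
#'
#' @param nSamples number of samples (>= 40).
#' @param proportions named proportions over CMS1..CMS4 and NONE.
#' @param nMarkerGenesPerSubtype,nNoiseGenes gene counts.
#' @param effectSize separation of the high mode in sd units (>= 0; 0
#'   makes markers indistinguishable from noise).
#' @param platform \code{"counts_nb"} (integer counts) or
#'   \code{"gaussian_log"} (continuous log2-scale values).
#' @param mixedFraction fraction of subtyped samples given a second
#'   subtype's elevation.
#' @param dispersion negative-binomial dispersion (platform counts_nb).
#' @param librarySdLog sd of the log-normal library-size factors.
#' @param locationShift,scaleFactor platform-specific affine transform of
#'   the log2 signal, used to differentiate cohorts of a trio.
#' @param seed integer seed.
#' @return A \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nSamples = 400L,
                       proportions = c(CMS1 = 0.17, CMS2 = 0.41,
                                       CMS3 = 0.12, CMS4 = 0.21,
                                       NONE = 0.09),
                       nMarkerGenesPerSubtype = 10L, nNoiseGenes = 20L,
                       effectSize = 4, platform = "counts_nb",
                       mixedFraction = 0.1, dispersion = 0.1,
                       librarySdLog = 0.3, locationShift = 0,
                       scaleFactor = 1, seed = 1L) {
    new("CohortSpec", nSamples = as.integer(nSamples),
        proportions = proportions,
        nMarkerGenesPerSubtype = as.integer(nMarkerGenesPerSubtype),
        nNoiseGenes = as.integer(nNoiseGenes), effectSize = effectSize,
        platform = platform, mixedFraction = mixedFraction,
        dispersion = dispersion, librarySdLog = librarySdLog,
        locationShift = locationShift, scaleFactor = scaleFactor,
        seed = as.integer(seed))
}

#' Generate one synthetic expression cohort with known subtypes
#'
#' Each subtype's marker genes are elevated by \code{effectSize}
#' within-component standard deviations in that subtype's samples and sit
#' in the low mode elsewhere; noise genes are subtype-independent.
#' Mixed-type samples additionally receive a second subtype's elevation
#' at 60\% magnitude while keeping their primary truth label. Gene
#' baselines are drawn from \code{geneSeed} so cohorts sharing it (a
#' platform trio) measure the same genes; everything sample-level flows
#' from \code{spec@seed}, making identical specs byte-identical.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param geneSeed seed for the gene-level baselines (defaults to the
#'   spec seed).
#' @return list with \code{expr} (an \linkS4class{ExpressionMatrix} in
#'   state \code{"raw_counts"} or \code{"log2_normalized"} per the
#'   platform), \code{truth} (named character labels),
#'   \code{secondary} (second subtype of mixed samples, \code{NA}
#'   otherwise) and \code{markerMap} (list subtype -> marker gene ids).
#' @export
generateCohort <- function(spec, geneSeed = spec@seed) {
    validObject(spec)
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, envir = globalenv()))

    subtypes <- .CMS_SUBTYPES
    nm <- spec@nMarkerGenesPerSubtype
    markerMap <- lapply(setNames(subtypes, subtypes), function(s)
        sprintf("%s.M%02d", s, seq_len(nm)))
    noiseGenes <- sprintf("NOISE%03d", seq_len(spec@nNoiseGenes))
    genes <- c(unlist(markerMap, use.names = FALSE), noiseGenes)

    # gene-level baselines, shared across a platform trio
    set.seed(deriveSeed(geneSeed, "gene-baselines"))
    baseMu <- setNames(runif(length(genes), 4, 8), genes)
    sigma <- 0.5   # within-component sd on the log2 scale

    set.seed(spec@seed)
    n <- spec@nSamples
    sampleId <- sprintf("S%04d", seq_len(n))
    truth <- sample(names(spec@proportions), n, replace = TRUE,
                    prob = spec@proportions)
    secondary <- rep(NA_character_, n)
    subtyped <- which(truth != "NONE")
    nMixed <- floor(spec@mixedFraction * length(subtyped))
    if (nMixed > 0) {
        mixedIdx <- sample(subtyped, nMixed)
        secondary[mixedIdx] <- vapply(truth[mixedIdx], function(s)
            sample(setdiff(subtypes, s), 1L), character(1))
    }

    shift <- matrix(0, nrow = length(genes), ncol = n,
                    dimnames = list(genes, sampleId))
    for (s in subtypes) {
        prim <- truth == s
        sec <- !is.na(secondary) & secondary == s
        if (any(prim))
            shift[markerMap[[s]], prim] <-
                shift[markerMap[[s]], prim] + spec@effectSize * sigma
        if (any(sec))
            shift[markerMap[[s]], sec] <-
                shift[markerMap[[s]], sec] + 0.6 * spec@effectSize * sigma
    }
    signal <- baseMu + shift +
        matrix(rnorm(length(genes) * n, sd = sigma),
               nrow = length(genes))
    signal <- spec@locationShift + spec@scaleFactor * signal
    dimnames(signal) <- list(genes, sampleId)

    if (spec@platform == "gaussian_log") {
        expr <- ExpressionMatrix(signal, "log2_normalized")
    } else {
        lib <- exp(rnorm(n, 0, spec@librarySdLog))
        mu <- sweep(2^signal, 2L, lib, "*")
        counts <- matrix(rnbinom(length(mu), mu = mu,
                                 size = 1 / spec@dispersion),
                         nrow = length(genes),
                         dimnames = dimnames(mu))
        expr <- ExpressionMatrix(counts, "raw_counts")
    }
    list(expr = expr, truth = setNames(truth, sampleId),
         secondary = setNames(secondary, sampleId),
         markerMap = markerMap, spec = spec)
}

#' Generate a three-platform cohort trio
#'
#' Three cohorts sharing one marker map but differing in platform and in
#' location/scale on the log2 scale, mirroring a training domain of two
#' array-style platforms and one RNA-seq platform: cohort A continuous
#' values on the base scale, cohort B continuous values shifted by +1 and
#' scaled by 1.2, cohort C negative-binomial counts. Each cohort gets its
#' own sample-level seed derived from the base spec's seed.
#'
#' @param baseSpec a \linkS4class{CohortSpec}; its platform/shift/scale
#'   fields are overridden per cohort, everything else is shared.
#' @return named list (A, B, C) of [generateCohort()] results.
#' @export
generatePlatformTrio <- function(baseSpec = cohortSpec()) {
    platforms <- list(
        A = list(platform = "gaussian_log", locationShift = 0,
                 scaleFactor = 1),
        B = list(platform = "gaussian_log", locationShift = 1,
                 scaleFactor = 1.2),
        C = list(platform = "counts_nb", locationShift = 0,
                 scaleFactor = 1))
    out <- lapply(names(platforms), function(nm) {
        p <- platforms[[nm]]
        sp <- baseSpec
        sp@platform <- p$platform
        sp@locationShift <- p$locationShift
        sp@scaleFactor <- p$scaleFactor
        sp@seed <- deriveSeed(baseSpec@seed, paste0("cohort-", nm))
        generateCohort(sp, geneSeed = baseSpec@seed)
    })
    setNames(out, names(platforms))
}
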