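# posterior probability of the high component (component 2) at x,
# computed in log space so narrow components do not underflow
.posteriorHigh <- function(x, means, sds, weights) {
    l1 <- log(weights[1]) + dnorm(x, means[1], sds[1], log = TRUE)
    l2 <- log(weights[2]) + dnorm(x, means[2], sds[2], log = TRUE)
    1 / (1 + exp(l1 - l2))
}

# Equal-posterior points between the two component means: roots of the
# quadratic log(w1 f1(x)) = log(w2 f2(x)). Returns numeric(0) when no root
# falls between the means.
.equalPosteriorPoints <- function(means, sds, weights) {
    m1 <- means[1]; m2 <- means[2]
    s1 <- sds[1]; s2 <- sds[2]
    A <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
    B <- m1 / s1^2 - m2 / s2^2
    C <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) +
        log(weights[1] * s2 / (weights[2] * s1))
    if (abs(A) < 1e-12 * max(1, abs(B))) {
        roots <- if (abs(B) > 0) -C / B else numeric(0)
    } else {
        disc <- B^2 - 4 * A * C
        roots <- if (disc < 0) numeric(0)
                 else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    }
    roots[roots >= m1 & roots <= m2]
}

# boundary between the (ascending) component means; NA when none exists
.mixtureBoundary <- function(means, sds, weights, hint = NULL) {
    roots <- .equalPosteriorPoints(means, sds, weights)
    if (!length(roots)) {
        f <- function(x) .posteriorHigh(x, means, sds, weights) - 0.5
        if (sign(f(means[1])) * sign(f(means[2])) < 0) {
            roots <- stats::uniroot(f, c(means[1], means[2]),
                                    tol = 1e-10)$root
        } else {
            return(NA_real_)
        }
    }
    target <- if (is.null(hint)) mean(means) else hint
    roots[which.min(abs(roots - target))]
}

#' Fit a two-component Gaussian mixture to one gene's expression values
#'
#' EM fit of a univariate two-component Gaussian mixture with unequal
#' variances, the dichotomization engine behind every risk score. EM is
#' run from several deterministic starts (k-means with centers at the
#' outer deciles, plus upper- and lower-tail splits that seed a minority
#' mode): unbalanced mixtures often have a spurious heavy-tail local
#' optimum with no posterior crossing between the means, and a
#' tail-split start recovers the separated solution. Each run uses
#' Aitken-accelerated stopping at relative log-likelihood tolerance
#' \code{tol} (at most \code{maxIter} iterations); among runs that admit
#' a boundary, the one with the highest log-likelihood is kept, with
#' components ordered so component 1 is the low mode. The boundary is
#' the expression value between the two component means where the
#' posterior probabilities of the components are equal; for genes with
#' irregular rather than cleanly bimodal distributions,
#' \code{boundaryHint} selects the equal-posterior point nearest a
#' previously chosen boundary, which keeps bootstrap refits anchored to
#' the same mode split. Degenerate fits (a component weight below 0.02,
#' coincident means, or no equal-posterior boundary in any run) are
#' rejected as unimodal.
#'
#' @param values numeric vector of at least 20 finite expression values
#'   with nonzero variance.
#' @param boundaryHint optional number; when several equal-posterior
#'   points exist the one nearest the hint is returned.
#' @param init optional warm start, a list with \code{means}, \code{sds},
#'   \code{weights}; bootstrap refits start from the full-data estimates
#'   instead of k-means.
#' @param maxIter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance (applied to the Aitken-projected limit).
#' @return A \linkS4class{MixtureFit}.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(100, 0), rnorm(100, 6))
#' fitMixture(x)
#' @export
fitMixture <- function(values, boundaryHint = NULL, init = NULL,
                       maxIter = 500L, tol = 1e-8) {
    values <- values[is.finite(values)]
    n <- length(values)
    if (n < 20L)
        stop("fitMixture requires at least 20 finite values", call. = FALSE)
    if (stats::var(values) == 0)
        stop("unimodal: values are constant", call. = FALSE)

    sdFloor <- 1e-3 * stats::sd(values)
    inits <- if (!is.null(init)) {
        list(list(means = init$means, sds = pmax(init$sds, sdFloor),
                  weights = init$weights))
    } else {
        .mixtureInits(values, sdFloor)
    }

    best <- NULL        # best boundary-admitting fit
    bestAny <- NULL     # best converged fit regardless of boundary
    anyConverged <- FALSE
    for (ini in inits) {
        fit <- .emRun(values, ini, sdFloor, maxIter, tol)
        if (is.null(fit)) next
        anyConverged <- TRUE
        if (is.null(bestAny) || fit$ll > bestAny$ll) bestAny <- fit
        if (min(fit$w) < 0.02 || fit$mu[2] - fit$mu[1] < sdFloor) next
        fit$boundary <- .mixtureBoundary(fit$mu, fit$sg, fit$w,
                                         hint = boundaryHint)
        if (is.na(fit$boundary)) next
        if (is.null(best) || fit$ll > best$ll) best <- fit
    }
    if (!anyConverged)
        stop("EM did not converge within ", maxIter, " iterations",
             call. = FALSE)
    if (is.null(best)) {
        if (!is.null(bestAny) && min(bestAny$w) < 0.02)
            stop("unimodal: degenerate mixture fit (component weight < 0.02)",
                 call. = FALSE)
        stop("unimodal: no equal-posterior boundary between the component means",
             call. = FALSE)
    }
    new("MixtureFit", means = best$mu, sds = best$sg, weights = best$w,
        boundary = best$boundary, logLik = best$ll, nIter = best$iter)
}

# deterministic initial partitions: outer-decile k-means plus tail splits
.mixtureInits <- function(values, sdFloor) {
    n <- length(values)
    grpFromSplit <- function(grp) {
        if (min(table(factor(grp, levels = 1:2))) < 2L) return(NULL)
        mu <- as.numeric(tapply(values, grp, mean))
        sg <- as.numeric(tapply(values, grp, stats::sd))
        sg <- pmax(ifelse(is.na(sg), sdFloor, sg), sdFloor)
        list(means = mu, sds = sg,
             weights = as.numeric(table(grp)) / n)
    }
    centers <- unname(quantile(values, c(0.1, 0.9), type = 7))
    if (diff(centers) <= 0) centers <- range(values)
    km <- tryCatch(suppressWarnings(
        kmeans(values, centers = matrix(sort(centers), ncol = 1)))$cluster,
        error = function(e) as.integer(values > median(values)) + 1L)
    inits <- list(
        grpFromSplit(km),
        grpFromSplit(as.integer(values > quantile(values, 0.85)) + 1L),
        grpFromSplit(as.integer(values > quantile(values, 0.15)) + 1L))
    Filter(Negate(is.null), inits)
}

# one EM run; returns NULL on non-convergence or an empty component,
# otherwise list(mu, sg, w, ll, iter) with components ordered ascending
.emRun <- function(values, ini, sdFloor, maxIter, tol) {
    n <- length(values)
    mu <- ini$means; sg <- ini$sds; w <- ini$weights
    ll2 <- ll1 <- NA_real_
    ll <- -Inf
    iter <- 0L
    converged <- FALSE
    while (iter < maxIter) {
        iter <- iter + 1L
        d1 <- w[1] * dnorm(values, mu[1], sg[1])
        d2 <- w[2] * dnorm(values, mu[2], sg[2])
        tot <- d1 + d2
        tot[tot == 0] <- .Machine$double.xmin
        g2 <- d2 / tot
        g1 <- 1 - g2
        newll <- sum(log(tot))
        n1 <- sum(g1); n2 <- sum(g2)
        if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
        mu <- c(sum(g1 * values) / n1, sum(g2 * values) / n2)
        sg <- pmax(sqrt(c(sum(g1 * (values - mu[1])^2) / n1,
                          sum(g2 * (values - mu[2])^2) / n2)), sdFloor)
        w <- c(n1, n2) / n
        # Aitken projection of the log-likelihood limit
        if (!is.na(ll2)) {
            a <- (newll - ll1) / (ll1 - ll2)
            if (!is.finite(a) || a >= 1) a <- 0
            proj <- ll1 + (newll - ll1) / (1 - a)
            if (abs(proj - newll) < tol * (1 + abs(newll))) {
                ll <- newll; converged <- TRUE; break
            }
        }
        ll2 <- ll1; ll1 <- newll; ll <- newll
    }
    if (!converged) return(NULL)
    o <- order(mu)
    list(mu = unname(mu[o]), sg = unname(sg[o]), w = unname(w[o]),
         ll = ll, iter = iter)
}

# Refit the mixture on B bootstrap resamples simultaneously (one EM in
# lockstep over an n x B matrix, warm-started from the full-data fit) and
# return the boundary per resample (NA = failed fit). Same model,
# iteration cap, tolerance, weight floor and boundary rule as fitMixture;
# vectorization and the shrinking active set only change the speed.
.bootstrapBoundaries <- function(X, full, maxIter = 500L, tol = 1e-8) {
    n <- nrow(X); B <- ncol(X)
    sdFloorAll <- 1e-3 * apply(X, 2L, stats::sd)

    resMu1 <- resMu2 <- resS1 <- resS2 <- resW1 <- resW2 <-
        rep(NA_real_, B)
    settled <- sdFloorAll == 0        # constant resample: fails outright
    active <- which(!settled)
    if (length(active)) {
        Xa <- X[, active, drop = FALSE]
        sdFloor <- sdFloorAll[active]
        k <- length(active)
        mu1 <- rep(full@means[1], k); mu2 <- rep(full@means[2], k)
        s1 <- pmax(rep(full@sds[1], k), sdFloor)
        s2 <- pmax(rep(full@sds[2], k), sdFloor)
        w1 <- rep(full@weights[1], k); w2 <- rep(full@weights[2], k)
        ll2 <- ll1 <- rep(NA_real_, k)
        iter <- 0L
        while (iter < maxIter && length(active)) {
            iter <- iter + 1L
            rowRep <- function(v) matrix(v, nrow = n, ncol = length(active),
                                         byrow = TRUE)
            Z1 <- (Xa - rowRep(mu1)) / rowRep(s1)
            Z2 <- (Xa - rowRep(mu2)) / rowRep(s2)
            d1 <- rowRep(w1 / s1) * exp(-Z1 * Z1 / 2)
            d2 <- rowRep(w2 / s2) * exp(-Z2 * Z2 / 2)
            tot <- d1 + d2
            tot[tot == 0] <- .Machine$double.xmin
            g2 <- d2 / tot
            newll <- colSums(log(tot)) - n * log(sqrt(2 * pi))
            n2 <- colSums(g2); n1 <- n - n2
            bad <- n1 < 1e-8 | n2 < 1e-8
            ok <- !bad
            mu1[ok] <- (colSums((1 - g2) * Xa) / n1)[ok]
            mu2[ok] <- (colSums(g2 * Xa) / n2)[ok]
            s1[ok] <- pmax(sqrt(colSums((1 - g2) *
                (Xa - rowRep(mu1))^2) / n1), sdFloor)[ok]
            s2[ok] <- pmax(sqrt(colSums(g2 *
                (Xa - rowRep(mu2))^2) / n2), sdFloor)[ok]
            w1[ok] <- (n1 / n)[ok]; w2[ok] <- (n2 / n)[ok]
            a <- (newll - ll1) / (ll1 - ll2)
            a[!is.finite(a) | a >= 1] <- 0
            proj <- ll1 + (newll - ll1) / (1 - a)
            conv <- ok & !is.na(ll2) &
                abs(proj - newll) < tol * (1 + abs(newll))
            finish <- conv | bad
            if (any(finish)) {
                idx <- active[finish]
                settled[idx] <- TRUE
                keepPar <- conv[finish]          # bad columns stay NA
                resMu1[idx[keepPar]] <- mu1[finish][keepPar]
                resMu2[idx[keepPar]] <- mu2[finish][keepPar]
                resS1[idx[keepPar]] <- s1[finish][keepPar]
                resS2[idx[keepPar]] <- s2[finish][keepPar]
                resW1[idx[keepPar]] <- w1[finish][keepPar]
                resW2[idx[keepPar]] <- w2[finish][keepPar]
                keep <- !finish
                active <- active[keep]
                Xa <- Xa[, keep, drop = FALSE]
                sdFloor <- sdFloor[keep]
                mu1 <- mu1[keep]; mu2 <- mu2[keep]
                s1 <- s1[keep]; s2 <- s2[keep]
                w1 <- w1[keep]; w2 <- w2[keep]
                ll2 <- ll1[keep]; ll1 <- newll[keep]
            } else {
                ll2 <- ll1; ll1 <- newll
            }
        }
        # columns still active hit maxIter unconverged -> failed (NA)
    }

    out <- rep(NA_real_, B)
    for (b in which(!is.na(resMu1))) {
        w <- c(resW1[b], resW2[b])
        if (min(w) < 0.02) next
        m <- c(resMu1[b], resMu2[b]); s <- c(resS1[b], resS2[b])
        o <- order(m)
        m <- m[o]; s <- s[o]; w <- w[o]
        if (m[2] - m[1] < sdFloorAll[b]) next
        bd <- .mixtureBoundary(m, s, w, hint = full@boundary)
        if (!is.na(bd)) out[b] <- bd
    }
    out
}
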