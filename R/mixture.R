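# Finite Gamma-mixture modeling of nearest-neighbor distance samples.
#
# The NND distribution is modeled as sum_{i=1..K} lambda_i Gamma(alpha_i,
# beta_i) in the shape--scale parameterization. K = 1 captures a single
# spacing population; K = 2 captures a coupled short-distance population on
# top of a background population, which is what makes an inter-channel NND
# histogram bimodal. A K = 1 fit with shape near 1 is close to exponential,
# the hallmark of complete spatial randomness of sparse points.

# Weighted Gamma MLE. Solves log(a) - digamma(a) = s with
# s = log(weighted mean x) - weighted mean log x via Newton iterations from
# the Minka closed-form start; scale follows as (weighted mean x) / a.
# s -> 0 means a degenerate (zero-variance) sample.
.weightedGammaMLE <- function(x, w = rep(1, length(x))) {
    W <- sum(w)
    mw <- sum(w * x) / W
    mlog <- sum(w * log(x)) / W
    s <- log(mw) - mlog
    if (!is.finite(s) || s < 1e-12) {
        return(NULL)  # degenerate: all mass on one value
    }
    a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
    for (it in 1:100) {
        f <- log(a) - digamma(a) - s
        fp <- 1 / a - trigamma(a)
        step <- f / fp
        aNew <- a - step
        if (!is.finite(aNew) || aNew <= 0) aNew <- a / 2
        if (abs(aNew - a) < 1e-12 * a) {
            a <- aNew
            break
        }
        a <- aNew
    }
    c(shape = a, scale = mw / a)
}

.gammaLogLik <- function(x, shape, scale) {
    sum(stats::dgamma(x, shape = shape, scale = scale, log = TRUE))
}

# Drop non-positive distances (Gamma support is (0, Inf)); returns list with
# the cleaned vector and the dropped count.
.positivePart <- function(sample) {
    x <- if (is(sample, "NNDSample")) sample@distances else as.numeric(sample)
    nDropped <- sum(x <= 0)
    if (nDropped > 0) {
        message(sprintf("dropped %d non-positive distance(s) before fitting",
                        nDropped))
    }
    list(x = x[x > 0], nDropped = as.integer(nDropped))
}

.mixtureBIC <- function(logLik, K, n) {
    -2 * logLik + (3 * K - 1) * log(n)
}

# Local maxima of the mixture density. K = 1 has the closed form
# (shape-1)*scale for shape > 1 and a boundary mode at 0 otherwise. K >= 2
# uses a dense grid scan over (0, xmax] refined by golden-section
# optimization, with maxima closer than the grid step merged.
.mixtureModesRaw <- function(weights, shapes, scales, xmax) {
    K <- length(weights)
    if (K == 1L) {
        return(if (shapes[1] > 1) (shapes[1] - 1) * scales[1] else 0)
    }
    dens <- function(x) {
        out <- numeric(length(x))
        for (k in seq_len(K)) {
            out <- out + weights[k] * stats::dgamma(x, shape = shapes[k],
                                                    scale = scales[k])
        }
        out
    }
    nGrid <- 2000L
    xs <- seq(0, xmax, length.out = nGrid)
    step <- xs[2] - xs[1]
    d <- dens(xs)
    d[1] <- dens(step * 1e-6)  # finite stand-in for the x -> 0 limit
    modes <- numeric(0)
    heights <- numeric(0)
    if (d[1] > d[2]) {  # density decreasing at the origin: boundary mode
        modes <- 0
        heights <- d[1]
    }
    for (i in 2:(nGrid - 1L)) {
        if (d[i] > d[i - 1] && d[i] > d[i + 1]) {
            opt <- stats::optimize(dens, c(xs[i - 1], xs[i + 1]),
                                   maximum = TRUE,
                                   tol = .Machine$double.eps^0.5)
            modes <- c(modes, opt$maximum)
            heights <- c(heights, opt$objective)
        }
    }
    if (!length(modes)) {
        # monotone density on the grid: boundary maximum
        modes <- xs[which.max(d)]
        heights <- max(d)
    }
    ord <- order(modes)
    modes <- modes[ord]
    heights <- heights[ord]
    keep <- rep(TRUE, length(modes))
    for (i in seq_along(modes)[-1]) {
        if (modes[i] - modes[max(which(keep[seq_len(i - 1)]))] <= step) {
            # merge: keep the taller of the pair
            j <- max(which(keep[seq_len(i - 1)]))
            if (heights[i] > heights[j]) keep[j] <- FALSE else keep[i] <- FALSE
        }
    }
    sort(modes[keep])
}

.makeFit <- function(weights, shapes, scales, logLik, n, xmax, converged,
                     nIter, trace, seed, nDropped) {
    ord <- order(shapes * scales)  # sort components by mean
    new("GammaMixtureFit",
        weights = weights[ord], shapes = shapes[ord], scales = scales[ord],
        logLik = logLik, n = as.integer(n),
        bic = .mixtureBIC(logLik, length(weights), n),
        modes = .mixtureModesRaw(weights[ord], shapes[ord], scales[ord], xmax),
        converged = converged, nIter = as.integer(nIter),
        logLikTrace = trace, seed = as.integer(seed),
        nDroppedZeros = as.integer(nDropped))
}

#' Maximum-likelihood single-Gamma fit
#'
#' Fits Gamma(shape, scale) to the strictly positive distances of an NND
#' sample by Newton iteration on the profile likelihood, starting from the
#' method-of-moments estimate. Zero distances (coincident centroids) are
#' dropped with a message before fitting.
#'
#' @param sample an [NNDSample-class] or numeric vector of distances
#'   (micrometers).
#' @param seed recorded on the fit for provenance (no randomness is used).
#' @return A [GammaMixtureFit-class] with one component.
#' @examples
#' x <- sampleNNDMixture(1, 2, 0.2, n = 2000, seed = 5)
#' fitGamma(x)
#' @export
fitGamma <- function(sample, seed = 0L) {
    pp <- .positivePart(sample)
    x <- pp$x
    if (length(x) < 5L) stop("need at least 5 strictly positive distances")
    est <- .weightedGammaMLE(x)
    if (is.null(est)) stop("degenerate sample: all distances identical")
    ll <- .gammaLogLik(x, est["shape"], est["scale"])
    .makeFit(1, unname(est["shape"]), unname(est["scale"]), ll,
             length(x), max(x), TRUE, 0L, ll, seed, pp$nDropped)
}

# Method-of-moments Gamma estimate, guarded for near-zero variance.
.momGamma <- function(x) {
    m <- mean(x)
    v <- stats::var(x)
    if (!is.finite(v) || v <= 0) v <- (m * 0.1)^2
    c(shape = m^2 / v, scale = v / m)
}

# Quantile-split initialization: method-of-moments Gamma per block, equal
# weights. Returns NULL when a block is too small.
.emInit <- function(x, K, splitProbs) {
    cuts <- stats::quantile(x, probs = splitProbs, names = FALSE)
    grp <- findInterval(x, cuts) + 1L
    shapes <- numeric(K)
    scls <- numeric(K)
    for (k in seq_len(K)) {
        xk <- x[grp == k]
        if (length(xk) < 2L) return(NULL)
        est <- .momGamma(xk)
        shapes[k] <- est["shape"]
        scls[k] <- est["scale"]
    }
    list(lambda = rep(1 / K, K), shapes = shapes, scales = scls)
}

# One EM run from given parameters. Returns NULL on component collapse.
.emRun <- function(x, K, init, maxIter, tol) {
    n <- length(x)
    lambda <- init$lambda
    shapes <- init$shapes
    scls <- init$scales
    llOld <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        lmat <- vapply(seq_len(K), function(k) {
            log(lambda[k]) + stats::dgamma(x, shape = shapes[k],
                                           scale = scls[k], log = TRUE)
        }, numeric(n))
        m <- lmat[, 1]
        for (k in seq_len(K)[-1]) m <- pmax(m, lmat[, k])
        lse <- m + log(rowSums(exp(lmat - m)))
        ll <- sum(lse)
        trace <- c(trace, ll)
        if (is.finite(llOld) &&
            abs(ll - llOld) < tol * (abs(llOld) + 1e-12)) {
            converged <- TRUE
            break
        }
        llOld <- ll
        resp <- exp(lmat - lse)
        lambda <- colMeans(resp)
        if (any(lambda < 1e-6)) return(NULL)
        for (k in seq_len(K)) {
            est <- .weightedGammaMLE(x, resp[, k])
            if (is.null(est)) return(NULL)
            shapes[k] <- est["shape"]
            scls[k] <- est["scale"]
        }
    }
    list(weights = lambda / sum(lambda), shapes = shapes, scales = scls,
         logLik = trace[length(trace)], converged = converged,
         nIter = iter, trace = trace)
}


#' Fit a K-component Gamma mixture by EM
#'
#' Expectation-maximization with exact M-steps: component weights are mean
#' responsibilities and each component is refit by weighted Gamma MLE
#' (Newton on the shape, scale in closed form). Initialization splits the
#' sample at its empirical quantiles (the median for K = 2), fits
#' method-of-moments Gammas per block, and runs \code{nRestarts} seeded
#' restarts with jittered split points; the best-likelihood run is returned.
#' A run whose component collapses (weight below 1e-6 or degenerate
#' variance) is discarded; an error is raised only if every restart
#' collapses. Iteration stops when the relative log-likelihood change drops
#' below 1e-8 (500 iterations cap).
#'
#' With K = 1 this reduces exactly to [fitGamma()].
#'
#' @param sample an [NNDSample-class] or numeric vector (micrometers).
#' @param K number of components (n >= 10 K required).
#' @param seed integer seed controlling restart jitter.
#' @param nRestarts number of EM restarts (default 5).
#' @param maxIter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return A [GammaMixtureFit-class]; components sorted by ascending mean.
#' @examples
#' x <- sampleNNDMixture(c(0.4, 0.6), c(4, 9), c(0.03, 0.0512),
#'                       n = 2000, seed = 11)
#' fitGammaMixture(x, K = 2, seed = 1)
#' @export
fitGammaMixture <- function(sample, K, seed = 1L, nRestarts = 5L,
                            maxIter = 500L, tol = 1e-8) {
    stopifnot(K >= 1L)
    pp <- .positivePart(sample)
    x <- pp$x
    if (length(x) < 10L * K && K > 1L) {
        stop(sprintf("need at least %d observations for K = %d", 10L * K, K))
    }
    if (K == 1L) {
        return(fitGamma(x, seed = seed))
    }
    # short-runs strategy: each restart gets a capped burn-in, then only the
    # best run is iterated to full convergence
    burnIn <- min(100L, maxIter)
    best <- NULL
    withSeed(seed, {
        for (r in seq_len(nRestarts)) {
            base <- seq_len(K - 1L) / K
            probs <- if (r == 1L) {
                base
            } else {
                sort(pmin(0.95, pmax(0.05,
                    base + stats::runif(K - 1L, -0.2, 0.2))))
            }
            init <- .emInit(x, K, probs)
            if (is.null(init)) next
            run <- .emRun(x, K, init, burnIn, tol)
            if (!is.null(run) &&
                (is.null(best) || run$logLik > best$logLik)) {
                best <- run
            }
        }
    })
    if (is.null(best)) {
        stop("all EM restarts collapsed; the sample may not support this K")
    }
    if (!best$converged && maxIter > burnIn) {
        cont <- .emRun(x, K, list(lambda = best$weights,
                                  shapes = best$shapes,
                                  scales = best$scales),
                       maxIter - burnIn, tol)
        if (!is.null(cont)) {
            cont$trace <- c(best$trace, cont$trace)
            cont$nIter <- best$nIter + cont$nIter
            best <- cont
        }
    }
    .makeFit(best$weights, best$shapes, best$scales, best$logLik,
             length(x), max(x), best$converged, best$nIter, best$trace,
             seed, pp$nDropped)
}

#' Select the mixture order by BIC
#'
#' Fits K = 1 .. \code{kMax} components and returns the fit minimizing the
#' Bayesian information criterion (-2 logLik + (3K - 1) log n). BIC is the
#' selection rule because the three extra parameters of each added component
#' must buy a commensurate likelihood gain.
#'
#' @param sample an [NNDSample-class] or numeric vector (micrometers).
#' @param kMax maximum component count (default 2).
#' @param seed integer seed for EM restarts.
#' @param nRestarts EM restarts per K.
#' @return The best [GammaMixtureFit-class].
#' @export
selectMixtureModel <- function(sample, kMax = 2L, seed = 1L, nRestarts = 5L) {
    fits <- list()
    for (K in seq_len(kMax)) {
        f <- tryCatch(
            fitGammaMixture(sample, K = K, seed = childSeed(seed, K),
                            nRestarts = nRestarts),
            error = function(e) NULL)
        if (!is.null(f)) fits[[length(fits) + 1L]] <- f
    }
    if (!length(fits)) stop("no mixture order could be fitted")
    fits[[which.min(vapply(fits, bic, numeric(1)))]]
}

#' Modes of a fitted mixture density
#'
#' Local maxima of the mixture density. K = 1 uses the closed form
#' (shape - 1) * scale (0 when shape <= 1, where the density peaks at the
#' origin); K >= 2 scans a 2000-point grid over [0, xmax] and refines each
#' maximum by local optimization, merging maxima closer than the grid step.
#'
#' @param fit a [GammaMixtureFit-class].
#' @param xmax upper end of the scan; defaults to the 99.99th percentile of
#'   the fitted mixture.
#' @return numeric vector of mode locations (micrometers), ascending.
#' @export
mixtureModes <- function(fit, xmax = NULL) {
    stopifnot(is(fit, "GammaMixtureFit"))
    if (is.null(xmax)) {
        xmax <- max(stats::qgamma(0.9999, shape = fit@shapes,
                                  scale = fit@scales))
    }
    .mixtureModesRaw(fit@weights, fit@shapes, fit@scales, xmax)
}

#' Mixture density function of a fit
#'
#' @param fit a [GammaMixtureFit-class].
#' @param x numeric vector of evaluation points (micrometers).
#' @return mixture density values.
#' @export
mixtureDensity <- function(fit, x) {
    out <- numeric(length(x))
    for (k in seq_along(fit@weights)) {
        out <- out + fit@weights[k] * stats::dgamma(x, shape = fit@shapes[k],
                                                    scale = fit@scales[k])
    }
    out
}

#' Distance of each component's shape from the exponential limit
#'
#' A Gamma with shape 1 is exponential; for nearest-neighbor distances of
#' sparse, completely random points the fitted shape approaches 1, so
#' |shape - 1| per component measures departure from spatial randomness. A
#' single-component fit whose shape falls inside \code{band} is flagged
#' consistent with randomly distributed clusters.
#'
#' @param fit a [GammaMixtureFit-class].
#' @param band two-sided shape band around 1 (default c(0.8, 1.2)).
#' @return list with \code{deviation} (|shape_i - 1| per component) and
#'   \code{consistentWithRandom} (logical).
#' @examples
#' f <- fitGamma(sampleNNDMixture(1, 1, 0.3, n = 3000, seed = 8))
#' randomnessIndex(f)$consistentWithRandom
#' @export
randomnessIndex <- function(fit, band = c(0.8, 1.2)) {
    stopifnot(is(fit, "GammaMixtureFit"), length(band) == 2L)
    list(deviation = abs(fit@shapes - 1),
         consistentWithRandom = length(fit@weights) == 1L &&
             fit@shapes[1] >= band[1] && fit@shapes[1] <= band[2])
}

#' Histogram with fitted mixture density overlay
#'
#' @param sample an [NNDSample-class] or numeric vector (micrometers).
#' @param fit a [GammaMixtureFit-class] for the same sample.
#' @param main plot title.
#' @param breaks histogram breaks (passed to [graphics::hist()]).
#' @return invisibly, NULL.
#' @export
plotDensityOverlay <- function(sample, fit, main = "NND density", breaks = 40) {
    x <- if (is(sample, "NNDSample")) sample@distances else as.numeric(sample)
    graphics::hist(x, breaks = breaks, freq = FALSE, main = main,
                   xlab = "nearest-neighbor distance (um)", col = "grey85",
                   border = "white")
    xs <- seq(1e-6, max(x), length.out = 512)
    graphics::lines(xs, mixtureDensity(fit, xs), col = "firebrick", lwd = 2)
    if (length(fit@modes)) {
        graphics::abline(v = fit@modes, col = "steelblue", lty = 2)
    }
    invisible(NULL)
}

#' Write a mixture fit as JSON
#'
#' Records components, log-likelihood, BIC, modes and convergence metadata.
#'
#' @param fit a [GammaMixtureFit-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMixtureFit <- function(fit, path) {
    jsonlite::write_json(list(
        weights = fit@weights, shapes = fit@shapes, scales = fit@scales,
        log_likelihood = fit@logLik, n = fit@n, bic = fit@bic,
        modes_um = fit@modes, converged = fit@converged, n_iter = fit@nIter,
        seed = fit@seed, n_dropped_zeros = fit@nDroppedZeros),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
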