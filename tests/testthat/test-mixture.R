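test_that("single-Gamma MLE recovers generating parameters", {
    x <- sampleNNDMixture(1, 2, 0.2, 50000L, seed = 51L)
    f <- fitGamma(x)
    expect_gt(shapes(f), 1.94)
    expect_lt(shapes(f), 2.06)
    expect_gt(scales(f), 0.19)
    expect_lt(scales(f), 0.21)
    # exponential data: shape within 1 +/- 0.05 at n = 10,000
    fe <- fitGamma(sampleNNDMixture(1, 1, 0.3, 10000L, seed = 52L))
    expect_lt(abs(shapes(fe) - 1), 0.05)
})

test_that("MLE log-likelihood beats the method-of-moments start", {
    for (seed in 1:10) {
        x <- distances(sampleNNDMixture(1, runif(1, 0.5, 6),
                                        runif(1, 0.05, 0.5), 500L,
                                        seed = seed))
        f <- fitGamma(x)
        m <- mean(x)
        v <- var(x)
        llMom <- sum(dgamma(x, shape = m^2 / v, scale = v / m, log = TRUE))
        expect_gte(f@logLik, llMom)
    }
})

test_that("single-Gamma MLE agrees with an independent fitter", {
    skip_if_not_installed("fitdistrplus")
    x <- distances(sampleNNDMixture(1, 3.2, 0.15, 3000L, seed = 53L))
    f <- fitGamma(x)
    ref <- fitdistrplus::fitdist(x, "gamma")
    expect_equal(shapes(f), unname(ref$estimate["shape"]), tolerance = 1e-3)
    expect_equal(scales(f), 1 / unname(ref$estimate["rate"]),
                 tolerance = 1e-3)
})

test_that("degenerate and undersized samples are rejected", {
    expect_error(fitGamma(rep(0.3, 50)), "identical")
    expect_error(fitGamma(c(0.1, 0.2, 0.3)), "at least 5")
    expect_error(fitGammaMixture(runif(15), K = 2), "at least 20")
})

test_that("zero distances are dropped with a recorded count", {
    x <- c(rep(0, 3), distances(sampleNNDMixture(1, 2, 0.2, 500L, seed = 3L)))
    expect_message(f <- fitGamma(x), "dropped 3")
    expect_equal(f@nDroppedZeros, 3L)
    expect_equal(f@n, 500L)
})

test_that("K = 1 mixture fitting reduces exactly to the direct MLE", {
    x <- distances(sampleNNDMixture(1, 2.5, 0.2, 800L, seed = 61L))
    f1 <- fitGamma(x)
    fm <- fitGammaMixture(x, K = 1L)
    expect_identical(shapes(fm), shapes(f1))
    expect_identical(scales(fm), scales(f1))
    expect_identical(fm@logLik, f1@logLik)
})

test_that("EM recovers a bimodal mixture and its log-likelihood is monotone", {
    sc <- bimodalScenario()
    for (seed in 1:5) {
        x <- sampleNNDMixture(sc$weights, sc$shapes, sc$scales, 5000L,
                              seed = seed)
        f <- fitGammaMixture(x, K = 2L, seed = seed)
        expect_true(all(diff(f@logLikTrace) > -1e-8 * abs(f@logLikTrace[-1])))
        expect_length(modes(f), 2L)
        expect_lt(max(abs(modes(f) - sc$modes)), 0.03)
        expect_equal(sum(weights(f)), 1, tolerance = 1e-9)
        expect_true(all(shapes(f) > 0) && all(scales(f) > 0))
        expect_true(f@converged)
    }
})

test_that("fitted mixtures are scale-equivariant", {
    sc <- bimodalScenario()
    x <- distances(sampleNNDMixture(sc$weights, sc$shapes, sc$scales, 2000L,
                                    seed = 71L))
    k <- 3.6
    # tight convergence so both runs reach the same optimum
    f1 <- fitGammaMixture(x, K = 2L, seed = 1L, tol = 1e-12, maxIter = 2000L)
    f2 <- fitGammaMixture(k * x, K = 2L, seed = 1L, tol = 1e-12,
                          maxIter = 2000L)
    expect_equal(weights(f2), weights(f1), tolerance = 1e-6)
    expect_equal(shapes(f2), shapes(f1), tolerance = 1e-5)
    expect_equal(scales(f2), k * scales(f1), tolerance = 1e-5)
    expect_equal(modes(f2), k * modes(f1), tolerance = 1e-4)
})

test_that("density modes match closed forms", {
    # K = 1, shape > 1: exact closed form
    x <- distances(sampleNNDMixture(1, 4, 0.1, 1000L, seed = 81L))
    f <- fitGamma(x)
    expect_equal(modes(f)[1], (shapes(f) - 1) * scales(f))
    # K = 1, shape <= 1: density maximum at the origin
    fe <- fitGamma(distances(sampleNNDMixture(1, 0.8, 0.3, 3000L,
                                              seed = 82L)))
    expect_equal(modes(fe)[1], 0)
    # far-separated narrow components: per-component closed form
    f2 <- new("GammaMixtureFit", weights = c(0.5, 0.5),
              shapes = c(100, 400), scales = c(0.001, 0.002),
              logLik = 0, n = 1L, bic = 0, modes = numeric(0),
              converged = TRUE, nIter = 0L, logLikTrace = 0, seed = 0L,
              nDroppedZeros = 0L)
    m <- mixtureModes(f2, xmax = 1.2)
    expect_length(m, 2L)
    expect_equal(m, c(99 * 0.001, 399 * 0.002), tolerance = 1.2 / 1999)
})

test_that("BIC selects the generating order", {
    sc <- bimodalScenario()
    xb <- sampleNNDMixture(sc$weights, sc$shapes, sc$scales, 3000L,
                           seed = 91L)
    expect_equal(nComponents(selectMixtureModel(xb, kMax = 2L, seed = 1L)),
                 2L)
    xu <- sampleNNDMixture(1, 2.5, 0.2, 3000L, seed = 92L)
    expect_equal(nComponents(selectMixtureModel(xu, kMax = 2L, seed = 1L)),
                 1L)
    # tiny samples fall back to K = 1 (the BIC penalty dominates)
    tiny <- sampleNNDMixture(1, 2, 0.2, 15L, seed = 93L)
    expect_equal(nComponents(selectMixtureModel(tiny, kMax = 2L, seed = 1L)),
                 1L)
})

test_that("the randomness flag tracks the exponential limit", {
    fe <- fitGamma(sampleNNDMixture(1, 1, 0.3, 5000L, seed = 94L))
    ri <- randomnessIndex(fe)
    expect_true(ri$consistentWithRandom)
    expect_lt(ri$deviation[1], 0.2)
    f3 <- fitGamma(sampleNNDMixture(1, 3, 0.2, 5000L, seed = 95L))
    expect_false(randomnessIndex(f3)$consistentWithRandom)
    # a K = 2 fit is never flagged random, whatever its shapes
    sc <- bimodalScenario()
    f2 <- fitGammaMixture(sampleNNDMixture(sc$weights, sc$shapes, sc$scales,
                                           2000L, seed = 96L),
                          K = 2L, seed = 1L)
    expect_false(randomnessIndex(f2)$consistentWithRandom)
})

test_that("fit JSON serialization captures the components", {
    x <- sampleNNDMixture(1, 2, 0.2, 500L, seed = 97L)
    f <- fitGamma(x)
    path <- tempfile(fileext = ".json")
    on.exit(unlink(path))
    writeMixtureFit(f, path)
    back <- jsonlite::read_json(path, simplifyVector = TRUE)
    expect_equal(back$shapes, shapes(f))
    expect_equal(back$bic, bic(f))
})
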