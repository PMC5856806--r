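# Independent re-computation of the three filter stages on a toy image,
# written as plain arithmetic so it cannot share bugs with the package code.
bruteFilterChain <- function(v, alpha = 1, beta = 1) {
    mu0 <- mean(v)
    sigma0 <- sqrt(mean((v - mu0)^2))
    i1 <- ifelse(v < mu0 + alpha * sigma0, v, 0)
    mu1 <- mean(i1)
    sigma1 <- sqrt(mean((i1 - mu1)^2))
    iw <- ifelse(v >= mu1 + beta * sigma1, v, 0)
    nz <- iw[iw > 0]
    list(mu0 = mu0, sigma0 = sigma0, mu1 = mu1, sigma1 = sigma1,
         muStar = if (length(nz)) mean(nz) else NA_real_,
         tauI = if (length(nz)) mu0 / mean(nz) else NA_real_,
         i1 = i1, iw = iw)
}

test_that("subthreshold image keeps pixels strictly below mu0 + alpha*sigma0", {
    st <- toyStack(c(0, 0, 0, 100))
    i1 <- voxels(subthresholdImage(st, alpha = 1))
    # mu0 = 25, sigma0 = 43.30 (population SD), criterion ~68.3:
    # three zeros kept, the 100 zeroed
    expect_equal(as.vector(i1), c(0, 0, 0, 0))
    # all-zero image stays all zero
    expect_true(all(voxels(subthresholdImage(toyStack(rep(0, 4)))) == 0))
    # alpha -> Inf keeps everything
    rnd <- toyStack(c(3, 9, 1, 7))
    expect_equal(voxels(subthresholdImage(rnd, alpha = 1e9)), voxels(rnd))
})

test_that("filter chain matches the independent brute-force on toy images", {
    toys <- list(
        c(0, 0, 0, 100),
        c(5, 5, 5, 5, 5, 5, 80, 90, 3, 2, 7, 6, 5, 4, 5, 5))
    for (v in toys) {
        d <- if (length(v) == 4L) c(1L, 2L, 2L) else c(1L, 4L, 4L)
        st <- toyStack(v, dim = d)
        ref <- bruteFilterChain(v)
        res <- imageThreshold(st)
        expect_equal(res@mu0, ref$mu0)
        expect_equal(res@sigma0, ref$sigma0)
        expect_equal(res@mu1, ref$mu1)
        expect_equal(res@sigma1, ref$sigma1)
        expect_equal(res@muStar, ref$muStar)
        expect_equal(res@tauI, ref$tauI)
        w <- workingImage(st)
        expect_equal(as.vector(voxels(w$working)), ref$iw)
    }
})

test_that("the 4-voxel toy yields tauI = 0.25 and its known intermediates", {
    res <- imageThreshold(toyStack(c(0, 0, 0, 100)))
    expect_equal(res@mu0, 25)
    expect_equal(res@sigma0, sqrt(1875))
    expect_equal(res@mu1, 0)
    expect_equal(res@sigma1, 0)
    expect_equal(res@muStar, 100)
    expect_equal(res@tauI, 0.25)
})

test_that("degenerate images are flagged rather than mis-thresholded", {
    # constant positive image: tauI = 1
    res <- imageThreshold(toyStack(rep(7, 4)))
    expect_equal(res@tauI, 1)
    # all-zero image: explicit no-signal marker
    res0 <- imageThreshold(toyStack(rep(0, 4)))
    expect_true(res0@noSignal)
    expect_true(is.na(res0@tauI))
    w0 <- workingImage(toyStack(rep(0, 4)))
    expect_true(w0$stats@noSignal)
})

test_that("tauI is invariant to intensity scaling", {
    set.seed(4)
    v <- rpois(64, 5) + c(rep(0, 60), 50, 60, 70, 80)
    t1 <- imageThreshold(toyStack(v, c(1L, 8L, 8L)))@tauI
    t2 <- imageThreshold(toyStack(3.7 * v, c(1L, 8L, 8L)))@tauI
    expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("re-masking the working image at the same cutoff is idempotent", {
    set.seed(9)
    v <- c(rpois(60, 4), 90, 95, 100, 110)
    st <- toyStack(v, c(1L, 8L, 8L))
    w <- workingImage(st)
    cutoff <- w$stats@mu1 + w$stats@sigma1
    iw <- as.vector(voxels(w$working))
    iw2 <- ifelse(iw >= cutoff, iw, 0)
    expect_equal(iw2, iw)
})

test_that("global threshold is the minimum, order- and duplication-invariant", {
    expect_equal(globalThreshold(c(0.4, 0.7, 0.55)), 0.4)
    expect_equal(globalThreshold(0.62), 0.62)
    expect_equal(globalThreshold(c(0.55, 0.4, 0.7)), 0.4)
    expect_equal(globalThreshold(c(0.4, 0.7, 0.55, 0.4)), 0.4)
    expect_error(globalThreshold(numeric(0)), "no image")
    # ThresholdResult input: no-signal planes do not contribute
    sig <- imageThreshold(toyStack(c(0, 0, 0, 100)))
    none <- imageThreshold(toyStack(rep(0, 4)))
    expect_equal(globalThreshold(list(sig, none)), 0.25)
    expect_equal(globalThreshold(list(sig, sig, none)), 0.25)
})

test_that("per-plane thresholds cover every plane with 0-based indices", {
    spec <- separatedSpec(2, nClusters = 6L)
    st <- renderStack(generateScene(spec), spec, "A")
    res <- stackThresholds(st)
    expect_length(res, 20L)
    expect_equal(vapply(res, function(r) r@planeIndex, integer(1)), 0:19)
})

test_that("well-separated noise-free spots are each detected once, accurately", {
    hits <- 0L
    worst <- 0
    for (seed in 1:10) {
        spec <- separatedSpec(seed)
        sim <- simulateStacks(spec)
        cs <- detectClusters(sim$A, channelThreshold(sim$A))
        if (length(cs) == spec@nClustersA) hits <- hits + 1L
        err <- bruteNND(centroids(cs), centersA(sim$scene))
        worst <- max(worst, max(err))
    }
    expect_gte(hits, 9L)
    expect_lt(worst, 0.5 * 0.04)  # half a lateral voxel, in um
})

test_that("empty and elongated inputs label sensibly", {
    # all-zero stack: no clusters, not an error
    z <- toyStack(rep(0, 4 * 16), c(4L, 2L, 8L))
    expect_length(detectClusters(z, tau = 0.5), 0L)
    # a spot spanning several Z planes is one cluster under 26-connectivity
    v <- array(0, c(8L, 9L, 9L))
    v[2:7, 5, 5] <- 100
    v[2:7, 5, 6] <- 60
    st <- ImageStack(v, c(0.18, 0.04, 0.04), "elong")
    cs <- detectClusters(st, tau = 0.5)
    expect_length(cs, 1L)
    expect_equal(voxelCounts(cs), 12L)
})

test_that("raising tau never increases the suprathreshold voxel count", {
    spec <- couplingSpec(3, 0.5)
    spec@gridShape <- c(8L, 64L, 64L)
    spec@nClustersA <- 20L
    spec@nClustersB <- 0L
    sim <- simulateStacks(spec)
    v <- voxels(sim$A)
    counts <- vapply(seq(0.05, 0.95, by = 0.1),
                     function(tau) sum(v >= tau * max(v) & v > 0), numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("centroids respect anisotropic voxel size", {
    mkSpot <- function(z) {
        v <- array(0, c(8L, 8L, 8L))
        v[z, 4:5, 4] <- 50
        ImageStack(v, c(0.18, 0.04, 0.04), "spot")
    }
    c1 <- centroids(detectClusters(mkSpot(3L), tau = 0.5))
    c2 <- centroids(detectClusters(mkSpot(4L), tau = 0.5))
    expect_equal(c2[1, 1] - c1[1, 1], 0.18)
    expect_equal(c2[1, 2:3], c1[1, 2:3])
})

test_that("minVoxels filters singleton components", {
    v <- array(0, c(4L, 8L, 8L))
    v[2, 2, 2] <- 100           # singleton
    v[3, 6, 6] <- 100           # pair
    v[3, 6, 7] <- 90
    st <- ImageStack(v, c(0.18, 0.04, 0.04), "mv")
    cs2 <- detectClusters(st, tau = 0.5, FilterParams(minVoxels = 2L))
    expect_length(cs2, 1L)
    cs1 <- detectClusters(st, tau = 0.5, FilterParams(minVoxels = 1L))
    expect_length(cs1, 2L)
})

test_that("cluster CSV round trip preserves the table", {
    spec <- separatedSpec(7, nClusters = 5L)
    sim <- simulateStacks(spec)
    cs <- detectClusters(sim$A, channelThreshold(sim$A))
    path <- tempfile(fileext = ".csv")
    on.exit(unlink(path))
    writeClusterSet(cs, path)
    df <- read.csv(path)
    expect_equal(nrow(df), length(cs))
    expect_equal(df$z_um, centroids(cs)[, 1])
    expect_equal(df$voxels, voxelCounts(cs))
})

test_that("subthreshold statistics can optionally exclude zeros", {
    v <- c(0, 0, 0, 10, 12, 14, 0, 0, 200)
    st <- toyStack(v, c(1L, 3L, 3L))
    withZeros <- workingImage(st, FilterParams())$stats
    nonzeroOnly <- workingImage(st, FilterParams(statsOnNonzeroOnly = TRUE))$stats
    i1 <- ifelse(v < mean(v) + sqrt(mean((v - mean(v))^2)), v, 0)
    expect_equal(withZeros@mu1, mean(i1))
    expect_equal(nonzeroOnly@mu1, mean(i1[i1 > 0]))
    expect_gt(nonzeroOnly@mu1, withZeros@mu1)
})

test_that("label volumes round-trip through TIFF", {
    v <- array(0, c(2L, 6L, 6L))
    v[1, 2, 2:3] <- 100
    v[2, 5, 4:5] <- 80
    st <- ImageStack(v, c(0.18, 0.04, 0.04), "lab")
    cs <- detectClusters(st, tau = 0.5)
    path <- tempfile(fileext = ".tif")
    on.exit(unlink(c(path, sub("\\.tif$", ".json", path))))
    writeLabelVolume(cs, path)
    back <- readImageStack(path)
    expect_equal(voxels(back), labelsVolume(cs) * 1.0)
})
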