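test_that("empty scene and validation edge cases behave", {
    spec <- SceneSpec(nClustersA = 0L, nClustersB = 0L, seed = 1)
    scene <- generateScene(spec)
    expect_equal(nrow(centersA(scene)), 0L)
    expect_equal(nrow(centersB(scene)), 0L)
    expect_error(SceneSpec(coupledFraction = 1.5), "coupledFraction")
    expect_error(SceneSpec(voxelSize = c(0.18, 0, 0.04)), "voxelSize")
    # coupled placement needs at least one A cluster
    expect_error(generateScene(SceneSpec(nClustersA = 0L, nClustersB = 4L,
                                         coupledFraction = 1, seed = 1)),
                 "no clusters")
})

test_that("scene generation is a pure function of spec and seed", {
    spec <- SceneSpec(nClustersA = 30L, nClustersB = 30L,
                      coupledFraction = 0.4, seed = 99L)
    s1 <- generateScene(spec)
    s2 <- generateScene(spec)
    expect_identical(centersA(s1), centersA(s2))
    expect_identical(centersB(s1), centersB(s2))
    st1 <- renderStack(s1, spec, "B")
    st2 <- renderStack(s2, spec, "B")
    expect_identical(voxels(st1), voxels(st2))
})

test_that("all centers respect bounds and coupled counts match the spec", {
    for (seed in 1:5) {
        spec <- SceneSpec(nClustersA = 40L, nClustersB = 37L,
                          coupledFraction = 0.5, seed = seed)
        scene <- generateScene(spec)
        bounds <- spec@gridShape * spec@voxelSize
        expect_true(all(centersA(scene) >= 0) &&
                    all(t(centersA(scene)) <= bounds))
        expect_true(all(centersB(scene) >= 0) &&
                    all(t(centersB(scene)) <= bounds))
        expect_equal(sum(coupledFlags(scene)), round(0.5 * 37))
    }
})

test_that("fully coupled scenes put B at coupled distances from A", {
    # independent mini-generator for the same placement law, used as the
    # distributional oracle for the mean nearest-A distance
    spec <- SceneSpec(gridShape = c(20L, 160L, 160L), nClustersA = 50L,
                      nClustersB = 50L, coupledFraction = 1,
                      coupledShape = 4, coupledScale = 0.025, seed = 5L)
    scene <- generateScene(spec)
    got <- bruteNND(centersB(scene), centersA(scene))

    set.seed(1234)
    bounds <- spec@gridShape * spec@voxelSize
    ref <- replicate(40, {
        A <- cbind(runif(50, 0, bounds[1]), runif(50, 0, bounds[2]),
                   runif(50, 0, bounds[3]))
        B <- t(vapply(seq_len(50), function(i) {
            repeat {
                a <- A[sample.int(50, 1), ]
                d <- rgamma(1, shape = 4, scale = 0.025)
                u <- rnorm(3)
                p <- a + d * u / sqrt(sum(u^2))
                if (all(p >= 0) && all(p <= bounds)) return(p)
            }
        }, numeric(3)))
        mean(bruteNND(B, A))
    })
    se <- sd(ref) + sd(got) / sqrt(length(got))
    expect_lt(abs(mean(got) - mean(ref)), 3 * se)
})

test_that("uncoupled B points are uniform (octant chi-square)", {
    for (seed in 1:20) {
        spec <- SceneSpec(nClustersA = 10L, nClustersB = 160L,
                          coupledFraction = 0, seed = seed)
        scene <- generateScene(spec)
        b <- centersB(scene)
        mid <- spec@gridShape * spec@voxelSize / 2
        octant <- 1L + (b[, 1] > mid[1]) + 2L * (b[, 2] > mid[2]) +
                  4L * (b[, 3] > mid[3])
        counts <- tabulate(octant, nbins = 8L)
        p <- suppressWarnings(chisq.test(counts)$p.value)
        expect_gt(p, 0.001)
    }
})

test_that("rendered spot integrates to the nominal intensity", {
    spec <- SceneSpec(gridShape = c(24L, 64L, 64L), nClustersA = 1L,
                      nClustersB = 0L, noiseModel = "none",
                      backgroundLevel = 0, marginUm = 1, seed = 3L)
    scene <- generateScene(spec)
    st <- renderStack(scene, spec, "A")
    expect_lt(abs(sum(voxels(st)) / spec@intensityPerCluster - 1), 0.01)
    expect_true(all(voxels(st) >= 0))
})

test_that("rendering an empty scene with zero background is all zero", {
    spec <- SceneSpec(nClustersA = 0L, nClustersB = 0L, noiseModel = "none",
                      backgroundLevel = 0, gridShape = c(4L, 16L, 16L),
                      seed = 1L)
    st <- renderStack(generateScene(spec), spec, "A")
    expect_true(all(voxels(st) == 0))
})

test_that("rendering is linear: union scene equals voxelwise sum", {
    spec <- SceneSpec(gridShape = c(10L, 48L, 48L), nClustersA = 4L,
                      nClustersB = 5L, noiseModel = "none",
                      backgroundLevel = 0, seed = 8L)
    scene <- generateScene(spec)
    stA <- renderStack(scene, spec, "A")
    stB <- renderStack(scene, spec, "B")
    union <- new("GroundTruthScene",
                 centersA = rbind(centersA(scene), centersB(scene)),
                 centersB = matrix(numeric(0), ncol = 3),
                 coupled = logical(0), partner = integer(0),
                 bounds = scene@bounds)
    stU <- renderStack(union, spec, "A")
    expect_equal(voxels(stU), voxels(stA) + voxels(stB), tolerance = 1e-12)
})

test_that("mixture sampling honors weights, errors, and determinism", {
    expect_error(sampleNNDMixture(c(0.5, 0.6), c(1, 1), c(1, 1), 10),
                 "sum to 1")
    theta <- 0.3
    n <- 4000L
    s <- sampleNNDMixture(1, 1, theta, n, seed = 21L)
    expect_lt(abs(mean(distances(s)) - theta), 3 * theta / sqrt(n))
    s5a <- sampleNNDMixture(c(0.5, 0.5), c(2, 5), c(0.1, 0.2), 5, seed = 2L)
    s5b <- sampleNNDMixture(c(0.5, 0.5), c(2, 5), c(0.1, 0.2), 5, seed = 2L)
    expect_identical(distances(s5a), distances(s5b))
})

test_that("a half-and-half mixture with modes 0.09 and 0.41 um is bimodal", {
    sc <- bimodalScenario()
    s <- sampleNNDMixture(c(0.5, 0.5), sc$shapes, sc$scales, 10000L,
                          seed = 31L)
    dens <- density(distances(s))
    y <- dens$y
    peaks <- which(diff(sign(diff(y))) == -2) + 1L
    peaks <- peaks[y[peaks] > 0.05 * max(y)]
    expect_gte(length(peaks), 2L)
})

test_that("shape-1 single-component draws match exponential quantiles", {
    for (seed in 1:20) {
        s <- sampleNNDMixture(1, 1, 0.25, 2000L, seed = seed)
        p <- suppressWarnings(
            ks.test(distances(s), "pexp", rate = 1 / 0.25)$p.value)
        expect_gt(p, 0.001)
    }
})

test_that("TIFF round-trip preserves the stack and its sidecar", {
    spec <- SceneSpec(gridShape = c(6L, 24L, 24L), nClustersA = 3L,
                      nClustersB = 0L, seed = 12L)
    sim <- simulateStacks(spec)
    path <- tempfile(fileext = ".tif")
    on.exit(unlink(c(path, sub("\\.tif$", ".json", path))))
    writeImageStack(sim$A, path, extra = list(seed = 12L))
    back <- readImageStack(path)
    expect_equal(voxels(back), round(voxels(sim$A)))
    expect_equal(voxelSize(back), voxelSize(sim$A))
    meta <- readStackSidecar(path)
    expect_equal(meta$seed, 12L)
    expect_equal(meta$n_planes, 6L)
})

test_that("gammaFromMode returns a Gamma with the requested mode and sd", {
    g <- gammaFromMode(0.09, 0.05)
    expect_equal(unname((g["shape"] - 1) * g["scale"]), 0.09)
    expect_equal(unname(sqrt(g["shape"]) * g["scale"]), 0.05)
})
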