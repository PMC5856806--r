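# Shared fixture builders. Everything is generated in code; no files.

# Tiny stack from a vector of intensities, default 1 Z plane.
toyStack <- function(values, dim = c(1L, 2L, 2L),
                     voxelSize = c(0.18, 0.04, 0.04), channel = "toy") {
    ImageStack(array(values, dim), voxelSize, channel)
}

# Noise-free scene with well-separated spots, for detection fidelity checks.
separatedSpec <- function(seed, nClusters = 10L) {
    SceneSpec(gridShape = c(20L, 128L, 128L), nClustersA = nClusters,
              nClustersB = 0L, noiseModel = "none", backgroundLevel = 0,
              minSeparationUm = 1.2, marginUm = 0.5, seed = seed)
}

# The study conditions for end-to-end coupling detection: ~0.6 um
# same-channel spacing, half of channel B coupled at Gamma(4, 0.025)
# distances (mean 0.1 um), photon-limited Poisson detection.
couplingSpec <- function(seed, coupledFraction) {
    SceneSpec(gridShape = c(20L, 160L, 160L), nClustersA = 110L,
              nClustersB = 110L, coupledFraction = coupledFraction,
              seed = seed)
}

# Brute-force O(n^2) nearest-neighbor oracle, written independently of the
# package's grid search: per query, the minimum over the full column-ordered
# distance scan.
bruteNND <- function(from, to, excludeSelf = FALSE) {
    vapply(seq_len(nrow(from)), function(i) {
        d <- sqrt(colSums((t(to) - from[i, ])^2))
        if (excludeSelf) d <- d[-i]
        min(d)
    }, numeric(1))
}

# The two-component scenario with density modes at 0.09 and 0.41 um.
bimodalScenario <- function() {
    g1 <- gammaFromMode(0.09, 0.05)
    g2 <- gammaFromMode(0.41, 0.15)
    list(weights = c(0.4, 0.6),
         shapes = c(g1["shape"], g2["shape"]),
         scales = c(g1["scale"], g2["scale"]),
         modes = c(0.09, 0.41))
}
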