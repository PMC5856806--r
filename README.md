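# punctacoloc

Spatial-coupling analysis of punctate channel clusters in two-channel
super-resolution Z-stacks.

Ion channels such as SK2, Ca<sub>v</sub>1.2 and RyR2 appear in STED-class
fluorescence volumes as compact puncta. Whether two such populations form
functional microdomains — one channel's clusters sitting preferentially
near the other's — is a spatial-statistics question. `punctacoloc` answers
it from a pair of 3D image stacks on a common voxel grid, for researchers
quantifying channel organization in cardiomyocytes and similar systems.

## What it computes

1. **Cluster detection.** A spark-detection-style filter chain estimates a
   per-image threshold: the subthreshold image `I1` keeps raw pixels below
   `mu0 + alpha*sigma0`; the working image masks the raw image at
   `mu1 + beta*sigma1`; the per-image threshold is `tau_i = mu0 / mu*`
   (mean of the raw image over mean of the non-zero working pixels); the
   channel threshold `tau` is the minimum `tau_i` over all images (default
   `alpha = beta = 1`). 3D connected components above the cutoff become
   clusters with intensity-weighted centroids in micrometers.
2. **Nearest-neighbor distances.** `NND(X-Y)` is, for each cluster of X,
   the 3D distance to the nearest cluster of Y — asymmetric in X and Y —
   reported for the whole volume and stratified into surface vs interior
   Z-regions.
3. **Finite Gamma mixtures.** NND samples are modeled as
   `sum_i lambda_i * Gamma(alpha_i, beta_i)` (shape–scale, weights summing
   to 1), fit by EM with weighted Gamma MLE M-steps, order selected by BIC,
   density modes extracted, and each component's shape compared with 1 (the
   exponential limit) as a randomness check. A bimodal inter-channel NND —
   two mixture components — is the signature of spatial coupling.
4. **Colocalization.** Presence-based conditional probabilities
   `P(B|A) = overlap voxels / A voxels` (exact integer identity
   `P(B|A)*nA = P(A|B)*nB = overlap`) and the Pearson correlation of voxel
   intensities, per region.

A synthetic-scene generator (`SceneSpec`, `generateScene`, `renderStack`)
renders ground-truth two-channel scenes through an anisotropic Gaussian PSF
with Poisson noise, so the full pipeline is testable without microscopy
data.

## Worked example

```r
library(punctacoloc)

cfg <- RunConfig(scene = SceneSpec(coupledFraction = 0.5), seed = 1)
rep <- runPipeline(cfg)

rep@clusters
#>   channel n_clusters median_voxels
#> 1       A        140            35
#> 2       B        129            10

nndTable(rep, region = "all")
#>     To
#> From A               B
#>    A "0.73 +/- 0.23" "0.50 +/- 0.41"
#>    B "0.44 +/- 0.37" "0.74 +/- 0.31"

modes(rep@fits[["B-A"]])
#> [1] 0.05625931 0.63140449

subset(rep@coloc, region == "all")
#>   region prob_b_given_a prob_a_given_b overlap_voxels  n_a  n_b pearson_r
#> 1    all      0.1046693      0.3306699            538 5140 1627 0.2969138
```

Reading: most of both channels' 150 seeded clusters are detected (a few
merge, and the coupled channel's coincident spots raise its threshold, so
its clusters are tighter); B-to-A nearest-neighbor distances average
0.44 µm against a same-channel spacing of ~0.73 µm; the fitted
two-component mixture puts density modes at 0.056 and 0.631 µm — the short
mode is the coupled subpopulation placed at mean 0.1 µm — and 33% of
B-positive voxels are also A-positive. On an uncoupled control scene the
same pipeline selects a single component and a conditional probability
below 1%.

Each stage is also available on its own (`channelThreshold`,
`detectClusters`, `nearestNeighborDistances`, `fitGammaMixture`,
`selectMixtureModel`, `conditionalProbability`, `pearsonCorrelation`), and
stacks round-trip to multi-page 16-bit TIFF with JSON sidecars
(`writeImageStack` / `readImageStack`).

See `vignettes/punctacoloc-methods.Rmd` for the model, parameter meanings,
numerical choices, and known limitations (no edge correction, no labeling
artifacts in the simulator, exponential-null-only randomness check).

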