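---
title: "Quantifying spatial coupling of punctate channel clusters in Z-stacks"
author: "punctacoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial coupling of punctate channel clusters in Z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctacoloc)
```

## The problem

Membrane ion channels such as the small-conductance Ca^2+^-activated K^+^
channel (SK2), the L-type Ca^2+^ channel (Ca~v~1.2) and the ryanodine
receptor (RyR2) appear in super-resolution fluorescence images as punctate
clusters. Whether two such populations form functional microdomains is a
question about their spatial relationship: are the clusters of one channel
placed near the clusters of the other more often than chance predicts?

`punctacoloc` answers this from two-channel 3D image stacks (one Z-stack
per channel on an identical voxel grid, e.g. 48 planes at a 0.18 µm Z-step)
with four linked analyses:

1. **Cluster detection** — spark-detection-style iterative thresholding and
   3D connected-component labeling yield cluster centroids in physical
   micrometers.
2. **Nearest-neighbor distances (NND)** — for each cluster of channel X,
   the distance to the nearest cluster of channel Y. NND(X–Y) is asymmetric
   in X and Y: it has one entry per X cluster, and the two directions
   generally differ whenever the populations differ in number.
3. **Finite Gamma mixtures** — the NND distribution is modeled as
   $\sum_{i=1}^{K}\lambda_i\,\Gamma(\alpha_i,\beta_i)$ (shape–scale
   parameterization, $\sum\lambda_i = 1$). One component describes a single
   spacing population; two components — selected by BIC — describe a coupled
   short-distance population on top of a background population, which is
   what makes an inter-channel NND histogram bimodal. The modes of the
   fitted density are the observable summary of that structure.
4. **Presence-based colocalization** — voxelwise conditional probabilities
   $P(B\mid A) = \sum(\mathbb{1}_A \mathbb{1}_B) / \sum \mathbb{1}_A$ on
   filtered presence masks, plus the Pearson correlation of raw voxel
   intensities.

Because real acquisitions of this kind are rarely deposited, the package
carries a first-class synthetic-scene generator with known ground truth, so
every stage can be exercised end to end and its operating characteristics
measured.

## The filter chain

Cluster detection starts from a per-image threshold estimated the way
Ca^2+^-spark detectors estimate theirs. For each image (each Z plane is one
image):

1. the *subthreshold image* $I_1$ keeps the pixels of the raw image $I_0$
   with intensity strictly below $\mu_0 + \alpha\sigma_0$, where $\mu_0$
   and $\sigma_0$ are the mean and SD of $I_0$;
2. the *working image* $I_w = I_0 \cdot M_1$ uses the binary mask
   $M_1 = (I_0 \ge \mu_1 + \beta\sigma_1)$, with $\mu_1, \sigma_1$ the mean
   and SD of $I_1$;
3. the per-image threshold is the ratio $\tau_i = \mu_0 / \mu^*$, where
   $\mu^*$ is the mean of the non-zero pixels of $I_w$.

The channel's global threshold $\tau$ is the minimum $\tau_i$ over all
contributing images; images whose working image is empty are flagged
"no signal" and do not contribute. Defaults are $\alpha = \beta = 1$.

Two conventions deserve explicit statement because they are easy to get
silently wrong:

* **Image SDs are population SDs** (divide by $n$): the statistics are
  moments of a fixed pixel grid, not estimates from a sample. On the
  four-pixel toy $\{0,0,0,100\}$ this gives $\sigma_0 = 43.3$, and the full
  chain gives $\tau_i = 0.25$, which the test suite re-derives with
  independent arithmetic. NND summaries, by contrast, use the sample SD
  ($n-1$), as they describe a sample of distances.
* **$\mu_1, \sigma_1$ include the zeros of $I_1$**, because $I_1$ is
  defined as an image rather than a pixel subset. The
  `statsOnNonzeroOnly` switch in `FilterParams` provides the alternative
  reading.

### Applying τ

$\tau$ is a ratio of means, typically well below 1, so turning it into an
intensity cutoff needs a rule. The default is percent-of-maximum semantics:
binarize at $\tau \cdot \max(I_0)$, matching how commercial "% intensity"
object finders apply relative thresholds. The alternative
(`tauMode = "tau_times_mu_star"`) cuts at $\tau \cdot \mu^*$ of the stack's
working image.

The percent-of-maximum rule has a failure mode worth knowing: the cutoff
scales with the brightest voxel, so if two spots nearly coincide the stack
maximum roughly doubles and the cutoff can climb past the peak of a typical
single spot. With spots whose per-channel contrast gives $\tau \approx 0.2$
this leaves a comfortable safety margin (even a doubled maximum keeps the
cutoff below single-spot peaks); with dim spots ($\tau \approx 0.5$) it does
not. This drove the generator's default spot intensity (below). In the
scenes this package simulates, the $\tau\cdot\mu^*$ alternative places the
cutoff near the background mean and is therefore not the default.

Detected components under the configured connectivity (default 26) smaller
than `minVoxels` (default 2) are discarded as shot noise. Centroids are
intensity-weighted and reported in micrometers with voxel centers at
$(\text{index} + 0.5)\cdot\text{voxelSize}$, 0-based, so the Z plane of a
centroid is $\lfloor z/\text{voxelSize}_z\rfloor$.

## NND and stratification

Distances are centroid-to-centroid 3D Euclidean distances with anisotropic
voxel-to-micrometer conversion; an edge-to-edge option
(`type = "edge"`) measures between nearest suprathreshold voxels instead,
for workflows where cluster extent matters. For same-population NND the
zero self-match is excluded. The accelerated implementation is a
uniform-grid shell search whose result is exactly (not approximately) the
brute-force answer; the test suite verifies elementwise equality against an
independent $O(n^2)$ scan.

Clusters are assigned to the *surface* region when the Z plane containing
their centroid is listed in `surfacePlanes` (by default the first three
planes: the surface plane and the planes 0.18 and 0.36 µm deeper at the
default Z-step), otherwise to the *interior*; the partition is exhaustive
and disjoint. No edge correction is applied to distances near the volume
boundary — a known bias shared with the analysis this package reimplements.

## Mixture fitting choices

* **Estimation** — EM with exact M-steps: weights are mean
  responsibilities; each component is refit by weighted Gamma maximum
  likelihood, with the shape found by Newton iteration on
  $\log\alpha - \psi(\alpha) = \log\overline{x}_w - \overline{\log x}_w$
  from Minka's closed-form start and the scale in closed form. Single-Gamma
  fits use the same solver with unit weights, so `fitGammaMixture(x, K = 1)`
  reduces *exactly* to `fitGamma(x)`.
* **Initialization and restarts** — the sample is split at its empirical
  quantiles (the median for $K = 2$), a method-of-moments Gamma is fit per
  block, and `nRestarts = 5` seeded restarts jitter the split points. Each
  restart runs a capped 100-iteration burn-in; only the best run continues
  to convergence (relative log-likelihood change $< 10^{-8}$, 500-iteration
  cap). The log-likelihood trace is stored on the fit and is non-decreasing.
* **Degeneracies** — zero distances are dropped (with a recorded count)
  because the Gamma support is $(0,\infty)$; a component whose weight falls
  below $10^{-6}$ or whose weighted sample degenerates collapses that
  restart; all-identical samples are an error.
* **Model selection** — BIC with $3K - 1$ free parameters. The choice is
  deliberate: the three extra parameters of a second component must buy a
  commensurate likelihood gain, which keeps one-component samples from
  being over-split at the sample sizes cluster counts produce
  ($n \approx 100$–$5000$).
* **Modes** — for $K = 1$ the closed form $(\alpha - 1)\beta$ (0 when
  $\alpha \le 1$, where the density peaks at the origin); for $K \ge 2$ a
  2000-point grid scan refined by local optimization, with maxima closer
  than the grid step merged.

### The exponential randomness check

A Gamma with shape 1 is exponential, and the fitted shape's distance from 1
is reported per component (`randomnessIndex`), with a single-component fit
flagged "consistent with random" when its shape lies in a configurable band
(default $[0.8, 1.2]$). One caveat from point-process theory: the NND of
*genuinely uniform points in 3D* is not exponential but Weibull-like (a
Gamma fit to it lands at shape 5–7), so a completely random 3D scene will
not be flagged random by this criterion — only spacings that are truly
exponential will. The flag is therefore a check against the exponential
null it states, not a general CSR test; Ripley-type statistics are out of
scope here.

## What the generator emulates — and what it does not

`SceneSpec` describes a two-channel ground-truth scene and its rendering.
Channel A centers are uniform in the physical volume; a configurable
fraction of channel B centers is *coupled* — placed at a
Gamma($\alpha, \beta$)-distributed distance (default mean 0.1 µm, SD
0.05 µm) in a uniformly random 3D direction from a uniformly chosen A
center — and the rest are uniform. The intended partner is recorded, but a
coupled B center may land nearer to a different A center, as in a physical
scene. Rendering integrates an anisotropic Gaussian PSF exactly over each
voxel, adds a constant background, and applies Poisson noise to signal plus
background (photon-limited detection); Gaussian and noise-free models are
available.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `gridShape` | 48 × 128 × 128 | 48 Z planes, the targeted acquisition depth |
| `voxelSize` | (0.18, 0.04, 0.04) µm | 0.18 µm Z-step; lateral sampling below the lateral PSF width |
| `psfSigma` | (0.20, 0.05, 0.05) µm | STED resolves laterally far better than axially; fixture values, not measured PSFs |
| `nClustersA/B` | 150 | same-channel spacing ≈ 0.6 µm, the scale observed for these channel types |
| `coupledFraction` | 0.5 | half the B population coupled; the regime of interest |
| `coupledShape/Scale` | 4, 0.025 | coupled distances with mean 0.1 µm, below the first observable mode |
| `intensityPerCluster` | 10000 photons | bright antibody-labeled clusters; keeps $\tau \approx 0.2$ so the percent-of-maximum cutoff tolerates coincident spots |
| `backgroundLevel` | 5 | photon-limited background |
| `minSeparationUm` | 0 (off) | rejection-sampled minimum spacing, for constructing well-separated validation scenes |
| `marginUm` | 0 | border-truncated spots allowed by default — truncation is a real detection stressor |

The generator does **not** emulate antibody labeling stochasticity or
blinking, spectral bleed-through, drift, or spatially varying background.
Passing tests on these scenes therefore show that the chain of estimators
is correct and well-calibrated under photon-limited imaging of compact
spots — not that it is robust to every artifact real microscopy produces.

## Operating characteristics

The test suite measures, at fixed seeds:

* detection on noise-free, well-separated scenes recovers the seeded
  cluster count in ≥ 95% of 50 scenes with centroid error below half a
  lateral voxel;
* two-Gamma samples parameterized to have density modes at 0.09 and
  0.41 µm ($n = 5000$) are recovered with both modes within ±0.03 µm in
  ≥ 18 of 20 seeds;
* BIC selects $K = 2$ on bimodal and $K = 1$ on unimodal samples
  ($n = 3000$) in ≥ 18 of 20 seeds each, and exponential spacing
  ($n = 10^4$) yields $K = 1$ with shape in $[0.95, 1.05]$;
* end to end — simulate, render, detect, NND, fit, colocalize — coupled
  scenes (110 clusters per channel, 20 × 160 × 160 voxels, half of B
  coupled at mean 0.1 µm) select $K = 2$ and uncoupled scenes $K = 1$ in
  ≥ 18 of 20 seeds, and the coupled member of every matched pair shows the
  higher conditional probability (paired sign test, $p < 0.01$).

These problem sizes are the package's validation conditions, chosen to
match the cluster densities and spacings the analysis is meant for.

## A worked run

```{r, eval = FALSE}
cfg <- RunConfig(scene = SceneSpec(coupledFraction = 0.5), seed = 1)
rep <- runPipeline(cfg)
rep
nndTable(rep, region = "all")
modes(rep@fits[["B-A"]])
```

The report carries the four ordered NND summaries per region (the From\\To
table mirrors how such results are conventionally tabulated), the mixture
fit per inter-channel direction, and per-region conditional probabilities
and Pearson correlation. `runPipeline` is deterministic given
(config, seed): rerunning writes a byte-identical `report.json`.

## Interface note

The package is an in-R analysis toolkit: the exported functions and
`runPipeline()` are the interface, and all file exchange uses open formats
(multi-page 16-bit TIFF with JSON sidecars, CSV tables, JSON reports), so
the stages can be scripted individually where a shell workflow is needed.

## Known limitations

* No deconvolution, background subtraction or drift correction; stacks are
  assumed pre-registered on one voxel grid.
* No edge correction for NND near the volume boundary.
* Cluster-level association uses centroids by default; sub-cluster
  (single-molecule) structure is out of scope.
* The randomness flag tests the exponential null only (see above).
* Pearson correlation is computed on raw intensities by default; whether to
  filter first is exposed as an option because either convention is
  defensible.
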