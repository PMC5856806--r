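#' @import methods
NULL

.checkVoxelSize <- function(vs) {
    if (length(vs) != 3L || !is.numeric(vs) || any(!is.finite(vs)) ||
        any(vs <= 0)) {
        return("voxelSize must be 3 strictly positive finite values (z, y, x)")
    }
    NULL
}

#' ImageStack: a 3D fluorescence intensity volume
#'
#' Container for a single-channel Z-stack: a 3D array of nonnegative voxel
#' intensities indexed (z, y, x) together with the physical voxel size in
#' micrometers per axis.
#'
#' @slot voxels 3D numeric array of nonnegative finite intensities, dimension
#'   order (z, y, x).
#' @slot voxelSize numeric(3), micrometers per voxel along (z, y, x).
#' @slot channelName single character label, e.g. \code{"SK2"}.
#'
#' @seealso [ImageStack()] for the constructor, [detectClusters()],
#'   [renderStack()]
#' @exportClass ImageStack
setClass("ImageStack",
    representation(
        voxels = "array",
        voxelSize = "numeric",
        channelName = "character"
    )
)

setValidity("ImageStack", function(object) {
    msgs <- character()
    if (length(dim(object@voxels)) != 3L) {
        msgs <- c(msgs, "voxels must be a 3D array (z, y, x)")
    }
    if (any(!is.finite(object@voxels))) {
        msgs <- c(msgs, "all voxel intensities must be finite")
    } else if (any(object@voxels < 0)) {
        msgs <- c(msgs, "all voxel intensities must be >= 0")
    }
    msgs <- c(msgs, .checkVoxelSize(object@voxelSize))
    if (length(object@channelName) != 1L) {
        msgs <- c(msgs, "channelName must be a single string")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct an ImageStack
#'
#' @param voxels 3D numeric array, dimension order (z, y, x), nonnegative.
#' @param voxelSize numeric(3) voxel size in micrometers (z, y, x).
#' @param channelName channel label.
#' @return An [ImageStack-class] object.
#' @examples
#' st <- ImageStack(array(0, c(4, 8, 8)), c(0.18, 0.04, 0.04), "SK2")
#' dim(voxels(st))
#' @export
ImageStack <- function(voxels, voxelSize, channelName = "channel") {
    new("ImageStack", voxels = voxels, voxelSize = as.numeric(voxelSize),
        channelName = channelName)
}

#' FilterParams: parameters of the spark-detection filter chain
#'
#' @slot alpha multiplier on the raw-image SD in the subthreshold criterion
#'   mu0 + alpha * sigma0.
#' @slot beta multiplier on the subthreshold-image SD in the mask level
#'   mu1 + beta * sigma1.
#' @slot connectivity 3D neighborhood for connected components: 6, 18 or 26.
#' @slot minVoxels minimum cluster size in voxels (smaller components are
#'   discarded as shot noise).
#' @slot statsOnNonzeroOnly if TRUE, mu1/sigma1 are computed over the
#'   non-zero pixels of the subthreshold image only (alternative reading);
#'   default FALSE computes them over the whole image including zeros.
#' @slot tauMode how the global threshold tau is applied when binarizing:
#'   \code{"fraction_of_max"} thresholds at tau * max intensity of the stack
#'   (percent-of-maximum semantics); \code{"tau_times_mu_star"} thresholds at
#'   tau * mu* of the stack's working image.
#' @seealso [FilterParams()]
#' @exportClass FilterParams
setClass("FilterParams",
    representation(
        alpha = "numeric",
        beta = "numeric",
        connectivity = "integer",
        minVoxels = "integer",
        statsOnNonzeroOnly = "logical",
        tauMode = "character"
    )
)

setValidity("FilterParams", function(object) {
    msgs <- character()
    if (!is.finite(object@alpha) || !is.finite(object@beta)) {
        msgs <- c(msgs, "alpha and beta must be finite")
    }
    if (!object@connectivity %in% c(6L, 18L, 26L)) {
        msgs <- c(msgs, "connectivity must be 6, 18 or 26")
    }
    if (object@minVoxels < 1L) {
        msgs <- c(msgs, "minVoxels must be >= 1")
    }
    if (!object@tauMode %in% c("fraction_of_max", "tau_times_mu_star")) {
        msgs <- c(msgs, "tauMode must be 'fraction_of_max' or 'tau_times_mu_star'")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct FilterParams
#'
#' Defaults follow the published analysis: alpha = beta = 1, 26-connectivity,
#' clusters of at least 2 voxels.
#'
#' @param alpha,beta SD multipliers of the two filter stages.
#' @param connectivity 6, 18 or 26.
#' @param minVoxels minimum cluster size in voxels.
#' @param statsOnNonzeroOnly see [FilterParams-class].
#' @param tauMode see [FilterParams-class].
#' @return A [FilterParams-class] object.
#' @export
FilterParams <- function(alpha = 1, beta = 1, connectivity = 26L,
                         minVoxels = 2L, statsOnNonzeroOnly = FALSE,
                         tauMode = "fraction_of_max") {
    new("FilterParams", alpha = alpha, beta = beta,
        connectivity = as.integer(connectivity),
        minVoxels = as.integer(minVoxels),
        statsOnNonzeroOnly = statsOnNonzeroOnly, tauMode = tauMode)
}

#' ThresholdResult: statistics of the filter chain for one image
#'
#' Records the intermediates of the three-stage spark-detection threshold
#' estimation on a single image (typically one Z plane): raw mean/SD, the
#' subthreshold image's mean/SD, the mean of the non-zero working-image
#' pixels, and the per-image threshold ratio tauI = mu0 / muStar. SDs are
#' population SDs (divide by n), matching how image statistics are defined
#' on a fixed pixel grid.
#'
#' @slot mu0,sigma0 mean and SD of the raw image.
#' @slot mu1,sigma1 mean and SD of the subthreshold image.
#' @slot muStar mean of the non-zero pixels of the working image (NA when the
#'   working image is empty).
#' @slot tauI per-image threshold ratio mu0 / muStar (NA when no signal).
#' @slot noSignal TRUE when the working image has no non-zero pixel, so tauI
#'   is undefined for this image.
#' @slot planeIndex 0-based Z plane index this result refers to, or NA when
#'   computed on a whole stack.
#' @exportClass ThresholdResult
setClass("ThresholdResult",
    representation(
        mu0 = "numeric", sigma0 = "numeric",
        mu1 = "numeric", sigma1 = "numeric",
        muStar = "numeric", tauI = "numeric",
        noSignal = "logical", planeIndex = "integer"
    )
)

#' ClusterSet: labeled 3D connected regions of one channel
#'
#' Result of 3D cluster detection: per-cluster intensity-weighted centroids
#' in physical micrometers, voxel counts and integrated intensities, plus the
#' integer label volume (label 0 = background). Voxel centers sit at
#' (index + 0.5) * voxelSize with 0-based indices, so a centroid's Z plane is
#' \code{floor(z / voxelSize[1])}.
#'
#' @slot centroids n x 3 numeric matrix of (z, y, x) centroids in micrometers.
#' @slot voxelCounts integer voxels per cluster.
#' @slot totalIntensity summed raw intensity per cluster.
#' @slot clusterIds integer label of each row in \code{labelsVolume}.
#' @slot labelsVolume integer 3D label array (possibly empty for subsets that
#'   dropped it).
#' @slot channelName channel label.
#' @slot voxelSize numeric(3) micrometers per voxel (z, y, x).
#' @seealso [detectClusters()], [stratifyByRegion()],
#'   [nearestNeighborDistances()]
#' @exportClass ClusterSet
setClass("ClusterSet",
    representation(
        centroids = "matrix",
        voxelCounts = "integer",
        totalIntensity = "numeric",
        clusterIds = "integer",
        labelsVolume = "array",
        channelName = "character",
        voxelSize = "numeric"
    )
)

setValidity("ClusterSet", function(object) {
    msgs <- character()
    n <- nrow(object@centroids)
    if (ncol(object@centroids) != 3L && n > 0L) {
        msgs <- c(msgs, "centroids must have 3 columns (z, y, x)")
    }
    if (length(object@voxelCounts) != n || length(object@totalIntensity) != n ||
        length(object@clusterIds) != n) {
        msgs <- c(msgs, "per-cluster slots must have one entry per centroid")
    }
    msgs <- c(msgs, .checkVoxelSize(object@voxelSize))
    if (length(msgs)) msgs else TRUE
})

#' NNDSample: nearest-neighbor distances from one population to another
#'
#' For each cluster of the source channel, the 3D Euclidean distance in
#' micrometers to the nearest cluster of the target channel. The measure is
#' asymmetric: NND(A-B) has one entry per A cluster, NND(B-A) one per B
#' cluster, and the two generally differ.
#'
#' @slot distances numeric vector of nonnegative distances (micrometers).
#' @slot fromChannel,toChannel channel labels.
#' @slot region one of "all", "surface", "interior".
#' @slot nFrom,nTo source and target cluster counts.
#' @seealso [nearestNeighborDistances()], [fitGammaMixture()]
#' @exportClass NNDSample
setClass("NNDSample",
    representation(
        distances = "numeric",
        fromChannel = "character",
        toChannel = "character",
        region = "character",
        nFrom = "integer",
        nTo = "integer"
    )
)

setValidity("NNDSample", function(object) {
    msgs <- character()
    if (any(object@distances < 0) || any(!is.finite(object@distances))) {
        msgs <- c(msgs, "distances must be finite and >= 0")
    }
    if (object@nTo >= 1L && length(object@distances) != object@nFrom) {
        msgs <- c(msgs, "one distance per source cluster is required")
    }
    if (!object@region %in% c("all", "surface", "interior")) {
        msgs <- c(msgs, "region must be 'all', 'surface' or 'interior'")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct an NNDSample from raw distances
#'
#' Mostly useful for feeding externally computed or simulated distances into
#' the mixture-fitting stage; pipeline users get NNDSample objects from
#' [nearestNeighborDistances()].
#'
#' @param distances numeric vector of nonnegative distances in micrometers.
#' @param fromChannel,toChannel channel labels.
#' @param region "all", "surface" or "interior".
#' @param nFrom,nTo source/target cluster counts; default to
#'   \code{length(distances)} and \code{NA}-free sensible values.
#' @return An [NNDSample-class] object.
#' @export
NNDSample <- function(distances, fromChannel = "A", toChannel = "B",
                      region = "all", nFrom = length(distances),
                      nTo = length(distances)) {
    new("NNDSample", distances = as.numeric(distances),
        fromChannel = fromChannel, toChannel = toChannel, region = region,
        nFrom = as.integer(nFrom), nTo = as.integer(nTo))
}

#' GammaMixtureFit: a fitted finite Gamma mixture
#'
#' A K-component Gamma mixture sum_i lambda_i * Gamma(alpha_i, beta_i) in the
#' shape--scale parameterization (component mean = shape * scale), with fit
#' diagnostics and the locations of the density's local maxima (modes).
#'
#' @slot weights mixing weights lambda_i, summing to 1.
#' @slot shapes,scales per-component shape alpha_i and scale beta_i, all > 0.
#' @slot logLik maximized log-likelihood.
#' @slot n number of observations used in the fit.
#' @slot bic Bayesian information criterion, -2 logLik + p log n with
#'   p = 3K - 1 free parameters.
#' @slot modes density local maxima in micrometers, sorted ascending.
#' @slot converged TRUE when the EM relative log-likelihood change fell below
#'   tolerance before the iteration cap.
#' @slot nIter EM iterations of the returned (best) run; 0 for direct K=1 MLE.
#' @slot logLikTrace per-iteration log-likelihood of the returned run.
#' @slot seed seed used for restart initialization jitter.
#' @slot nDroppedZeros count of zero distances dropped before fitting (Gamma
#'   support is strictly positive).
#' @seealso [fitGamma()], [fitGammaMixture()], [selectMixtureModel()],
#'   [mixtureModes()], [randomnessIndex()]
#' @exportClass GammaMixtureFit
setClass("GammaMixtureFit",
    representation(
        weights = "numeric",
        shapes = "numeric",
        scales = "numeric",
        logLik = "numeric",
        n = "integer",
        bic = "numeric",
        modes = "numeric",
        converged = "logical",
        nIter = "integer",
        logLikTrace = "numeric",
        seed = "integer",
        nDroppedZeros = "integer"
    )
)

setValidity("GammaMixtureFit", function(object) {
    msgs <- character()
    K <- length(object@weights)
    if (length(object@shapes) != K || length(object@scales) != K) {
        msgs <- c(msgs, "weights, shapes, scales must have equal length")
    }
    if (abs(sum(object@weights) - 1) > 1e-9) {
        msgs <- c(msgs, "weights must sum to 1 (within 1e-9)")
    }
    if (any(object@weights < 0) || any(object@weights > 1)) {
        msgs <- c(msgs, "weights must lie in [0, 1]")
    }
    if (any(object@shapes <= 0) || any(object@scales <= 0)) {
        msgs <- c(msgs, "shapes and scales must be strictly positive")
    }
    if (is.unsorted(object@modes)) {
        msgs <- c(msgs, "modes must be sorted ascending")
    }
    if (length(msgs)) msgs else TRUE
})

#' PresenceMask: voxelwise binary signal-presence grid
#'
#' A binary volume marking where a channel's signal is present after the
#' spark-detection filter: 1 where the voxel survives thresholding, 0
#' otherwise. Presence is voxelwise (no minimum-size filtering), as the
#' conditional-probability definition sums per-voxel indicators.
#'
#' @slot mask logical 3D array.
#' @slot channelName channel label.
#' @seealso [presenceMask()], [conditionalProbability()]
#' @exportClass PresenceMask
setClass("PresenceMask",
    representation(mask = "array", channelName = "character")
)

setValidity("PresenceMask", function(object) {
    msgs <- character()
    if (length(dim(object@mask)) != 3L || !is.logical(object@mask)) {
        msgs <- c(msgs, "mask must be a logical 3D array")
    }
    if (length(msgs)) msgs else TRUE
})

#' ColocResult: conditional-probability and Pearson colocalization
#'
#' Presence-based conditional probabilities P(B|A) = overlap / nA and
#' P(A|B) = overlap / nB (exact integer identity
#' P(B|A) * nA = P(A|B) * nB = overlap), plus the Pearson correlation of the
#' two channels' voxel intensities over the analyzed region. An undefined
#' probability (empty conditioning mask) is NA with the matching
#' \code{definedA}/\code{definedB} flag FALSE, never reported as 0.
#'
#' @slot probBgivenA,probAgivenB conditional probabilities in [0, 1] or NA.
#' @slot overlapCount,nA,nB voxel counts.
#' @slot definedA,definedB FALSE when the corresponding conditioning mask was
#'   empty.
#' @slot pearsonR Pearson correlation in [-1, 1], NA when undefined.
#' @slot region "all", "surface" or "interior".
#' @slot channelA,channelB channel labels.
#' @seealso [conditionalProbability()], [pearsonCorrelation()]
#' @exportClass ColocResult
setClass("ColocResult",
    representation(
        probBgivenA = "numeric", probAgivenB = "numeric",
        overlapCount = "integer", nA = "integer", nB = "integer",
        definedA = "logical", definedB = "logical",
        pearsonR = "numeric", region = "character",
        channelA = "character", channelB = "character"
    )
)

setValidity("ColocResult", function(object) {
    msgs <- character()
    for (p in c(object@probBgivenA, object@probAgivenB)) {
        if (!is.na(p) && (p < 0 || p > 1)) {
            msgs <- c(msgs, "probabilities must lie in [0, 1]")
        }
    }
    if (!is.na(object@pearsonR) &&
        (object@pearsonR < -1 - 1e-12 || object@pearsonR > 1 + 1e-12)) {
        msgs <- c(msgs, "pearsonR must lie in [-1, 1]")
    }
    if (length(msgs)) msgs else TRUE
})

#' SceneSpec: parameters of a synthetic two-channel scene
#'
#' Declarative description of a ground-truth scene: the voxel grid and
#' physical voxel size, how many clusters each channel carries, which
#' fraction of channel-B clusters is coupled (placed at a Gamma-distributed
#' short distance from a random channel-A cluster), and how the scene is
#' rendered (total spot intensity, anisotropic Gaussian PSF sigma, noise
#' model, background). Identical spec + seed reproduces the scene and stacks
#' bit for bit.
#'
#' @slot gridShape integer(3) voxel counts (nz, ny, nx).
#' @slot voxelSize numeric(3) micrometers per voxel (z, y, x).
#' @slot nClustersA,nClustersB cluster counts per channel.
#' @slot coupledFraction fraction of B clusters coupled to A, in [0, 1].
#' @slot coupledShape,coupledScale shape and scale of the Gamma law of
#'   coupled pair distances (micrometers; mean = shape * scale).
#' @slot intensityPerCluster total integrated photons per rendered spot.
#' @slot psfSigma numeric(3) Gaussian PSF SD per axis (z, y, x) in
#'   micrometers.
#' @slot noiseModel "poisson", "gaussian" or "none".
#' @slot noiseSigma SD of the Gaussian noise model (ignored otherwise).
#' @slot backgroundLevel constant offset intensity added before noise.
#' @slot marginUm border band (micrometers) excluded from cluster placement;
#'   0 allows border-truncated spots.
#' @slot minSeparationUm minimum pairwise center distance enforced by
#'   rejection (0 disables; use to build well-separated scenes).
#' @slot seed integer seed; all outputs are pure functions of (spec, seed).
#' @seealso [SceneSpec()], [generateScene()], [renderStack()]
#' @exportClass SceneSpec
setClass("SceneSpec",
    representation(
        gridShape = "integer",
        voxelSize = "numeric",
        nClustersA = "integer",
        nClustersB = "integer",
        coupledFraction = "numeric",
        coupledShape = "numeric",
        coupledScale = "numeric",
        intensityPerCluster = "numeric",
        psfSigma = "numeric",
        noiseModel = "character",
        noiseSigma = "numeric",
        backgroundLevel = "numeric",
        marginUm = "numeric",
        minSeparationUm = "numeric",
        seed = "integer"
    )
)

setValidity("SceneSpec", function(object) {
    msgs <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L)) {
        msgs <- c(msgs, "gridShape must be 3 positive voxel counts (nz, ny, nx)")
    }
    msgs <- c(msgs, .checkVoxelSize(object@voxelSize))
    if (object@nClustersA < 0L || object@nClustersB < 0L) {
        msgs <- c(msgs, "cluster counts must be >= 0")
    }
    if (object@coupledFraction < 0 || object@coupledFraction > 1) {
        msgs <- c(msgs, "coupledFraction must lie in [0, 1]")
    }
    if (object@coupledShape <= 0 || object@coupledScale <= 0) {
        msgs <- c(msgs, "coupled distance Gamma shape and scale must be > 0")
    }
    if (length(object@psfSigma) != 3L || any(object@psfSigma <= 0)) {
        msgs <- c(msgs, "psfSigma must be 3 positive values (z, y, x)")
    }
    if (!object@noiseModel %in% c("poisson", "gaussian", "none")) {
        msgs <- c(msgs, "noiseModel must be 'poisson', 'gaussian' or 'none'")
    }
    if (object@marginUm < 0 || object@minSeparationUm < 0) {
        msgs <- c(msgs, "marginUm and minSeparationUm must be >= 0")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a SceneSpec
#'
#' Defaults describe the acquisition geometry the pipeline targets (48 Z
#' planes at a 0.18 um Z-step, fine lateral sampling) with fixture rendering
#' choices typical of photon-limited STED detection: anisotropic PSF sigma
#' (0.20, 0.05, 0.05) um, Poisson noise on signal plus background.
#'
#' @param gridShape integer(3) voxel counts (nz, ny, nx).
#' @param voxelSize numeric(3) micrometers per voxel (z, y, x).
#' @param nClustersA,nClustersB cluster counts.
#' @param coupledFraction fraction of B clusters coupled to A.
#' @param coupledShape,coupledScale Gamma law of coupled distances
#'   (defaults: mean 0.1 um, SD 0.05 um).
#' @param intensityPerCluster total photons per spot.
#' @param psfSigma numeric(3) PSF SD (z, y, x) um.
#' @param noiseModel "poisson", "gaussian" or "none".
#' @param noiseSigma Gaussian noise SD.
#' @param backgroundLevel background offset.
#' @param marginUm placement-free border band, um.
#' @param minSeparationUm minimum pairwise center distance, um (0 = off).
#' @param seed integer seed.
#' @return A [SceneSpec-class] object.
#' @examples
#' spec <- SceneSpec(nClustersA = 20, nClustersB = 20, seed = 1)
#' scene <- generateScene(spec)
#' nrow(centersB(scene))
#' @export
SceneSpec <- function(gridShape = c(48L, 128L, 128L),
                      voxelSize = c(0.18, 0.04, 0.04),
                      nClustersA = 150L, nClustersB = 150L,
                      coupledFraction = 0.5,
                      coupledShape = 4, coupledScale = 0.025,
                      intensityPerCluster = 10000,
                      psfSigma = c(0.20, 0.05, 0.05),
                      noiseModel = "poisson", noiseSigma = 1,
                      backgroundLevel = 5,
                      marginUm = 0, minSeparationUm = 0,
                      seed = 1L) {
    new("SceneSpec",
        gridShape = as.integer(gridShape), voxelSize = as.numeric(voxelSize),
        nClustersA = as.integer(nClustersA),
        nClustersB = as.integer(nClustersB),
        coupledFraction = coupledFraction,
        coupledShape = coupledShape, coupledScale = coupledScale,
        intensityPerCluster = intensityPerCluster,
        psfSigma = as.numeric(psfSigma),
        noiseModel = noiseModel, noiseSigma = noiseSigma,
        backgroundLevel = backgroundLevel,
        marginUm = marginUm, minSeparationUm = minSeparationUm,
        seed = as.integer(seed))
}

#' GroundTruthScene: known cluster centers of a synthetic scene
#'
#' @slot centersA,centersB n x 3 matrices of (z, y, x) centers in
#'   micrometers, inside the physical bounds gridShape * voxelSize.
#' @slot coupled logical per B cluster: placed at a coupled distance from an
#'   A cluster (TRUE) or uniformly at random (FALSE).
#' @slot partner intended A partner index per B cluster (NA for uncoupled);
#'   a coupled B may still fall nearer to a different A, as in a physical
#'   scene.
#' @slot bounds numeric(3) physical extent (z, y, x) in micrometers.
#' @seealso [generateScene()]
#' @exportClass GroundTruthScene
setClass("GroundTruthScene",
    representation(
        centersA = "matrix",
        centersB = "matrix",
        coupled = "logical",
        partner = "integer",
        bounds = "numeric"
    )
)

setValidity("GroundTruthScene", function(object) {
    msgs <- character()
    inb <- function(m) {
        nrow(m) == 0L || (all(m >= 0) && all(t(m) <= object@bounds + 1e-12))
    }
    if (!inb(object@centersA) || !inb(object@centersB)) {
        msgs <- c(msgs, "all centers must lie inside the physical bounds")
    }
    if (length(object@coupled) != nrow(object@centersB) ||
        length(object@partner) != nrow(object@centersB)) {
        msgs <- c(msgs, "coupled/partner must have one entry per B center")
    }
    if (length(msgs)) msgs else TRUE
})

#' RunConfig: configuration of a full pipeline run
#'
#' @slot scene a [SceneSpec-class] describing the synthetic input (or the
#'   scene used to document a run on real stacks).
#' @slot filter a [FilterParams-class].
#' @slot surfacePlanes integer 0-based Z plane indices forming the surface
#'   region; all other planes are interior.
#' @slot kMax maximum mixture components tried during model selection.
#' @slot nRestarts EM restarts per mixture fit.
#' @slot seed master seed, fanned out to per-stage child seeds.
#' @slot outputDir directory for report and intermediates (character(0) to
#'   keep everything in memory).
#' @seealso [RunConfig()], [runPipeline()]
#' @exportClass RunConfig
setClass("RunConfig",
    representation(
        scene = "SceneSpec",
        filter = "FilterParams",
        surfacePlanes = "integer",
        kMax = "integer",
        nRestarts = "integer",
        seed = "integer",
        outputDir = "character"
    )
)

setValidity("RunConfig", function(object) {
    msgs <- character()
    if (object@kMax < 1L) msgs <- c(msgs, "kMax must be >= 1")
    if (object@nRestarts < 1L) msgs <- c(msgs, "nRestarts must be >= 1")
    if (any(object@surfacePlanes < 0L)) {
        msgs <- c(msgs, "surfacePlanes are 0-based and must be >= 0")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a RunConfig
#'
#' @param scene a [SceneSpec-class].
#' @param filter a [FilterParams-class].
#' @param surfacePlanes 0-based surface Z plane indices (default the first
#'   three planes: the surface plane plus the planes 0.18 and 0.36 um deeper
#'   at the default Z-step).
#' @param kMax maximum mixture components (default 2).
#' @param nRestarts EM restarts (default 5).
#' @param seed master seed.
#' @param outputDir optional output directory.
#' @return A [RunConfig-class] object.
#' @export
RunConfig <- function(scene = SceneSpec(), filter = FilterParams(),
                      surfacePlanes = 0:2, kMax = 2L, nRestarts = 5L,
                      seed = 1L, outputDir = character(0)) {
    new("RunConfig", scene = scene, filter = filter,
        surfacePlanes = as.integer(surfacePlanes), kMax = as.integer(kMax),
        nRestarts = as.integer(nRestarts), seed = as.integer(seed),
        outputDir = outputDir)
}

#' RunReport: results of a full pipeline run
#'
#' @slot clusters per-channel cluster summary (data.frame).
#' @slot thresholds per-channel global threshold tau (data.frame).
#' @slot nnd all NND mean/SD/n summaries: four ordered channel pairs times
#'   regions (data.frame).
#' @slot fits named list of [GammaMixtureFit-class] for the inter-channel
#'   NND samples.
#' @slot coloc per-region colocalization summary (data.frame).
#' @slot config the [RunConfig-class] that produced the report.
#' @slot version package version string.
#' @slot seed master seed.
#' @seealso [runPipeline()], [nndTable()]
#' @exportClass RunReport
setClass("RunReport",
    representation(
        clusters = "data.frame",
        thresholds = "data.frame",
        nnd = "data.frame",
        fits = "list",
        coloc = "data.frame",
        config = "RunConfig",
        version = "character",
        seed = "integer"
    )
)
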