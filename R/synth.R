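#' Generate a ground-truth two-channel scene
#'
#' Places \code{nClustersA} channel-A cluster centers uniformly in the
#' physical volume, then places channel-B centers in two sub-populations:
#' \code{round(coupledFraction * nClustersB)} coupled centers, each at a
#' distance drawn from the coupled Gamma law in a uniformly random 3D
#' direction from a uniformly chosen A center, and the remainder uniformly at
#' random. A placement that falls outside the allowed volume (or violates the
#' same-channel minimum separation, when enabled) is re-drawn up to 100
#' times; persistent failure raises an error naming the offending cluster.
#'
#' A coupled B center may end up nearer to a different A center than its
#' intended partner; the partner is recorded but no exclusion is applied, as
#' in a physical scene.
#'
#' @param spec a [SceneSpec-class].
#' @return A [GroundTruthScene-class].
#' @examples
#' scene <- generateScene(SceneSpec(nClustersA = 10, nClustersB = 10,
#'                                  seed = 7))
#' sum(coupledFlags(scene))
#' @export
generateScene <- function(spec) {
    stopifnot(is(spec, "SceneSpec"))
    validObject(spec)
    bounds <- spec@gridShape * spec@voxelSize
    lo <- rep(spec@marginUm, 3)
    hi <- bounds - spec@marginUm
    if (any(hi <= lo) && (spec@nClustersA > 0L || spec@nClustersB > 0L)) {
        stop("marginUm leaves no placement volume")
    }
    maxRetries <- 100L

    withSeed(childSeed(spec@seed, 1L), {
        placeUniform <- function(n, existing, channel) {
            pts <- matrix(numeric(0), ncol = 3)
            for (i in seq_len(n)) {
                ok <- FALSE
                for (try in seq_len(maxRetries)) {
                    p <- lo + stats::runif(3) * (hi - lo)
                    if (spec@minSeparationUm > 0 && nrow(existing)) {
                        dmin <- min(sqrt(colSums((t(existing) - p)^2)))
                        if (dmin < spec@minSeparationUm) next
                    }
                    ok <- TRUE
                    break
                }
                if (!ok) {
                    stop(sprintf(
                        "placement failed after %d retries for cluster %d of channel %s",
                        maxRetries, i, channel))
                }
                pts <- rbind(pts, p)
                existing <- rbind(existing, p)
            }
            pts
        }

        cA <- placeUniform(spec@nClustersA, matrix(numeric(0), ncol = 3), "A")

        nB <- spec@nClustersB
        nCoupled <- as.integer(round(spec@coupledFraction * nB))
        if (nCoupled > 0L && spec@nClustersA == 0L) {
            stop("coupled B clusters requested but channel A has no clusters")
        }
        cB <- matrix(numeric(0), ncol = 3)
        coupled <- logical(0)
        partner <- integer(0)
        for (i in seq_len(nCoupled)) {
            ok <- FALSE
            for (try in seq_len(maxRetries)) {
                a <- sample.int(spec@nClustersA, 1L)
                d <- stats::rgamma(1L, shape = spec@coupledShape,
                                   scale = spec@coupledScale)
                p <- cA[a, ] + d * as.vector(runifDirections(1L))
                if (any(p < lo) || any(p > hi)) next
                if (spec@minSeparationUm > 0 && nrow(cB)) {
                    if (min(sqrt(colSums((t(cB) - p)^2))) <
                        spec@minSeparationUm) next
                }
                ok <- TRUE
                break
            }
            if (!ok) {
                stop(sprintf(
                    "placement failed after %d retries for coupled cluster %d of channel B",
                    maxRetries, i))
            }
            cB <- rbind(cB, p)
            coupled <- c(coupled, TRUE)
            partner <- c(partner, a)
        }
        if (nB > nCoupled) {
            cB <- rbind(cB, placeUniform(nB - nCoupled, cB, "B"))
            coupled <- c(coupled, rep(FALSE, nB - nCoupled))
            partner <- c(partner, rep(NA_integer_, nB - nCoupled))
        }
        dimnames(cA) <- dimnames(cB) <- NULL
        new("GroundTruthScene", centersA = cA, centersB = cB,
            coupled = coupled, partner = partner, bounds = bounds)
    })
}

# Integral of a 1D Gaussian over each voxel along one axis, restricted to a
# +/- 6 sigma window. Returns indices (1-based) and weights.
.axisWeights <- function(center, sigma, vs, n) {
    i0 <- max(1L, floor((center - 6 * sigma) / vs) + 1L)
    i1 <- min(n, ceiling((center + 6 * sigma) / vs))
    if (i1 < i0) return(list(idx = integer(0), w = numeric(0)))
    idx <- i0:i1
    edges <- (c(idx - 1L, i1)) * vs
    w <- stats::pnorm((edges[-1] - center) / sigma) -
         stats::pnorm((edges[-length(edges)] - center) / sigma)
    list(idx = idx, w = w)
}

#' Render a scene channel into a noisy PSF-blurred Z-stack
#'
#' Each center contributes an anisotropic Gaussian spot with SD
#' \code{psfSigma} per axis and total integrated intensity
#' \code{intensityPerCluster}; the spot profile is integrated exactly over
#' each voxel, so the voxel sum of an interior spot equals the nominal
#' intensity up to border truncation. A constant background is added, then
#' the configured noise model applied (Poisson on signal plus background by
#' default). Output intensities are clamped nonnegative.
#'
#' @param scene a [GroundTruthScene-class].
#' @param spec the [SceneSpec-class] that produced the scene.
#' @param channel "A" or "B".
#' @return An [ImageStack-class].
#' @examples
#' spec <- SceneSpec(nClustersA = 3, nClustersB = 3, noiseModel = "none",
#'                   backgroundLevel = 0, seed = 2)
#' st <- renderStack(generateScene(spec), spec, "A")
#' sum(voxels(st)) / (3 * 2000)
#' @export
renderStack <- function(scene, spec, channel = c("A", "B")) {
    channel <- match.arg(channel)
    stopifnot(is(scene, "GroundTruthScene"), is(spec, "SceneSpec"))
    centers <- if (channel == "A") scene@centersA else scene@centersB
    d <- spec@gridShape
    arr <- array(0, d)
    for (i in seq_len(nrow(centers))) {
        wz <- .axisWeights(centers[i, 1], spec@psfSigma[1], spec@voxelSize[1], d[1])
        wy <- .axisWeights(centers[i, 2], spec@psfSigma[2], spec@voxelSize[2], d[2])
        wx <- .axisWeights(centers[i, 3], spec@psfSigma[3], spec@voxelSize[3], d[3])
        if (!length(wz$idx) || !length(wy$idx) || !length(wx$idx)) next
        spot <- spec@intensityPerCluster *
            outer(outer(wz$w, wy$w), wx$w)
        arr[wz$idx, wy$idx, wx$idx] <- arr[wz$idx, wy$idx, wx$idx] + spot
    }
    arr <- arr + spec@backgroundLevel
    if (spec@noiseModel != "none") {
        chOffset <- if (channel == "A") 11L else 12L
        arr <- withSeed(childSeed(spec@seed, chOffset), {
            if (spec@noiseModel == "poisson") {
                array(stats::rpois(length(arr), lambda = arr), d)
            } else {
                arr + array(stats::rnorm(length(arr), sd = spec@noiseSigma), d)
            }
        })
        arr[arr < 0] <- 0
    }
    ImageStack(arr, spec@voxelSize, channel)
}

#' Generate a scene and render both channels
#'
#' Convenience wrapper: [generateScene()] followed by [renderStack()] for
#' channels A and B.
#'
#' @param spec a [SceneSpec-class].
#' @return list with elements \code{scene}, \code{A}, \code{B}.
#' @export
simulateStacks <- function(spec) {
    scene <- generateScene(spec)
    list(scene = scene,
         A = renderStack(scene, spec, "A"),
         B = renderStack(scene, spec, "B"))
}

#' Draw nearest-neighbor distances from a finite Gamma mixture
#'
#' Samples n i.i.d. values from sum_i lambda_i Gamma(shape_i, scale_i): the
#' component is chosen by weight, the value by that component's Gamma law.
#' Useful for calibrating and testing the mixture-fitting stage against a
#' known generating model.
#'
#' @param weights mixing weights, must sum to 1 within 1e-9.
#' @param shapes,scales per-component Gamma shape and scale (> 0).
#' @param n number of draws.
#' @param seed integer seed.
#' @param fromChannel,toChannel labels recorded on the sample.
#' @return An [NNDSample-class].
#' @examples
#' s <- sampleNNDMixture(c(0.4, 0.6), c(4, 9), c(0.03, 0.0512),
#'                       n = 1000, seed = 3)
#' summarizeNND(s)
#' @export
sampleNNDMixture <- function(weights, shapes, scales, n, seed = 1L,
                             fromChannel = "sim", toChannel = "sim") {
    if (abs(sum(weights) - 1) > 1e-9) {
        stop("mixture weights must sum to 1 (within 1e-9)")
    }
    stopifnot(all(shapes > 0), all(scales > 0), n > 0,
              length(shapes) == length(weights),
              length(scales) == length(weights))
    x <- withSeed(seed, {
        comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
        stats::rgamma(n, shape = shapes[comp], scale = scales[comp])
    })
    NNDSample(x, fromChannel = fromChannel, toChannel = toChannel,
              region = "all", nFrom = n, nTo = n)
}

#' Gamma shape/scale with a prescribed mode and SD
#'
#' Solves for the shape--scale pair whose density mode (shape-1)*scale sits
#' at \code{mode} with the given SD sqrt(shape)*scale. Convenient for
#' parameterizing simulation scenarios by their observable modes.
#'
#' @param mode desired density mode (> 0), micrometers.
#' @param sd desired SD, micrometers.
#' @return named numeric with elements \code{shape}, \code{scale}.
#' @examples
#' gammaFromMode(0.09, 0.05)
#' @export
gammaFromMode <- function(mode, sd) {
    stopifnot(mode > 0, sd > 0)
    # mode = (a-1) b, sd^2 = a b^2  =>  b = (-mode + sqrt(mode^2 + 4 sd^2)) / 2
    b <- (-mode + sqrt(mode^2 + 4 * sd^2)) / 2
    a <- mode / b + 1
    c(shape = a, scale = b)
}

#' Write an ImageStack as multi-page TIFF with a JSON sidecar
#'
#' Writes one 16-bit unsigned page per Z plane in ascending Z order, plus a
#' \code{.json} sidecar recording voxel size, channel name and any extra
#' metadata (for simulated scenes: the seed and ground-truth centers in
#' micrometers). Intensities are rounded to integers; values above 65535 are
#' clipped with a warning.
#'
#' @param stack an [ImageStack-class].
#' @param path output path ending in \code{.tif}.
#' @param extra named list of additional sidecar fields.
#' @return \code{path}, invisibly.
#' @seealso [readImageStack()]
#' @export
writeImageStack <- function(stack, path, extra = list()) {
    stopIfNot3D(stack)
    v <- round(voxels(stack))
    if (any(v > 65535)) {
        warning("intensities above 65535 clipped for 16-bit output")
        v[v > 65535] <- 65535
    }
    pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    meta <- c(list(voxel_size_um = voxelSize(stack),
                   channel_name = channelName(stack),
                   n_planes = dim(v)[1]),
              extra)
    jsonlite::write_json(meta, sub("\\.tiff?$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read an ImageStack written by [writeImageStack()]
#'
#' @param path path to the \code{.tif} file; the \code{.json} sidecar must
#'   sit next to it.
#' @return An [ImageStack-class].
#' @export
readImageStack <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    meta <- jsonlite::read_json(sub("\\.tiff?$", ".json", path),
                                simplifyVector = TRUE)
    arr <- array(0, c(length(pages), dim(pages[[1]])))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    ImageStack(arr, as.numeric(meta$voxel_size_um),
               as.character(meta$channel_name))
}

#' Read the JSON sidecar of a written stack
#'
#' @param path path to the \code{.tif} or \code{.json} file.
#' @return named list of sidecar fields.
#' @export
readStackSidecar <- function(path) {
    if (!grepl("\\.json$", path)) path <- sub("\\.tiff?$", ".json", path)
    jsonlite::read_json(path, simplifyVector = TRUE)
}
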