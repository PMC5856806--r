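# Spark-detection-style threshold estimation and 3D cluster detection.
#
# The filter chain, per image: (1) the subthreshold image I1 keeps raw pixels
# strictly below mu0 + alpha*sigma0; (2) the working image Iw masks the raw
# image at mu1 + beta*sigma1 computed on I1; (3) the per-image threshold is
# the ratio tauI = mu0 / mu*, with mu* the mean of Iw's non-zero pixels. The
# global threshold tau is the minimum tauI over all contributing images of a
# channel. All image means/SDs are population moments over the full pixel
# grid (zeros of I1 included, unless statsOnNonzeroOnly).

#' Subthreshold image of the filter chain
#'
#' Keeps the pixels of the raw image with intensity strictly below the
#' criterion mu0 + alpha * sigma0 (mean and population SD over all voxels of
#' the raw image); all other pixels are set to zero.
#'
#' @param stack an [ImageStack-class] (a single Z plane is a 1-plane stack).
#' @param alpha SD multiplier (default 1).
#' @return An [ImageStack-class] holding the subthreshold image.
#' @examples
#' st <- ImageStack(array(c(0, 0, 0, 100), c(1, 2, 2)), c(0.18, 0.04, 0.04))
#' range(voxels(subthresholdImage(st, alpha = 1)))
#' @export
subthresholdImage <- function(stack, alpha = 1) {
    stopIfNot3D(stack)
    v <- voxels(stack)
    crit <- mean(v) + alpha * popSD(v)
    out <- v
    out[!(v < crit)] <- 0
    ImageStack(out, voxelSize(stack), channelName(stack))
}

#' Working image of the filter chain
#'
#' Builds the binary mask M1 = (raw >= mu1 + beta * sigma1), with mu1 and
#' sigma1 the mean and population SD of the subthreshold image, and returns
#' the working image Iw = raw * M1 together with the partial threshold
#' statistics. When the mask is empty the result carries the explicit
#' no-signal marker instead of an undefined threshold.
#'
#' @param stack an [ImageStack-class].
#' @param params a [FilterParams-class].
#' @return list with elements \code{working} (an [ImageStack-class]) and
#'   \code{stats} (a [ThresholdResult-class] with \code{muStar}/\code{tauI}
#'   still NA).
#' @export
workingImage <- function(stack, params = FilterParams()) {
    stopIfNot3D(stack)
    v <- voxels(stack)
    mu0 <- mean(v)
    sigma0 <- popSD(v)
    i1 <- voxels(subthresholdImage(stack, params@alpha))
    base <- if (params@statsOnNonzeroOnly) i1[i1 > 0] else i1
    if (length(base) == 0L) base <- 0
    mu1 <- mean(base)
    sigma1 <- popSD(base)
    mask <- v >= mu1 + params@beta * sigma1
    iw <- v
    iw[!mask] <- 0
    noSignal <- !any(iw > 0)
    stats <- new("ThresholdResult", mu0 = mu0, sigma0 = sigma0,
                 mu1 = mu1, sigma1 = sigma1, muStar = NA_real_,
                 tauI = NA_real_, noSignal = noSignal,
                 planeIndex = NA_integer_)
    list(working = ImageStack(iw, voxelSize(stack), channelName(stack)),
         stats = stats)
}

#' Per-image threshold ratio
#'
#' Runs the full filter chain on one image and computes
#' tauI = mu0 / mu*, the ratio of the raw-image mean to the mean of the
#' non-zero pixels of the working image.
#'
#' @param stack an [ImageStack-class].
#' @param params a [FilterParams-class].
#' @return A [ThresholdResult-class]; \code{noSignal} is TRUE and
#'   \code{tauI} NA when the working image has no non-zero pixel.
#' @export
imageThreshold <- function(stack, params = FilterParams()) {
    w <- workingImage(stack, params)
    res <- w$stats
    if (res@noSignal) return(res)
    iw <- voxels(w$working)
    res@muStar <- mean(iw[iw > 0])
    res@tauI <- res@mu0 / res@muStar
    res
}

#' Per-plane thresholds of a Z-stack
#'
#' Applies [imageThreshold()] to every Z plane of the stack independently
#' (each plane is one raw image of the channel).
#'
#' @param stack an [ImageStack-class].
#' @param params a [FilterParams-class].
#' @return list of [ThresholdResult-class], one per plane, with 0-based
#'   \code{planeIndex} set.
#' @export
stackThresholds <- function(stack, params = FilterParams()) {
    stopIfNot3D(stack)
    v <- voxels(stack)
    lapply(seq_len(dim(v)[1]), function(z) {
        plane <- ImageStack(array(v[z, , ], c(1L, dim(v)[2], dim(v)[3])),
                            voxelSize(stack), channelName(stack))
        res <- imageThreshold(plane, params)
        res@planeIndex <- z - 1L
        res
    })
}

#' Global threshold: minimum over per-image thresholds
#'
#' tau is the minimum tauI over all contributing images; images flagged
#' no-signal do not contribute. The value is invariant to input order and to
#' duplication of an image.
#'
#' @param results list of [ThresholdResult-class] (or a numeric vector of
#'   tauI values).
#' @return the global threshold tau.
#' @export
globalThreshold <- function(results) {
    if (is.numeric(results)) {
        taus <- results
    } else {
        taus <- vapply(results, function(r) r@tauI, numeric(1))
        taus <- taus[!vapply(results, function(r) r@noSignal, logical(1))]
    }
    taus <- taus[!is.na(taus)]
    if (!length(taus)) stop("no image contributed a defined threshold")
    min(taus)
}

#' Channel threshold from a stack
#'
#' Convenience: per-plane thresholds followed by the global minimum.
#'
#' @param stack an [ImageStack-class].
#' @param params a [FilterParams-class].
#' @return the channel's global threshold tau.
#' @export
channelThreshold <- function(stack, params = FilterParams()) {
    globalThreshold(stackThresholds(stack, params))
}

# Half-neighborhood offsets (z, y, x) for 6/18/26-connectivity: one of each
# +/- pair, so every undirected adjacency is enumerated once.
.halfOffsets <- function(connectivity) {
    full <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    full <- full[rowSums(abs(full)) > 0, , drop = FALSE]
    keep <- switch(as.character(connectivity),
        "6" = rowSums(abs(full)) == 1,
        "18" = rowSums(abs(full)) <= 2,
        "26" = rep(TRUE, nrow(full)),
        stop("connectivity must be 6, 18 or 26"))
    full <- full[keep, , drop = FALSE]
    # keep lexicographically positive offsets only
    pos <- full[, 1] * 9 + full[, 2] * 3 + full[, 3] > 0
    full[pos, , drop = FALSE]
}

# Label connected components of a logical 3D array. Returns an integer array
# of the same shape; 0 = background. Adjacencies between foreground voxels
# are enumerated by shifted index arithmetic and the partition delegated to
# igraph's union-find.
labelComponents <- function(bin, connectivity = 26L) {
    d <- dim(bin)
    idx <- which(bin)
    out <- array(0L, d)
    if (!length(idx)) return(out)
    rank <- array(0L, d)
    rank[idx] <- seq_along(idx)
    ai <- arrayInd(idx, d)
    offs <- .halfOffsets(connectivity)
    edges <- vector("list", nrow(offs))
    for (k in seq_len(nrow(offs))) {
        nb <- ai + matrix(offs[k, ], nrow(ai), 3, byrow = TRUE)
        ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
              nb[, 2] >= 1L & nb[, 2] <= d[2] &
              nb[, 3] >= 1L & nb[, 3] <= d[3]
        if (!any(ok)) next
        nbLin <- (nb[ok, 3] - 1L) * (d[1] * d[2]) + (nb[ok, 2] - 1L) * d[1] +
                 nb[ok, 1]
        r2 <- rank[nbLin]
        hit <- r2 > 0L
        if (!any(hit)) next
        edges[[k]] <- cbind(which(ok)[hit], r2[hit])
    }
    edges <- do.call(rbind, edges)
    if (is.null(edges)) {
        comp <- seq_along(idx)
    } else {
        g <- igraph::graph_from_edgelist(edges, directed = FALSE)
        g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
        comp <- igraph::components(g)$membership
    }
    # renumber components in first-voxel order for determinism
    first <- !duplicated(comp)
    relabel <- integer(max(comp))
    relabel[comp[first]] <- seq_len(sum(first))
    out[idx] <- relabel[comp]
    out
}

#' Detect 3D clusters with the global threshold
#'
#' Binarizes the raw stack with the channel's global threshold tau, labels
#' 3D connected components across all three axes, discards components
#' smaller than \code{minVoxels}, and reports intensity-weighted centroids
#' in physical micrometers (voxel centers at (index + 0.5) * voxelSize,
#' 0-based indices).
#'
#' tau is a ratio of means, so a binarization rule is needed to turn it into
#' an intensity cutoff. The default, percent-of-maximum semantics, cuts at
#' tau * max intensity of the stack; the alternative
#' (\code{tauMode = "tau_times_mu_star"}) cuts at tau * mu* of the stack's
#' working image.
#'
#' @param stack an [ImageStack-class] (the raw channel stack).
#' @param tau the global threshold from [channelThreshold()] /
#'   [globalThreshold()].
#' @param params a [FilterParams-class].
#' @return A [ClusterSet-class]; empty (0 clusters) when no voxel exceeds
#'   the cutoff.
#' @examples
#' spec <- SceneSpec(nClustersA = 5, nClustersB = 0, noiseModel = "none",
#'                   minSeparationUm = 1, marginUm = 0.5, seed = 4)
#' st <- renderStack(generateScene(spec), spec, "A")
#' cs <- detectClusters(st, channelThreshold(st), FilterParams())
#' length(cs)
#' @export
detectClusters <- function(stack, tau, params = FilterParams()) {
    stopIfNot3D(stack)
    stopifnot(tau > 0)
    v <- voxels(stack)
    cutoff <- if (params@tauMode == "fraction_of_max") {
        tau * max(v)
    } else {
        w <- workingImage(stack, params)
        iw <- voxels(w$working)
        if (!any(iw > 0)) Inf else tau * mean(iw[iw > 0])
    }
    bin <- v >= cutoff & v > 0
    labels <- labelComponents(bin, params@connectivity)
    ids <- sort(unique(labels[labels > 0L]))
    if (!length(ids)) {
        return(new("ClusterSet",
                   centroids = matrix(numeric(0), ncol = 3),
                   voxelCounts = integer(0), totalIntensity = numeric(0),
                   clusterIds = integer(0), labelsVolume = labels,
                   channelName = channelName(stack),
                   voxelSize = voxelSize(stack)))
    }
    idx <- which(labels > 0L)
    lab <- labels[idx]
    counts <- tabulate(lab, nbins = max(ids))
    keep <- which(counts >= params@minVoxels)
    # drop too-small components from the label volume, renumber survivors
    relabel <- integer(max(ids))
    relabel[keep] <- seq_along(keep)
    labels[idx] <- relabel[lab]
    idx <- which(labels > 0L)
    if (!length(idx)) {
        return(new("ClusterSet",
                   centroids = matrix(numeric(0), ncol = 3),
                   voxelCounts = integer(0), totalIntensity = numeric(0),
                   clusterIds = integer(0), labelsVolume = labels,
                   channelName = channelName(stack),
                   voxelSize = voxelSize(stack)))
    }
    lab <- labels[idx]
    ai <- arrayInd(idx, dim(v))
    wts <- v[idx]
    # rowsum sorts integer groups numerically, so row k is cluster label k
    totI <- as.numeric(rowsum(wts, lab))
    vs <- voxelSize(stack)
    cen <- vapply(1:3, function(axis) {
        pos <- (ai[, axis] - 0.5) * vs[axis]
        as.numeric(rowsum(wts * pos, lab)) / totI
    }, numeric(length(totI)))
    cen <- matrix(cen, ncol = 3)
    new("ClusterSet", centroids = cen,
        voxelCounts = as.integer(tabulate(lab)),
        totalIntensity = totI,
        clusterIds = seq_len(nrow(cen)),
        labelsVolume = labels,
        channelName = channelName(stack), voxelSize = vs)
}

#' Write a label volume as multi-page TIFF
#'
#' One 16-bit page per Z plane; pixel value = cluster label (0 background).
#'
#' @param clusters a [ClusterSet-class] whose label volume was kept.
#' @param path output path ending in \code{.tif}.
#' @return \code{path}, invisibly.
#' @export
writeLabelVolume <- function(clusters, path) {
    lv <- clusters@labelsVolume
    if (!length(lv)) stop("this ClusterSet carries no label volume")
    writeImageStack(ImageStack(lv * 1.0, clusters@voxelSize,
                               clusters@channelName),
                    path, extra = list(content = "labels"))
}

#' Write a ClusterSet as CSV
#'
#' Columns: cluster_id, z_um, y_um, x_um, voxels, intensity.
#'
#' @param clusters a [ClusterSet-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeClusterSet <- function(clusters, path) {
    df <- data.frame(cluster_id = clusters@clusterIds,
                     z_um = clusters@centroids[, 1],
                     y_um = clusters@centroids[, 2],
                     x_um = clusters@centroids[, 3],
                     voxels = clusters@voxelCounts,
                     intensity = clusters@totalIntensity)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
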