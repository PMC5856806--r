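# Asymmetric nearest-neighbor distances between cluster populations.

# Grid-accelerated nearest neighbor: uniform cells over the target bounding
# box, expanding Chebyshev shells around each query cell. A target in a cell
# at shell distance d from the query cell is at least (d-1)*h away, so the
# search stops once the best distance found is <= r*h after scanning shell r.
# Distances are computed with the same expression as the brute-force scan
# (sqrt of the coordinate-ordered sum of squares), so results match a full
# scan exactly, not just to rounding.
.gridNND <- function(from, to, excludeSelf = FALSE) {
    nFrom <- nrow(from)
    nTo <- nrow(to)
    out <- numeric(nFrom)
    lo <- apply(to, 2, min)
    span <- apply(to, 2, max) - lo
    # cell size ~ one target per cell, but never finer than 1/32 of the
    # widest extent: a too-fine grid on sparse or flat target sets would
    # force the shell search through huge empty regions
    h <- max((prod(pmax(span, 1e-9)) / nTo)^(1 / 3), max(span) / 32, 1e-9)
    ncell <- pmax(1L, as.integer(floor(span / h)) + 1L)
    toCell <- floor(sweep(to, 2, lo) / h)
    toCell[, 1] <- pmin(pmax(toCell[, 1], 0), ncell[1] - 1L)
    toCell[, 2] <- pmin(pmax(toCell[, 2], 0), ncell[2] - 1L)
    toCell[, 3] <- pmin(pmax(toCell[, 3], 0), ncell[3] - 1L)
    lin <- as.integer(toCell[, 1] * (ncell[2] * ncell[3]) +
                      toCell[, 2] * ncell[3] + toCell[, 3] + 1)
    buckets <- split(seq_len(nTo), lin)
    tto <- t(to)
    for (i in seq_len(nFrom)) {
        p <- from[i, ]
        qc <- floor((p - lo) / h)  # unclamped: query may sit outside the box
        best <- Inf
        maxR <- max(abs(qc), abs(ncell - 1 - qc)) + 1
        for (r in 0:maxR) {
            zr <- max(qc[1] - r, 0):min(qc[1] + r, ncell[1] - 1)
            yr <- max(qc[2] - r, 0):min(qc[2] + r, ncell[2] - 1)
            xr <- max(qc[3] - r, 0):min(qc[3] + r, ncell[3] - 1)
            if (zr[1] > zr[length(zr)] || yr[1] > yr[length(yr)] ||
                xr[1] > xr[length(xr)]) {
                if (is.finite(best) && best <= r * h) break
                next
            }
            cells <- expand.grid(z = zr, y = yr, x = xr)
            onShell <- pmax(abs(cells$z - qc[1]), abs(cells$y - qc[2]),
                            abs(cells$x - qc[3])) == r
            cells <- cells[onShell, , drop = FALSE]
            if (nrow(cells)) {
                keys <- as.character(as.integer(
                    cells$z * (ncell[2] * ncell[3]) +
                    cells$y * ncell[3] + cells$x + 1))
                cand <- unlist(buckets[keys], use.names = FALSE)
                if (excludeSelf) cand <- cand[cand != i]
                if (length(cand)) {
                    d <- sqrt(colSums((tto[, cand, drop = FALSE] - p)^2))
                    best <- min(best, min(d))
                }
            }
            if (is.finite(best) && best <= r * h) break
        }
        out[i] <- best
    }
    out
}

# Per-cluster voxel center coordinates (um) extracted from the label volume.
.clusterVoxelCoords <- function(cs) {
    lv <- cs@labelsVolume
    if (!length(lv)) stop("label volume required for edge-to-edge distances")
    idx <- which(lv > 0L)
    lab <- lv[idx]
    ai <- arrayInd(idx, dim(lv))
    coords <- sweep(ai - 0.5, 2, cs@voxelSize, `*`)
    lapply(cs@clusterIds, function(id) {
        coords[lab == id, , drop = FALSE]
    })
}

.edgeNND <- function(fromSet, toSet, sameSet) {
    fromVox <- .clusterVoxelCoords(fromSet)
    toVox <- .clusterVoxelCoords(toSet)
    cf <- fromSet@centroids
    ct <- toSet@centroids
    rFrom <- vapply(seq_along(fromVox), function(i) {
        max(sqrt(rowSums(sweep(fromVox[[i]], 2, cf[i, ])^2)))
    }, numeric(1))
    rTo <- vapply(seq_along(toVox), function(j) {
        max(sqrt(rowSums(sweep(toVox[[j]], 2, ct[j, ])^2)))
    }, numeric(1))
    vapply(seq_along(fromVox), function(i) {
        cd <- sqrt(colSums((t(ct) - cf[i, ])^2))
        ord <- order(cd)
        best <- Inf
        for (j in ord) {
            if (sameSet && j == i) next
            if (cd[j] - rFrom[i] - rTo[j] > best) break
            A <- fromVox[[i]]
            B <- toVox[[j]]
            for (kk in seq_len(nrow(A))) {
                d <- min(sqrt(colSums((t(B) - A[kk, ])^2)))
                if (d < best) best <- d
            }
        }
        best
    }, numeric(1))
}

#' Nearest-neighbor distances from one cluster population to another
#'
#' For every cluster of the source set, the 3D Euclidean distance in
#' micrometers to the nearest cluster of the target set; NND(A-B) and
#' NND(B-A) are different samples whenever the populations differ. When the
#' source and target are the same population the zero self-match is
#' excluded. Distances are centroid-to-centroid by default;
#' \code{type = "edge"} measures between the nearest suprathreshold voxels
#' of the label volumes instead.
#'
#' @param fromSet,toSet [ClusterSet-class] objects on the same micrometer
#'   coordinate frame.
#' @param region region tag recorded on the sample ("all", "surface",
#'   "interior").
#' @param type "centroid" (default) or "edge".
#' @return An [NNDSample-class] with one distance per source cluster.
#' @examples
#' a <- clusterSetFromCentroids(rbind(c(0, 0, 0)), "A")
#' b <- clusterSetFromCentroids(rbind(c(0, 0, 1), c(0, 0, 3)), "B")
#' distances(nearestNeighborDistances(a, b))
#' @export
nearestNeighborDistances <- function(fromSet, toSet, region = "all",
                                     type = c("centroid", "edge")) {
    type <- match.arg(type)
    stopifnot(is(fromSet, "ClusterSet"), is(toSet, "ClusterSet"))
    sameSet <- identical(fromSet@centroids, toSet@centroids) &&
        fromSet@channelName == toSet@channelName
    nTo <- nrow(toSet@centroids)
    if (nTo == 0L || (sameSet && nTo < 2L)) {
        stop(sprintf("no target clusters for NND(%s-%s)",
                     fromSet@channelName, toSet@channelName))
    }
    if (nrow(fromSet@centroids) == 0L) {
        return(new("NNDSample", distances = numeric(0),
                   fromChannel = fromSet@channelName,
                   toChannel = toSet@channelName, region = region,
                   nFrom = 0L, nTo = nTo))
    }
    d <- if (type == "centroid") {
        .gridNND(fromSet@centroids, toSet@centroids, excludeSelf = sameSet)
    } else {
        .edgeNND(fromSet, toSet, sameSet)
    }
    new("NNDSample", distances = d, fromChannel = fromSet@channelName,
        toChannel = toSet@channelName, region = region,
        nFrom = nrow(fromSet@centroids), nTo = nTo)
}

#' Build a ClusterSet from bare centroids
#'
#' Convenience for feeding externally known or simulated cluster positions
#' into the NND stage (no label volume, unit voxel counts).
#'
#' @param centroids n x 3 matrix of (z, y, x) positions in micrometers.
#' @param channelName channel label.
#' @param voxelSize numeric(3) micrometers per voxel, used only for region
#'   stratification.
#' @return A [ClusterSet-class].
#' @export
clusterSetFromCentroids <- function(centroids, channelName = "channel",
                                    voxelSize = c(0.18, 0.04, 0.04)) {
    centroids <- matrix(as.numeric(centroids), ncol = 3)
    n <- nrow(centroids)
    new("ClusterSet", centroids = centroids,
        voxelCounts = rep(1L, n), totalIntensity = rep(1, n),
        clusterIds = seq_len(n), labelsVolume = array(integer(0), c(0, 0, 0)),
        channelName = channelName, voxelSize = as.numeric(voxelSize))
}

#' Split a ClusterSet into surface and interior sub-populations
#'
#' A cluster belongs to the Z plane containing its centroid
#' (\code{floor(z / voxelSize_z)}, 0-based); clusters whose plane is listed
#' in \code{surfacePlanes} form the surface set, all others the interior
#' set. The partition is exhaustive and disjoint.
#'
#' @param clusters a [ClusterSet-class].
#' @param surfacePlanes integer vector of 0-based Z plane indices.
#' @return list with [ClusterSet-class] elements \code{surface} and
#'   \code{interior}.
#' @export
stratifyByRegion <- function(clusters, surfacePlanes) {
    stopifnot(is(clusters, "ClusterSet"))
    plane <- floor(clusters@centroids[, 1] / clusters@voxelSize[1])
    isSurf <- plane %in% as.integer(surfacePlanes)
    subsetCS <- function(keep) {
        new("ClusterSet",
            centroids = clusters@centroids[keep, , drop = FALSE],
            voxelCounts = clusters@voxelCounts[keep],
            totalIntensity = clusters@totalIntensity[keep],
            clusterIds = clusters@clusterIds[keep],
            labelsVolume = clusters@labelsVolume,
            channelName = clusters@channelName,
            voxelSize = clusters@voxelSize)
    }
    list(surface = subsetCS(isSurf), interior = subsetCS(!isSurf))
}

#' Mean, SD and size of an NND sample
#'
#' Arithmetic mean and sample SD (n - 1 denominator) in micrometers. A
#' single-element sample reports SD 0 (flagged by n = 1).
#'
#' @param sample an [NNDSample-class] (or bare numeric vector).
#' @return named numeric: \code{mean}, \code{sd}, \code{n}.
#' @examples
#' summarizeNND(NNDSample(c(1, 1, 2)))
#' @export
summarizeNND <- function(sample) {
    x <- if (is(sample, "NNDSample")) sample@distances else as.numeric(sample)
    if (!length(x)) stop("cannot summarize an empty NND sample")
    s <- if (length(x) == 1L) 0 else stats::sd(x)
    c(mean = mean(x), sd = s, n = length(x))
}

#' Write an NNDSample as CSV
#'
#' Columns: distance_um, from, to, region.
#'
#' @param sample an [NNDSample-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeNNDSample <- function(sample, path) {
    df <- data.frame(distance_um = sample@distances,
                     from = sample@fromChannel, to = sample@toChannel,
                     region = sample@region)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Read an NNDSample from CSV
#'
#' @param path CSV written by [writeNNDSample()].
#' @return An [NNDSample-class].
#' @export
readNNDSample <- function(path) {
    df <- utils::read.csv(path)
    NNDSample(df$distance_um,
              fromChannel = as.character(df$from[1]),
              toChannel = as.character(df$to[1]),
              region = as.character(df$region[1]))
}
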