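#' @rdname ImageStack-class
setMethod("voxels", "ImageStack", function(x) x@voxels)

#' @rdname ImageStack-class
setMethod("voxelSize", "ImageStack", function(x) x@voxelSize)

#' @rdname ClusterSet-class
setMethod("voxelSize", "ClusterSet", function(x) x@voxelSize)

#' @rdname ImageStack-class
setMethod("channelName", "ImageStack", function(x) x@channelName)

#' @rdname ClusterSet-class
setMethod("channelName", "ClusterSet", function(x) x@channelName)

#' @rdname PresenceMask-class
#' @param x a PresenceMask.
setMethod("channelName", "PresenceMask", function(x) x@channelName)

#' @rdname ClusterSet-class
setMethod("centroids", "ClusterSet", function(x) x@centroids)

#' @rdname ClusterSet-class
setMethod("voxelCounts", "ClusterSet", function(x) x@voxelCounts)

#' @rdname ClusterSet-class
setMethod("totalIntensity", "ClusterSet", function(x) x@totalIntensity)

#' @rdname ClusterSet-class
setMethod("labelsVolume", "ClusterSet", function(x) x@labelsVolume)

#' @rdname ClusterSet-class
#' @param object a ClusterSet.
#' @export
setMethod("length", "ClusterSet", function(x) nrow(x@centroids))

#' @rdname NNDSample-class
setMethod("distances", "NNDSample", function(x) x@distances)

#' @rdname NNDSample-class
#' @export
setMethod("length", "NNDSample", function(x) length(x@distances))

#' @rdname GammaMixtureFit-class
setMethod("weights", "GammaMixtureFit", function(object, ...) object@weights)

#' @rdname GammaMixtureFit-class
setMethod("shapes", "GammaMixtureFit", function(x) x@shapes)

#' @rdname GammaMixtureFit-class
setMethod("scales", "GammaMixtureFit", function(x) x@scales)

#' @rdname GammaMixtureFit-class
setMethod("modes", "GammaMixtureFit", function(x) x@modes)

#' @rdname GammaMixtureFit-class
setMethod("bic", "GammaMixtureFit", function(x) x@bic)

#' @rdname GammaMixtureFit-class
setMethod("nComponents", "GammaMixtureFit", function(x) length(x@weights))

#' @rdname GammaMixtureFit-class
setMethod("converged", "GammaMixtureFit", function(x) x@converged)

#' @rdname GroundTruthScene-class
setMethod("centersA", "GroundTruthScene", function(x) x@centersA)

#' @rdname GroundTruthScene-class
setMethod("centersB", "GroundTruthScene", function(x) x@centersB)

#' @rdname GroundTruthScene-class
setMethod("coupledFlags", "GroundTruthScene", function(x) x@coupled)

setMethod("show", "ImageStack", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("ImageStack '%s': %d x %d x %d voxels (z, y, x)\n",
                object@channelName, d[1], d[2], d[3]))
    cat(sprintf("  voxel size (um): z=%.3g y=%.3g x=%.3g\n",
                object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
    cat(sprintf("  intensity range: [%.4g, %.4g]\n",
                min(object@voxels), max(object@voxels)))
    invisible(NULL)
})

setMethod("show", "ClusterSet", function(object) {
    cat(sprintf("ClusterSet '%s': %d clusters\n", object@channelName,
                nrow(object@centroids)))
    if (nrow(object@centroids)) {
        cat(sprintf("  voxels per cluster: median %d, range [%d, %d]\n",
                    as.integer(stats::median(object@voxelCounts)),
                    min(object@voxelCounts), max(object@voxelCounts)))
    }
    invisible(NULL)
})

setMethod("show", "NNDSample", function(object) {
    cat(sprintf("NNDSample NND(%s-%s), region '%s': n = %d\n",
                object@fromChannel, object@toChannel, object@region,
                length(object@distances)))
    if (length(object@distances)) {
        s <- summarizeNND(object)
        cat(sprintf("  mean %.3f um, SD %.3f um\n", s["mean"], s["sd"]))
    }
    invisible(NULL)
})

setMethod("show", "GammaMixtureFit", function(object) {
    K <- length(object@weights)
    cat(sprintf("GammaMixtureFit: K = %d, n = %d, logLik = %.3f, BIC = %.3f\n",
                K, object@n, object@logLik, object@bic))
    for (i in seq_len(K)) {
        cat(sprintf("  comp %d: weight %.3f, shape %.3f, scale %.4f (mean %.3f um)\n",
                    i, object@weights[i], object@shapes[i], object@scales[i],
                    object@shapes[i] * object@scales[i]))
    }
    cat(sprintf("  modes (um): %s\n",
                paste(sprintf("%.3f", object@modes), collapse = ", ")))
    invisible(NULL)
})

setMethod("show", "ColocResult", function(object) {
    fmt <- function(p) if (is.na(p)) "undefined" else sprintf("%.3f", p)
    cat(sprintf("ColocResult (%s | %s), region '%s'\n", object@channelB,
                object@channelA, object@region))
    cat(sprintf("  P(%s|%s) = %s  P(%s|%s) = %s  (overlap %d, nA %d, nB %d)\n",
                object@channelB, object@channelA, fmt(object@probBgivenA),
                object@channelA, object@channelB, fmt(object@probAgivenB),
                object@overlapCount, object@nA, object@nB))
    cat(sprintf("  Pearson r = %s\n", fmt(object@pearsonR)))
    invisible(NULL)
})

setMethod("show", "GroundTruthScene", function(object) {
    cat(sprintf("GroundTruthScene: %d A centers, %d B centers (%d coupled)\n",
                nrow(object@centersA), nrow(object@centersB),
                sum(object@coupled)))
    cat(sprintf("  bounds (um): z=%.2f y=%.2f x=%.2f\n", object@bounds[1],
                object@bounds[2], object@bounds[3]))
    invisible(NULL)
})

setMethod("show", "RunReport", function(object) {
    cat(sprintf("RunReport (punctacoloc %s, seed %d)\n", object@version,
                object@seed))
    cat("Clusters:\n")
    print(object@clusters)
    cat("\nNND From\\To table, mean +/- SD (um), region 'all':\n")
    print(nndTable(object, region = "all"))
    cat("\nColocalization:\n")
    print(object@coloc)
    invisible(NULL)
})
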