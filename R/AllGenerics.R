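#' @rdname ImageStack-class
#' @param x an object.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname ImageStack-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname ImageStack-class
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @rdname ClusterSet-class
#' @param x an object.
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname ClusterSet-class
#' @export
setGeneric("voxelCounts", function(x) standardGeneric("voxelCounts"))

#' @rdname ClusterSet-class
#' @export
setGeneric("totalIntensity", function(x) standardGeneric("totalIntensity"))

#' @rdname ClusterSet-class
#' @export
setGeneric("labelsVolume", function(x) standardGeneric("labelsVolume"))

#' @rdname NNDSample-class
#' @param x an object.
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname GammaMixtureFit-class
#' @param object an object (for \code{weights}).
#' @param ... unused.
#' @export
setGeneric("weights")

#' @rdname GammaMixtureFit-class
#' @export
setGeneric("shapes", function(x) standardGeneric("shapes"))

#' @rdname GammaMixtureFit-class
#' @export
setGeneric("scales", function(x) standardGeneric("scales"))

#' @rdname GammaMixtureFit-class
#' @export
setGeneric("modes", function(x) standardGeneric("modes"))

#' @rdname GammaMixtureFit-class
#' @export
setGeneric("bic", function(x) standardGeneric("bic"))

#' @rdname GammaMixtureFit-class
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname GammaMixtureFit-class
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname GroundTruthScene-class
#' @param x an object.
#' @export
setGeneric("centersA", function(x) standardGeneric("centersA"))

#' @rdname GroundTruthScene-class
#' @export
setGeneric("centersB", function(x) standardGeneric("centersB"))

#' @rdname GroundTruthScene-class
#' @export
setGeneric("coupledFlags", function(x) standardGeneric("coupledFlags"))
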