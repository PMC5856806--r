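# Presence-based conditional-probability colocalization and Pearson
# intensity correlation for a two-channel pair.

#' Voxelwise signal-presence mask
#'
#' Marks the voxels where a channel's signal is present after filtering,
#' using the same binarization rule as [detectClusters()] but without any
#' minimum-cluster-size filtering: the conditional probabilities sum
#' per-voxel indicators, so presence is voxelwise.
#'
#' @param stack an [ImageStack-class] (raw channel stack).
#' @param tau the channel's global threshold.
#' @param params a [FilterParams-class] (only \code{tauMode} is used here).
#' @return A [PresenceMask-class].
#' @export
presenceMask <- function(stack, tau, params = FilterParams()) {
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
    new("PresenceMask", mask = v >= cutoff & v > 0,
        channelName = channelName(stack))
}

#' Conditional colocalization probabilities of two presence masks
#'
#' P(B|A) is the fraction of A-positive voxels that are also B-positive
#' (and symmetrically for P(A|B)): overlap and marginal counts are computed
#' in exact integer arithmetic before the single division, so
#' P(B|A) * nA = P(A|B) * nB = overlap holds exactly. An empty conditioning
#' mask makes the corresponding probability undefined (NA, flagged), never
#' zero.
#'
#' @param maskA,maskB [PresenceMask-class] objects on identical grids.
#' @param region region tag recorded on the result.
#' @param planes optional 0-based Z plane indices restricting the analysis
#'   to a region of the stack.
#' @return A [ColocResult-class] (Pearson slot NA; see
#'   [pearsonCorrelation()]).
#' @examples
#' a <- new("PresenceMask", mask = array(c(rep(TRUE, 4), rep(FALSE, 12)),
#'                                       c(1, 4, 4)), channelName = "A")
#' b <- new("PresenceMask", mask = array(c(FALSE, FALSE, TRUE, TRUE, TRUE,
#'                                         rep(FALSE, 11)), c(1, 4, 4)),
#'          channelName = "B")
#' conditionalProbability(a, b)
#' @export
conditionalProbability <- function(maskA, maskB, region = "all",
                                   planes = NULL) {
    stopifnot(is(maskA, "PresenceMask"), is(maskB, "PresenceMask"))
    if (!identical(dim(maskA@mask), dim(maskB@mask))) {
        stop("presence masks must share one voxel grid")
    }
    a <- maskA@mask
    b <- maskB@mask
    if (!is.null(planes)) {
        zKeep <- as.integer(planes) + 1L
        a <- a[zKeep, , , drop = FALSE]
        b <- b[zKeep, , , drop = FALSE]
    }
    nA <- sum(a)
    nB <- sum(b)
    overlap <- sum(a & b)
    new("ColocResult",
        probBgivenA = if (nA > 0L) overlap / nA else NA_real_,
        probAgivenB = if (nB > 0L) overlap / nB else NA_real_,
        overlapCount = as.integer(overlap), nA = as.integer(nA),
        nB = as.integer(nB), definedA = nA > 0L, definedB = nB > 0L,
        pearsonR = NA_real_, region = region,
        channelA = maskA@channelName, channelB = maskB@channelName)
}

#' Pearson correlation of two channels' voxel intensities
#'
#' Sample Pearson correlation over the analyzed region, computed on the raw
#' (unfiltered) intensities by default. Returns NA with a warning when
#' either channel is constant over the region.
#'
#' @param stackA,stackB [ImageStack-class] objects on identical grids.
#' @param planes optional 0-based Z plane indices restricting the region.
#' @param regionMask optional logical array selecting voxels (applied after
#'   any plane restriction must match the restricted grid).
#' @param filtered if TRUE, intensities below each channel's presence cutoff
#'   are zeroed before correlating (requires \code{tauA} and \code{tauB}).
#' @param tauA,tauB per-channel global thresholds, used when
#'   \code{filtered = TRUE}.
#' @param params a [FilterParams-class], used when \code{filtered = TRUE}.
#' @return Pearson r in [-1, 1], or NA when undefined.
#' @examples
#' a <- ImageStack(array(1:8, c(2, 2, 2)), c(0.18, 0.04, 0.04), "A")
#' b <- ImageStack(array(2 * (1:8) + 5, c(2, 2, 2)), c(0.18, 0.04, 0.04), "B")
#' pearsonCorrelation(a, b)
#' @export
pearsonCorrelation <- function(stackA, stackB, planes = NULL,
                               regionMask = NULL, filtered = FALSE,
                               tauA = NULL, tauB = NULL,
                               params = FilterParams()) {
    stopIfNot3D(stackA)
    stopIfNot3D(stackB)
    a <- voxels(stackA)
    b <- voxels(stackB)
    if (filtered) {
        if (is.null(tauA) || is.null(tauB)) {
            stop("filtered Pearson needs tauA and tauB")
        }
        a[!presenceMask(stackA, tauA, params)@mask] <- 0
        b[!presenceMask(stackB, tauB, params)@mask] <- 0
    }
    if (!identical(dim(a), dim(b))) stop("stacks must share one voxel grid")
    if (!is.null(planes)) {
        zKeep <- as.integer(planes) + 1L
        a <- a[zKeep, , , drop = FALSE]
        b <- b[zKeep, , , drop = FALSE]
    }
    va <- as.vector(a)
    vb <- as.vector(b)
    if (!is.null(regionMask)) {
        sel <- as.vector(regionMask)
        va <- va[sel]
        vb <- vb[sel]
    }
    if (length(va) < 2L) stop("need at least 2 voxels in the region")
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
        warning("constant channel in region: Pearson correlation undefined")
        return(NA_real_)
    }
    stats::cor(va, vb)
}

#' Write a ColocResult as JSON
#'
#' @param result a [ColocResult-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeColocResult <- function(result, path) {
    jsonlite::write_json(list(
        channel_a = result@channelA, channel_b = result@channelB,
        region = result@region,
        prob_b_given_a = result@probBgivenA,
        prob_a_given_b = result@probAgivenB,
        overlap_voxels = result@overlapCount,
        n_a = result@nA, n_b = result@nB,
        defined_a = result@definedA, defined_b = result@definedB,
        pearson_r = result@pearsonR),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
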