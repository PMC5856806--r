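# Orchestration: simulate -> detect -> NND -> mixture -> coloc, as one
# configured, reproducible run. A single master seed is fanned out to
# per-stage child seeds so each stage is individually reproducible.

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
    })
}

#' Run the full spatial-coupling pipeline
#'
#' Generates the configured synthetic scene (the scene seed is derived from
#' the run's master seed), renders both channels, estimates per-channel
#' global thresholds, detects 3D clusters, computes the four ordered NND
#' samples (A-A, B-B, A-B, B-A) for the whole volume and for the
#' surface/interior regions, fits Gamma mixtures to the inter-channel NNDs
#' with BIC order selection, and computes per-region conditional
#' probabilities and Pearson correlation. Rerunning with the same
#' configuration reproduces the report bit for bit.
#'
#' @param config a [RunConfig-class].
#' @param verbose if TRUE, log every per-plane mu0/sigma0/tauI, each
#'   channel's tau, and all sample sizes as messages while the run
#'   progresses.
#' @return A [RunReport-class]. When \code{config@outputDir} is set, the
#'   report JSON, the From\\To tables, and all per-stage intermediates
#'   (stack TIFFs, cluster and NND CSVs, fit and coloc JSONs, density
#'   plots) are written there.
#' @examples
#' \donttest{
#' cfg <- RunConfig(scene = SceneSpec(gridShape = c(12, 64, 64),
#'                                    nClustersA = 40, nClustersB = 40),
#'                  seed = 1)
#' rep <- runPipeline(cfg)
#' nndTable(rep)
#' }
#' @export
runPipeline <- function(config, verbose = FALSE) {
    stopifnot(is(config, "RunConfig"))
    validObject(config)
    log <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
    spec <- config@scene
    spec@seed <- childSeed(config@seed, 1L)

    sim <- .stage("simulate", simulateStacks(spec))
    chThreshold <- function(stack) {
        planes <- stackThresholds(stack, config@filter)
        for (p in planes) {
            log("channel %s plane %d: mu0=%.4g sigma0=%.4g tauI=%.4g%s",
                channelName(stack), p@planeIndex, p@mu0, p@sigma0, p@tauI,
                if (p@noSignal) " (no signal)" else "")
        }
        tau <- globalThreshold(planes)
        log("channel %s: tau = %.6g", channelName(stack), tau)
        tau
    }
    tauA <- .stage("threshold", chThreshold(sim$A))
    tauB <- .stage("threshold", chThreshold(sim$B))
    csA <- .stage("detect", detectClusters(sim$A, tauA, config@filter))
    csB <- .stage("detect", detectClusters(sim$B, tauB, config@filter))
    log("detected clusters: A=%d B=%d", length(csA), length(csB))

    strataA <- stratifyByRegion(csA, config@surfacePlanes)
    strataB <- stratifyByRegion(csB, config@surfacePlanes)
    sets <- list(
        all = list(A = csA, B = csB),
        surface = list(A = strataA$surface, B = strataB$surface),
        interior = list(A = strataA$interior, B = strataB$interior))

    pairs <- list(c("A", "A"), c("B", "B"), c("A", "B"), c("B", "A"))
    nndRows <- list()
    samples <- list()
    for (region in names(sets)) {
        for (p in pairs) {
            key <- sprintf("%s-%s.%s", p[1], p[2], region)
            smp <- tryCatch(
                nearestNeighborDistances(sets[[region]][[p[1]]],
                                         sets[[region]][[p[2]]],
                                         region = region),
                error = function(e) NULL)
            samples[[key]] <- smp
            log("NND %s: n = %d", key,
                if (is.null(smp)) 0L else length(smp@distances))
            if (!is.null(smp) && length(smp@distances)) {
                s <- summarizeNND(smp)
                nndRows[[key]] <- data.frame(
                    from = p[1], to = p[2], region = region,
                    mean_um = unname(s["mean"]), sd_um = unname(s["sd"]),
                    n = as.integer(s["n"]))
            } else {
                nndRows[[key]] <- data.frame(
                    from = p[1], to = p[2], region = region,
                    mean_um = NA_real_, sd_um = NA_real_, n = 0L)
            }
        }
    }
    nndDf <- do.call(rbind, nndRows)
    rownames(nndDf) <- NULL

    fits <- list()
    for (key in c("A-B", "B-A")) {
        smp <- samples[[paste0(key, ".all")]]
        fits[[key]] <- .stage("mixture", {
            if (is.null(smp) || length(smp@distances) < 20L) {
                stop(sprintf("too few %s distances for mixture fitting", key))
            }
            selectMixtureModel(smp, kMax = config@kMax,
                               seed = childSeed(config@seed,
                                                20L + match(key, c("A-B", "B-A"))),
                               nRestarts = config@nRestarts)
        })
    }

    maskA <- .stage("coloc", presenceMask(sim$A, tauA, config@filter))
    maskB <- .stage("coloc", presenceMask(sim$B, tauB, config@filter))
    nz <- spec@gridShape[1]
    planesOf <- list(all = NULL,
                     surface = intersect(config@surfacePlanes, 0:(nz - 1L)),
                     interior = setdiff(0:(nz - 1L), config@surfacePlanes))
    colocRows <- list()
    colocObjs <- list()
    for (region in names(planesOf)) {
        cp <- conditionalProbability(maskA, maskB, region = region,
                                     planes = planesOf[[region]])
        r <- tryCatch(
            pearsonCorrelation(sim$A, sim$B, planes = planesOf[[region]]),
            warning = function(w) NA_real_)
        cp@pearsonR <- r
        colocObjs[[region]] <- cp
        colocRows[[region]] <- data.frame(
            region = region,
            prob_b_given_a = cp@probBgivenA, prob_a_given_b = cp@probAgivenB,
            overlap_voxels = cp@overlapCount, n_a = cp@nA, n_b = cp@nB,
            pearson_r = r)
    }
    colocDf <- do.call(rbind, colocRows)
    rownames(colocDf) <- NULL

    clustersDf <- data.frame(
        channel = c("A", "B"),
        n_clusters = c(length(csA), length(csB)),
        median_voxels = c(
            if (length(csA)) stats::median(voxelCounts(csA)) else NA_real_,
            if (length(csB)) stats::median(voxelCounts(csB)) else NA_real_))
    thresholdsDf <- data.frame(channel = c("A", "B"), tau = c(tauA, tauB))

    report <- new("RunReport", clusters = clustersDf,
                  thresholds = thresholdsDf, nnd = nndDf, fits = fits,
                  coloc = colocDf, config = config,
                  version = as.character(utils::packageVersion("punctacoloc")),
                  seed = config@seed)

    if (length(config@outputDir)) {
        .writeRunOutputs(report, sim, list(A = csA, B = csB), samples,
                         colocObjs, config@outputDir)
    }
    report
}

.writeRunOutputs <- function(report, sim, clusterSets, samples, colocObjs,
                             dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fp <- function(...) file.path(dir, ...)
    writeImageStack(sim$A, fp("channel_A.tif"),
                    extra = list(seed = report@seed))
    writeImageStack(sim$B, fp("channel_B.tif"),
                    extra = list(seed = report@seed))
    writeClusterSet(clusterSets$A, fp("clusters_A.csv"))
    writeClusterSet(clusterSets$B, fp("clusters_B.csv"))
    for (key in names(samples)) {
        if (!is.null(samples[[key]])) {
            writeNNDSample(samples[[key]], fp(sprintf("nnd_%s.csv", key)))
        }
    }
    for (key in names(report@fits)) {
        writeMixtureFit(report@fits[[key]], fp(sprintf("fit_%s.json", key)))
        smp <- samples[[paste0(key, ".all")]]
        if (!is.null(smp)) {
            grDevices::pdf(fp(sprintf("density_%s.pdf", key)), width = 6,
                           height = 4)
            plotDensityOverlay(smp, report@fits[[key]],
                               main = sprintf("NND(%s)", key))
            grDevices::dev.off()
        }
    }
    for (region in names(colocObjs)) {
        writeColocResult(colocObjs[[region]],
                         fp(sprintf("coloc_%s.json", region)))
    }
    utils::write.csv(report@nnd, fp("tables.csv"), row.names = FALSE)
    jsonlite::write_json(reportAsList(report), fp("report.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(NULL)
}

#' Serialize a RunReport to a plain list
#'
#' Deterministic plain-data form of the report (what \code{report.json}
#' contains): identical configs and seeds serialize byte-identically.
#'
#' @param report a [RunReport-class].
#' @return nested list of plain values.
#' @export
reportAsList <- function(report) {
    cfg <- report@config
    fitAsList <- function(f) list(
        weights = f@weights, shapes = f@shapes, scales = f@scales,
        log_likelihood = f@logLik, n = f@n, bic = f@bic, modes_um = f@modes,
        converged = f@converged, n_iter = f@nIter)
    list(
        version = report@version,
        seed = report@seed,
        config = list(
            grid_shape = cfg@scene@gridShape,
            voxel_size_um = cfg@scene@voxelSize,
            n_clusters_a = cfg@scene@nClustersA,
            n_clusters_b = cfg@scene@nClustersB,
            coupled_fraction = cfg@scene@coupledFraction,
            coupled_shape = cfg@scene@coupledShape,
            coupled_scale = cfg@scene@coupledScale,
            intensity_per_cluster = cfg@scene@intensityPerCluster,
            psf_sigma_um = cfg@scene@psfSigma,
            noise_model = cfg@scene@noiseModel,
            background_level = cfg@scene@backgroundLevel,
            alpha = cfg@filter@alpha, beta = cfg@filter@beta,
            connectivity = cfg@filter@connectivity,
            min_voxels = cfg@filter@minVoxels,
            surface_planes = cfg@surfacePlanes,
            k_max = cfg@kMax, n_restarts = cfg@nRestarts),
        thresholds = report@thresholds,
        clusters = report@clusters,
        nnd = report@nnd,
        fits = lapply(report@fits, fitAsList),
        coloc = report@coloc)
}

#' From\\To table of NND means and SDs
#'
#' The ordered-pair nearest-neighbor summary laid out as a matrix with
#' source channels as rows and target channels as columns, entries
#' "mean +/- SD" in micrometers.
#'
#' @param report a [RunReport-class].
#' @param region "all", "surface" or "interior".
#' @return character matrix with From rows and To columns.
#' @export
nndTable <- function(report, region = "all") {
    stopifnot(is(report, "RunReport"))
    df <- report@nnd[report@nnd$region == region, ]
    chans <- c("A", "B")
    out <- matrix("", 2, 2, dimnames = list(From = chans, To = chans))
    for (i in seq_len(nrow(df))) {
        out[df$from[i], df$to[i]] <- if (is.na(df$mean_um[i])) {
            "NA"
        } else {
            sprintf("%.2f +/- %.2f", df$mean_um[i], df$sd_um[i])
        }
    }
    out
}

#' Two-sample t-test between NND samples
#'
#' Welch two-sample t-test on the distances of two NND samples, the
#' significance test behind the table annotations comparing ordered pairs
#' or regions.
#'
#' @param a,b [NNDSample-class] objects (or numeric vectors).
#' @param ... passed to [stats::t.test()].
#' @return an object of class \code{htest}.
#' @export
compareNNDSamples <- function(a, b, ...) {
    xa <- if (is(a, "NNDSample")) a@distances else as.numeric(a)
    xb <- if (is(b, "NNDSample")) b@distances else as.numeric(b)
    stats::t.test(xa, xb, ...)
}
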