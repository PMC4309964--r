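#' @include kinetics.R synth.R
NULL

## Polynomial rolling hash over a serialized object: a short stable
## fingerprint for the run log (not cryptographic).
configHash <- function(x) {
    bytes <- as.integer(serialize(x, NULL, version = 2))
    h <- 5381
    for (b in bytes) h <- (h * 33 + b) %% 2147483647
    sprintf("%08x", h)
}

#' Assemble and validate a pipeline run configuration
#'
#' Every numeric field is validated against its module's constraints here,
#' before any image is read, so a bad setting (e.g. an even kernel) fails
#' fast.
#'
#' @param input path to a multi-page TIFF, or an [ImageStack-class]
#'   directly.
#' @param pixelSizeUm,dtS calibration (required when `input` is a path).
#' @param mode `"2d"` or `"3d"`. Volumetric mode is explicit, never
#'   inferred, to avoid silently misreading page order.
#' @param dzUm,zCount z calibration and plane count (3d mode with a path
#'   input).
#' @param pageOrder TIFF page order, `"tz"` or `"zt"` (see [readStack()]).
#' @param outputDir directory for the output bundle.
#' @param seed integer recorded in output headers and used for any
#'   stochastic step.
#' @param preprocess a [preprocessConfig()].
#' @param segment a [segmentConfig()].
#' @param track a [trackConfig()].
#' @param kineticsMinRun minimum phase length for [extractPhases()]
#'   (default 5).
#' @param kineticsIntensity `"raw"` (default) or `"corrected"` series for
#'   the fits.
#' @param kineticsWindows optional manual phase windows (see
#'   [fitTrackKinetics()]).
#' @param exportIntensity `"corrected"` (default) or `"raw"` intensity
#'   column in the track CSV.
#' @param writeOverlays write per-frame outline PNGs (planar mode only;
#'   default FALSE).
#' @param overlayIds stamp adhesion IDs on the overlays (default TRUE).
#' @param lifetimeBinMin,sizeBinUm2 summary histogram bin widths
#'   (defaults 2 min, 2 um2).
#' @return a list of class `runConfig`.
#' @export
runConfig <- function(input, pixelSizeUm = NULL, dtS = NULL,
                      mode = c("2d", "3d"), dzUm = NULL, zCount = NULL,
                      pageOrder = "tz", outputDir = "adhesion_out",
                      seed = 1L,
                      preprocess = preprocessConfig(),
                      segment = segmentConfig(),
                      track = trackConfig(),
                      kineticsMinRun = 5L,
                      kineticsIntensity = c("raw", "corrected"),
                      kineticsWindows = NULL,
                      exportIntensity = c("corrected", "raw"),
                      writeOverlays = FALSE, overlayIds = TRUE,
                      lifetimeBinMin = 2, sizeBinUm2 = 2) {
    mode <- match.arg(mode)
    kineticsIntensity <- match.arg(kineticsIntensity)
    exportIntensity <- match.arg(exportIntensity)
    stopifnot(inherits(preprocess, "preprocessConfig"),
              inherits(segment, "segmentConfig"),
              inherits(track, "trackConfig"))
    if (!is(input, "ImageStack")) {
        if (!is.character(input) || length(input) != 1L)
            stop("input must be a TIFF path or an ImageStack", call. = FALSE)
        if (is.null(pixelSizeUm) || is.null(dtS))
            stop("pixelSizeUm and dtS are required with a path input",
                 call. = FALSE)
        if (mode == "3d" && (is.null(dzUm) || is.null(zCount)))
            stop("3d mode with a path input needs dzUm and zCount",
                 call. = FALSE)
    } else if (mode == "3d" && !isVolumetric(input)) {
        stop("mode is '3d' but the ImageStack is planar", call. = FALSE)
    } else if (mode == "2d" && isVolumetric(input)) {
        stop("mode is '2d' but the ImageStack is volumetric", call. = FALSE)
    }
    if (!is.finite(kineticsMinRun) || kineticsMinRun < 3)
        stop("kineticsMinRun must be >= 3", call. = FALSE)
    if (lifetimeBinMin <= 0 || sizeBinUm2 <= 0)
        stop("histogram bin widths must be > 0", call. = FALSE)
    structure(list(input = input, pixelSizeUm = pixelSizeUm, dtS = dtS,
                   mode = mode, dzUm = dzUm, zCount = zCount,
                   pageOrder = pageOrder, outputDir = outputDir,
                   seed = as.integer(seed), preprocess = preprocess,
                   segment = segment, track = track,
                   kineticsMinRun = as.integer(kineticsMinRun),
                   kineticsIntensity = kineticsIntensity,
                   kineticsWindows = kineticsWindows,
                   exportIntensity = exportIntensity,
                   writeOverlays = isTRUE(writeOverlays),
                   overlayIds = isTRUE(overlayIds),
                   lifetimeBinMin = lifetimeBinMin,
                   sizeBinUm2 = sizeBinUm2),
              class = "runConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Maps a YAML file with `input`, `preprocess`, `segment`, `track`,
#' `kinetics` and `output` sections (snake_case keys mirroring the
#' [runConfig()] arguments) onto a validated configuration.
#'
#' @param path YAML file.
#' @param overrides named list applied over the file's values (CLI
#'   flags).
#' @return a `runConfig`.
#' @export
readRunConfig <- function(path, overrides = list()) {
    y <- yaml::read_yaml(path)
    y <- utils::modifyList(y, overrides)
    g <- function(sec, key, default) {
        v <- y[[sec]][[key]]
        if (is.null(v)) default else v
    }
    pre <- preprocessConfig(
        gaussianSigmaPx = g("preprocess", "gaussian_sigma_px", 1.0),
        lowpassKernelPx = g("preprocess", "lowpass_kernel_px", 51L),
        epsilon = g("preprocess", "epsilon", NA_real_),
        lowpassType = g("preprocess", "lowpass_type", "box"))
    seg <- segmentConfig(
        localKernelPx = g("segment", "local_kernel_px", 15L),
        localOffset = g("segment", "local_offset", 0),
        cellThreshold = g("segment", "cell_threshold", "otsu"),
        minAreaUm2 = g("segment", "min_area_um2", 1.0),
        connectivity = g("segment", "connectivity", 8L),
        cellKeepLargest = g("segment", "cell_keep_largest", TRUE),
        cellFillHoles = g("segment", "cell_fill_holes", TRUE))
    trk <- trackConfig(
        maxLinkUm = g("track", "max_link_um", 2.0),
        zLinkRadiusUm = g("track", "z_link_radius_um", 1.0),
        minTrackLen = g("track", "min_track_len", 3L))
    runConfig(input = g("input", "path", stop("input.path is required")),
              pixelSizeUm = g("input", "pixel_size_um", NULL),
              dtS = g("input", "dt_s", NULL),
              mode = g("input", "mode", "2d"),
              dzUm = g("input", "dz_um", NULL),
              zCount = g("input", "z_count", NULL),
              pageOrder = g("input", "page_order", "tz"),
              outputDir = g("output", "dir", "adhesion_out"),
              seed = if (is.null(y$seed)) 1L else y$seed,
              preprocess = pre, segment = seg, track = trk,
              kineticsMinRun = g("kinetics", "min_run", 5L),
              kineticsIntensity = g("kinetics", "intensity", "raw"),
              exportIntensity = g("output", "intensity", "corrected"),
              writeOverlays = g("output", "write_overlays", FALSE),
              overlayIds = g("output", "overlay_ids", TRUE),
              lifetimeBinMin = g("kinetics", "lifetime_bin_min", 2),
              sizeBinUm2 = g("kinetics", "size_bin_um2", 2))
}

#' Run the full analysis pipeline
#'
#' Preprocess, segment, track (planar or volumetric per the config) and
#' fit kinetics, writing the output bundle to the configured directory:
#' `tracks.csv`, `kinetics.csv`, `summary.csv`, optional per-frame
#' overlay PNGs, and `run_log.txt` (configuration fingerprint, versions,
#' per-stage counts). Outputs are deterministic for a fixed configuration
#' and seed; the seed is recorded in every CSV header comment. If any
#' stage fails, partial outputs are removed and the error is re-thrown
#' with a stage label.
#'
#' @param config a [runConfig()].
#' @return invisibly, a list with `tracks` (filtered
#'   [AdhesionTrackSet-class]), `allTracks`, `fits`, `summary`, `counts`
#'   and `paths`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "runConfig"))
    outDir <- config$outputDir
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    written <- character()
    stage <- "setup"
    result <- tryCatch({
        stage <- "read"
        stack <- if (is(config$input, "ImageStack")) config$input
            else if (config$mode == "3d")
                readStack(config$input, config$pixelSizeUm, config$dtS,
                          dzUm = config$dzUm, zCount = config$zCount,
                          pageOrder = config$pageOrder)
            else readStack(config$input, config$pixelSizeUm, config$dtS,
                           pageOrder = config$pageOrder)
        stage <- "segment+track"
        tr <- trackStack(stack, config$preprocess, config$segment,
                         config$track)
        tracks <- filterTracks(tr$tracks, config$track$minTrackLen)
        stage <- "kinetics"
        fits <- fitTrackKinetics(tracks, minRun = config$kineticsMinRun,
                                 intensity = config$kineticsIntensity,
                                 windows = config$kineticsWindows)
        summ <- if (nTracks(tracks) > 0)
            summarizeTracks(tracks, config$lifetimeBinMin,
                            config$sizeBinUm2) else NULL
        stage <- "export"
        cm <- c(sprintf("seed: %d", config$seed),
                sprintf("config: %s", configHash(config[setdiff(
                    names(config), c("input", "outputDir"))])))
        p <- file.path(outDir, "tracks.csv")
        writeTrackTable(tracks, p, intensity = config$exportIntensity,
                        comments = cm)
        written <- c(written, p)
        p <- file.path(outDir, "kinetics.csv")
        writeKineticsTable(fits, p, comments = cm)
        written <- c(written, p)
        p <- file.path(outDir, "summary.csv")
        sdf <- if (is.null(summ))
            data.frame(metric = "n_adhesions", value = 0) else
            data.frame(metric = c("n_adhesions", "mean_lifetime_min",
                                  "sem_lifetime_min", "mean_area_um2",
                                  "sem_area_um2"),
                       value = c(summ$nAdhesions, summ$meanLifetimeMin,
                                 summ$semLifetimeMin, summ$meanAreaUm2,
                                 summ$semAreaUm2))
        writeCsvDeterministic(sdf, p, cm)
        written <- c(written, p)
        if (config$writeOverlays && config$mode == "2d") {
            regionSets <- tr$regionSets
            ov <- writeOverlays(stack, regionSets, outDir, stem = "frame",
                                showIds = config$overlayIds)
            written <- c(written, ov)
        }
        logPath <- file.path(outDir, "run_log.txt")
        writeLines(c(
            sprintf("config_hash: %s", configHash(config[setdiff(
                names(config), c("input", "outputDir"))])),
            sprintf("seed: %d", config$seed),
            sprintf("r_version: %s", R.version.string),
            sprintf("package_version: %s",
                    as.character(utils::packageVersion("AdhesionDynamics"))),
            sprintf("mode: %s", config$mode),
            sprintf("frames: %d", nFrames(stack)),
            sprintf("regions_per_frame: %s",
                    paste(tr$counts, collapse = ",")),
            sprintf("total_regions: %d", sum(tr$counts)),
            sprintf("tracks_total: %d", nTracks(tr$tracks)),
            sprintf("tracks_reported: %d", nTracks(tracks)),
            sprintf("kinetics_fits: %d", nrow(fits))), logPath)
        written <- c(written, logPath)
        list(tracks = tracks, allTracks = tr$tracks, fits = fits,
             summary = summ, counts = tr$counts,
             paths = written)
    }, error = function(e) {
        unlink(written)
        stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)),
             call. = FALSE)
    })
    invisible(result)
}

#' Three-color temporal overlay
#'
#' Composites three timepoints into one RGB image: the earliest frame in
#' red, the middle in green, the latest in blue, each min-max normalized.
#' Stationary structures render white/gray, appearing structures
#' green/blue, disappearing ones red/purple.
#'
#' @param stack an [ImageStack-class].
#' @param t1,t2,t3 1-based frame indices, `t1 < t2 < t3`.
#' @param z 1-based z-plane to composite (volumetric stacks only).
#' @return `[y, x, 3]` RGB array in `[0, 1]`.
#' @export
temporalOverlay <- function(stack, t1, t2, t3, z = NULL) {
    stopifnot(is(stack, "ImageStack"))
    ts <- c(t1, t2, t3)
    if (any(ts < 1L) || any(ts > nFrames(stack)))
        stop("frame index out of range", call. = FALSE)
    if (!(t1 < t2 && t2 < t3))
        stop("need t1 < t2 < t3", call. = FALSE)
    grab <- function(t) {
        f <- if (isVolumetric(stack)) {
            if (is.null(z)) stop("z is required for a volumetric stack",
                                 call. = FALSE)
            getFrame(stack, t, z)
        } else getFrame(stack, t)
        normalize01(f)
    }
    out <- array(0, c(dim(grab(t1)), 3L))
    out[, , 1] <- grab(t1)
    out[, , 2] <- grab(t2)
    out[, , 3] <- grab(t3)
    out
}
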