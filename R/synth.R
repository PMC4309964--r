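#' @include io.R
NULL

## Run code with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    force(code)
}

#' Specify one synthetic adhesion blob
#'
#' A blob is an elliptical Gaussian spot with a linear centroid drift
#' (laterally and, for volumetric scenes, through z) and an exponential
#' peak-amplitude trajectory `A(t) = amplitude0 * exp(kPerMin * minutes
#' since birth)` - positive `kPerMin` emulates assembly, negative
#' disassembly, zero a static adhesion. The footprint is truncated at
#' 4 lateral sigma (3 sigma in z) so blobs have finite support.
#'
#' @param x0,y0 centroid at birth, 0-based pixels.
#' @param birthFrame first live frame (0-based; default 0).
#' @param deathFrame first frame after death (exclusive; `Inf` = lives to
#'   the movie end). Must exceed `birthFrame`.
#' @param driftX,driftY centroid drift, px per frame (default 0).
#' @param z0 centroid z-plane at birth (0-based, volumetric scenes).
#' @param driftZ z drift, planes per frame.
#' @param amplitude0 peak amplitude at birth (> 0).
#' @param kPerMin signed exponential rate, per minute (default 0).
#' @param sigmaXPx,sigmaYPx Gaussian footprint sigmas in px (default 2).
#' @param sigmaZPlanes Gaussian sigma along z in planes (default 0.5, so
#'   an adhesion spans about three 0.5-um planes).
#' @param thetaRad orientation of the x-sigma axis, radians (elongation
#'   along a fiber direction; default 0).
#' @return a list of class `blobSpec`.
#' @export
blobSpec <- function(x0, y0, birthFrame = 0L, deathFrame = Inf,
                     driftX = 0, driftY = 0, z0 = 0, driftZ = 0,
                     amplitude0 = 100, kPerMin = 0,
                     sigmaXPx = 2, sigmaYPx = 2, sigmaZPlanes = 0.5,
                     thetaRad = 0) {
    if (deathFrame <= birthFrame)
        stop("deathFrame must exceed birthFrame", call. = FALSE)
    if (amplitude0 <= 0) stop("amplitude0 must be > 0", call. = FALSE)
    if (sigmaXPx <= 0 || sigmaYPx <= 0 || sigmaZPlanes <= 0)
        stop("sigmas must be > 0", call. = FALSE)
    structure(as.list(environment()), class = "blobSpec")
}

#' Specify a synthetic scene
#'
#' Stack dimensions and calibration, the blob population, an uneven
#' background illumination model, and a camera-noise model. Defaults
#' mirror a typical adhesion-imaging regime: dt = 1 min (acquisitions run
#' at 45 s - 1 min intervals), dz = 0.5 um, 0.2 um/px; blob amplitudes
#' and footprints put areas in the ~1-12 um2 range; with a fixed seed the
#' rendered movie is bit-reproducible.
#'
#' @param width,height frame size in px.
#' @param nFrames number of timepoints.
#' @param blobs list of [blobSpec()].
#' @param pixelSizeUm um per px (default 0.2).
#' @param dtS frame interval, seconds (default 60).
#' @param nPlanes number of z-planes; `NULL` (default) for a planar
#'   scene.
#' @param dzUm z spacing, um (default 0.5; volumetric scenes).
#' @param background list: `constant` offset, `gradientX`/`gradientY`
#'   (linear illumination slope per px) and `parabolic` (quadratic bowl
#'   coefficient), modelling uneven illumination.
#' @param noiseSd Gaussian read-noise sd; `NA` (default) = 2% of the
#'   largest blob birth amplitude; 0 disables noise.
#' @param poisson also apply Poisson shot noise (default FALSE).
#' @param seed RNG seed for the noise (default 1).
#' @return a list of class `sceneSpec`.
#' @export
sceneSpec <- function(width, height, nFrames, blobs = list(),
                      pixelSizeUm = 0.2, dtS = 60, nPlanes = NULL,
                      dzUm = 0.5,
                      background = list(constant = 20, gradientX = 0,
                                        gradientY = 0, parabolic = 0),
                      noiseSd = NA_real_, poisson = FALSE, seed = 1L) {
    stopifnot(width >= 4, height >= 4, nFrames >= 1)
    for (b in blobs) stopifnot(inherits(b, "blobSpec"))
    bg <- utils::modifyList(list(constant = 20, gradientX = 0,
                                 gradientY = 0, parabolic = 0), background)
    if (is.na(noiseSd))
        noiseSd <- if (length(blobs))
            0.02 * max(vapply(blobs, function(b) b$amplitude0, numeric(1)))
        else 0
    structure(list(width = as.integer(width), height = as.integer(height),
                   nFrames = as.integer(nFrames), blobs = blobs,
                   pixelSizeUm = pixelSizeUm, dtS = dtS,
                   nPlanes = if (is.null(nPlanes)) NULL
                             else as.integer(nPlanes),
                   dzUm = dzUm, background = bg, noiseSd = noiseSd,
                   poisson = isTRUE(poisson), seed = as.integer(seed)),
              class = "sceneSpec")
}

## Blob state at (0-based) frame t; NULL when not live.
blobState <- function(b, t, dtS) {
    if (t < b$birthFrame || t >= b$deathFrame) return(NULL)
    age <- t - b$birthFrame
    list(x = b$x0 + b$driftX * age,
         y = b$y0 + b$driftY * age,
         z = b$z0 + b$driftZ * age,
         amp = b$amplitude0 * exp(b$kPerMin * age * dtS / 60))
}

## Lateral footprint of a blob with unit amplitude on the full frame
## (truncated at 4 sigma). Returns a height x width matrix.
blobFootprint <- function(b, cx, cy, width, height) {
    m <- matrix(0, height, width)
    rmax <- 4 * max(b$sigmaXPx, b$sigmaYPx)
    xs <- max(0, floor(cx - rmax)):min(width - 1, ceiling(cx + rmax))
    ys <- max(0, floor(cy - rmax)):min(height - 1, ceiling(cy + rmax))
    if (!length(xs) || !length(ys)) return(m)
    dx <- outer(rep(1, length(ys)), xs - cx)
    dy <- outer(ys - cy, rep(1, length(xs)))
    ct <- cos(b$thetaRad); st <- sin(b$thetaRad)
    u <- dx * ct + dy * st
    v <- -dx * st + dy * ct
    g <- exp(-(u^2 / (2 * b$sigmaXPx^2) + v^2 / (2 * b$sigmaYPx^2)))
    g[(u / (4 * b$sigmaXPx))^2 + (v / (4 * b$sigmaYPx))^2 > 1] <- 0
    m[ys + 1, xs + 1] <- g
    m
}

backgroundFrame <- function(scene) {
    bg <- scene$background
    w <- scene$width; h <- scene$height
    xs <- outer(rep(1, h), seq_len(w) - 1)
    ys <- outer(seq_len(h) - 1, rep(1, w))
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    bg$constant + bg$gradientX * xs + bg$gradientY * ys +
        bg$parabolic * (((xs - cx) / w)^2 + ((ys - cy) / h)^2)
}

## z weights of a blob at plane indices 0..(nPlanes-1), truncated at
## 3 sigma_z; membership = planes with weight >= 10% of the peak weight.
blobZWeights <- function(b, zc, nPlanes) {
    z <- seq_len(nPlanes) - 1
    w <- exp(-(z - zc)^2 / (2 * b$sigmaZPlanes^2))
    w[abs(z - zc) > 3 * b$sigmaZPlanes] <- 0
    w
}

#' Render a synthetic movie with exact ground truth
#'
#' Each frame is background + the sum of blob Gaussians + noise, clipped
#' at zero. Alongside the [ImageStack-class], exact ground-truth tables
#' are produced: per blob and timepoint the true centroid, footprint
#' area (pixels at or above half the peak amplitude), the blob's own
#' integrated intensity (volumetric scenes: the mean of per-plane
#' integrated intensities over its member z-planes, the z-averaging used
#' by the tracker), and per-blob kinetics (signed rate constant,
#' phase, and half-life ln(2)/|k|).
#'
#' @param scene a [sceneSpec()].
#' @return list with `stack` (an [ImageStack-class]) and `truth` (list:
#'   `tracks` data.frame with `truth_`-prefixed schema, `kinetics`
#'   data.frame).
#' @examples
#' sc <- sceneSpec(32, 32, 3,
#'                 blobs = list(blobSpec(x0 = 15, y0 = 15, kPerMin = 0.1)),
#'                 noiseSd = 0)
#' mov <- renderMovie(sc)
#' mov$truth$kinetics
#' @export
renderMovie <- function(scene) {
    stopifnot(inherits(scene, "sceneSpec"))
    vol <- !is.null(scene$nPlanes)
    w <- scene$width; h <- scene$height; nt <- scene$nFrames
    nz <- if (vol) scene$nPlanes else 1L
    bg <- backgroundFrame(scene)
    data <- if (vol) array(0, c(h, w, nz, nt)) else array(0, c(h, w, nt))
    truthRows <- list()
    for (t in seq_len(nt) - 1L) {
        planes <- lapply(seq_len(nz), function(z) bg)
        for (bi in seq_along(scene$blobs)) {
            b <- scene$blobs[[bi]]
            st <- blobState(b, t, scene$dtS)
            if (is.null(st)) next
            if (st$x < 0 || st$x > w - 1 || st$y < 0 || st$y > h - 1)
                stop("blob ", bi, " out of bounds at frame ", t,
                     call. = FALSE)
            fp <- blobFootprint(b, st$x, st$y, w, h)
            if (vol) {
                if (st$z < 0 || st$z > nz - 1)
                    stop("blob ", bi, " out of z range at frame ", t,
                         call. = FALSE)
                zw <- blobZWeights(b, st$z, nz)
                member <- which(zw >= 0.1 * max(zw)) - 1L
                perPlane <- vapply(member + 1L, function(z)
                    st$amp * zw[z] * sum(fp), numeric(1))
                for (z in seq_len(nz))
                    if (zw[z] > 0)
                        planes[[z]] <- planes[[z]] + st$amp * zw[z] * fp
                intensity <- mean(perPlane)
                zIdx <- sum((member) * zw[member + 1L]) /
                    sum(zw[member + 1L])
            } else {
                planes[[1L]] <- planes[[1L]] + st$amp * fp
                member <- integer()
                intensity <- st$amp * sum(fp)
                zIdx <- NA_real_
            }
            truthRows[[length(truthRows) + 1L]] <- data.frame(
                truth_id = bi, t_index = t,
                centroid_x_px = st$x, centroid_y_px = st$y,
                centroid_z_index = if (vol) st$z else NA_real_,
                z_planes = paste(member, collapse = ";"),
                area_um2 = sum(fp >= 0.5) * scene$pixelSizeUm^2,
                integrated_intensity = intensity,
                amplitude = st$amp)
        }
        for (z in seq_len(nz)) {
            fr <- planes[[z]]
            if (scene$noiseSd > 0 || scene$poisson) {
                fr <- withSeed(scene$seed + 7919L * t + 104729L * z, {
                    out <- fr
                    if (scene$poisson)
                        out <- matrix(stats::rpois(length(out),
                                                   pmax(out, 0)),
                                      nrow(out), ncol(out))
                    if (scene$noiseSd > 0)
                        out <- out + stats::rnorm(length(out),
                                                  sd = scene$noiseSd)
                    out
                })
            }
            fr <- pmax(fr, 0)
            if (vol) data[, , z, t + 1L] <- fr else data[, , t + 1L] <- fr
        }
    }
    tracks <- if (length(truthRows)) do.call(rbind, truthRows) else
        data.frame(truth_id = integer(), t_index = integer(),
                   centroid_x_px = numeric(), centroid_y_px = numeric(),
                   centroid_z_index = numeric(), z_planes = character(),
                   area_um2 = numeric(), integrated_intensity = numeric(),
                   amplitude = numeric())
    tracks <- tracks[order(tracks$truth_id, tracks$t_index), , drop = FALSE]
    rownames(tracks) <- NULL
    kin <- do.call(rbind, lapply(seq_along(scene$blobs), function(bi) {
        k <- scene$blobs[[bi]]$kPerMin
        data.frame(truth_id = bi, k_per_min = k,
                   phase = if (k > 0) "assembly"
                           else if (k < 0) "disassembly" else "static",
                   t_half_min = if (k != 0) log(2) / abs(k) else NA_real_)
    }))
    stack <- if (vol)
        ImageStack(data, scene$pixelSizeUm, scene$dtS, scene$dzUm)
    else ImageStack(data, scene$pixelSizeUm, scene$dtS)
    list(stack = stack, truth = list(tracks = tracks, kinetics = kin))
}

#' Render a movie containing a split event
#'
#' A parent blob lives until `splitFrame`, where two children appear at
#' the parent's current position plus the given offsets. The truth table
#' records which child remained closer to the parent (the expected
#' ID-keeper under the split rule), whether the offsets tie, and whether
#' the event is detectable (children at least 5 noise-sd above the
#' noise floor); undetectable events are marked for exclusion from
#' scoring.
#'
#' @param scene a [sceneSpec()] whose blob list is ignored.
#' @param parent a [blobSpec()] for the parent.
#' @param offsets 2x2 numeric matrix, rows = child (dx, dy) offsets in px
#'   from the parent centroid at the split.
#' @param splitFrame 0-based frame at which the children replace the
#'   parent.
#' @return list with `stack`, `truth` (as [renderMovie()]) plus
#'   `truth$split`: data.frame with `split_frame`, `keeper_child` (1 or
#'   2; NA on a tie), `tie`, `detectable`.
#' @export
renderSplitEvent <- function(scene, parent, offsets, splitFrame) {
    stopifnot(inherits(parent, "blobSpec"), nrow(offsets) == 2L,
              splitFrame > parent$birthFrame)
    stp <- blobState(parent, splitFrame - 1L, scene$dtS)
    if (is.null(stp)) stop("parent is not alive just before splitFrame",
                           call. = FALSE)
    parent2 <- parent
    parent2$deathFrame <- splitFrame
    mkChild <- function(off) {
        ch <- parent
        ch$birthFrame <- splitFrame
        ch$deathFrame <- Inf
        ch$x0 <- stp$x + parent$driftX + off[1]
        ch$y0 <- stp$y + parent$driftY + off[2]
        ch$amplitude0 <- stp$amp * exp(parent$kPerMin * scene$dtS / 60) / 2
        ch
    }
    scene$blobs <- list(parent2, mkChild(offsets[1, ]),
                        mkChild(offsets[2, ]))
    mov <- renderMovie(scene)
    d <- sqrt(rowSums(offsets^2))
    tie <- isTRUE(all.equal(d[1], d[2]))
    childAmp <- scene$blobs[[2]]$amplitude0
    detectable <- scene$noiseSd == 0 || childAmp >= 5 * scene$noiseSd
    mov$truth$split <- data.frame(
        split_frame = splitFrame,
        keeper_child = if (tie) NA_integer_ else which.min(d),
        tie = tie, detectable = detectable)
    mov
}

#' Render a volumetric (z-stack) movie
#'
#' [renderMovie()] for a scene with z-planes; provided as an explicit
#' entry point for 4D fixtures. The truth table's `z_planes` column
#' lists, per frame, the 0-based planes where the blob's plane amplitude
#' is at least 10% of its peak, and `integrated_intensity` is the
#' z-averaged integrated intensity over those member planes.
#'
#' @param scene a [sceneSpec()] with `nPlanes` set.
#' @return as [renderMovie()].
#' @export
renderZMovie <- function(scene) {
    if (is.null(scene$nPlanes))
        stop("scene has no z axis; set nPlanes", call. = FALSE)
    renderMovie(scene)
}
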