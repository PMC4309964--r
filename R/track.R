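#' @include segment.R
NULL

#' Tracking configuration
#'
#' @param maxLinkUm distance cap for frame-to-frame linking, micrometres
#'   (default 2). Candidate pairs farther apart than this are never
#'   matched; an adhesion jumping beyond the cap starts a new track.
#' @param zLinkRadiusUm lateral radius for merging regions in adjacent
#'   z-planes into one 3D adhesion (default 1; a 0.5 um z-step means an
#'   adhesion spans consecutive planes).
#' @param minTrackLen observations required to report a track (default 3).
#'   Applied at reporting time, not during linking.
#' @return a validated list of class `trackConfig`.
#' @export
trackConfig <- function(maxLinkUm = 2.0, zLinkRadiusUm = 1.0,
                        minTrackLen = 3L) {
    if (!is.finite(maxLinkUm) || maxLinkUm <= 0)
        stop("maxLinkUm must be > 0", call. = FALSE)
    if (!is.finite(zLinkRadiusUm) || zLinkRadiusUm <= 0)
        stop("zLinkRadiusUm must be > 0", call. = FALSE)
    if (!is.finite(minTrackLen) || minTrackLen < 1)
        stop("minTrackLen must be >= 1", call. = FALSE)
    structure(list(maxLinkUm = maxLinkUm, zLinkRadiusUm = zLinkRadiusUm,
                   minTrackLen = as.integer(minTrackLen)),
              class = "trackConfig")
}

## Greedy closest-first one-to-one matching between two point sets (um
## coordinates, rows = objects). Pairs beyond `cap` are excluded; ties are
## broken by lower previous index, then lower next index. Returns a
## two-column matrix (prev, next) of matched indices.
greedyMatch <- function(prevUm, nextUm, cap) {
    np <- nrow(prevUm); nn <- nrow(nextUm)
    if (np == 0L || nn == 0L)
        return(matrix(integer(), 0, 2,
                      dimnames = list(NULL, c("prev", "next"))))
    d <- matrix(0, np, nn)
    for (j in seq_len(ncol(prevUm)))
        d <- d + outer(prevUm[, j], nextUm[, j], "-")^2
    d <- sqrt(d)
    cand <- which(d <= cap, arr.ind = TRUE)
    if (nrow(cand) == 0L)
        return(matrix(integer(), 0, 2,
                      dimnames = list(NULL, c("prev", "next"))))
    ord <- order(d[cand], cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    usedP <- logical(np); usedN <- logical(nn)
    out <- matrix(integer(), 0, 2)
    for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (!usedP[i] && !usedN[j]) {
            usedP[i] <- TRUE; usedN[j] <- TRUE
            out <- rbind(out, c(i, j))
        }
    }
    dimnames(out) <- list(NULL, c("prev", "next"))
    out
}

#' Link adhesions between two consecutive frames
#'
#' Greedy nearest-neighbour matching on centroid Euclidean distance in
#' micrometres: the closest pair is matched first, each region is used at
#' most once, and pairs farther apart than `maxLinkUm` are never matched.
#' Unmatched previous regions are terminations; unmatched next regions
#' are births. Splits and merges resolve themselves under this rule: when
#' one parent has several candidate children, the closest child takes the
#' parent's identity and the others are births (see [resolveSplit()]);
#' symmetrically, when two parents converge on one child, the closer
#' parent continues and the other's track ends.
#'
#' @param regionsPrev,regionsNext [RegionSet-class] objects from
#'   consecutive frames of one movie.
#' @param maxLinkUm distance cap in micrometres.
#' @return list with `matches` (data.frame `prev_label`, `next_label`,
#'   `distance_um`), `births` (unmatched next labels) and `terminated`
#'   (unmatched prev labels).
#' @export
linkFrames <- function(regionsPrev, regionsNext, maxLinkUm = 2.0) {
    stopifnot(is(regionsPrev, "RegionSet"), is(regionsNext, "RegionSet"))
    ps <- pixelSize(regionsPrev)
    rp <- regionTable(regionsPrev); rn <- regionTable(regionsNext)
    pm <- cbind(rp$centroid_x_px, rp$centroid_y_px) * ps
    nm <- cbind(rn$centroid_x_px, rn$centroid_y_px) * ps
    m <- greedyMatch(pm, nm, maxLinkUm)
    dist <- if (nrow(m)) sqrt(rowSums((pm[m[, 1], , drop = FALSE] -
                                       nm[m[, 2], , drop = FALSE])^2))
            else numeric()
    list(matches = data.frame(prev_label = rp$label[m[, 1]],
                              next_label = rn$label[m[, 2]],
                              distance_um = dist),
         births = setdiff(rn$label, rn$label[m[, 2]]),
         terminated = setdiff(rp$label, rp$label[m[, 1]]))
}

#' Resolve a split event
#'
#' When an adhesion splits, the child that remained closest to the
#' parent's previous position keeps the parent's ID number; every other
#' child is assigned a new ID (a birth at that frame). Equidistant
#' children are resolved in favour of the lower label index.
#'
#' @param parentCentroidUm numeric vector, parent centroid in um.
#' @param childCentroidsUm matrix (one row per child) of child centroids
#'   in um.
#' @param childLabels integer labels of the children.
#' @return list with `keeper` (label inheriting the ID) and `newIds`
#'   (labels that receive fresh IDs).
#' @export
resolveSplit <- function(parentCentroidUm, childCentroidsUm, childLabels) {
    childCentroidsUm <- rbind(childCentroidsUm)
    stopifnot(nrow(childCentroidsUm) == length(childLabels))
    d <- sqrt(colSums((t(childCentroidsUm) - parentCentroidUm)^2))
    ord <- order(childLabels)  # tie-break: lower label index
    keep <- ord[which.min(d[ord])]
    list(keeper = childLabels[keep], newIds = childLabels[-keep])
}

## Per-timepoint detections in a unified schema used by the temporal
## linker for both planar and volumetric movies.
.objectColumns <- c("label", "x_um", "y_um", "z_um", "centroid_x_px",
                    "centroid_y_px", "centroid_z_index", "z_planes",
                    "area_um2", "integrated_intensity",
                    "integrated_intensity_raw")

regionsToObjects <- function(regions) {
    rt <- regionTable(regions)
    ps <- pixelSize(regions)
    data.frame(label = rt$label,
               x_um = rt$centroid_x_px * ps, y_um = rt$centroid_y_px * ps,
               z_um = rep(0, nrow(rt)),
               centroid_x_px = rt$centroid_x_px,
               centroid_y_px = rt$centroid_y_px,
               centroid_z_index = rep(NA_real_, nrow(rt)),
               z_planes = rep("", nrow(rt)),
               area_um2 = rt$area_um2,
               integrated_intensity = rt$integrated_intensity,
               integrated_intensity_raw = rt$integrated_intensity_raw)
}

## Temporal linker over a list of per-timepoint object tables.
linkObjects <- function(objectsByT, dtS, pixelSizeUm, dzUm, maxLinkUm) {
    nextId <- 1L
    obsList <- list()
    activeIds <- integer()   # parallel to previous frame's object rows
    prevObjs <- NULL
    for (t in seq_along(objectsByT)) {
        objs <- objectsByT[[t]]
        n <- nrow(objs)
        ids <- integer(n)
        if (t == 1L || is.null(prevObjs) || nrow(prevObjs) == 0L || n == 0L) {
            matched <- matrix(integer(), 0, 2)
        } else {
            pm <- as.matrix(prevObjs[, c("x_um", "y_um", "z_um")])
            nm <- as.matrix(objs[, c("x_um", "y_um", "z_um")])
            matched <- greedyMatch(pm, nm, maxLinkUm)
        }
        if (nrow(matched)) ids[matched[, 2]] <- activeIds[matched[, 1]]
        ## births: new IDs in label order (order of first appearance)
        for (i in seq_len(n)) {
            if (ids[i] == 0L) {
                ids[i] <- nextId
                nextId <- nextId + 1L
            }
        }
        if (n > 0) {
            o <- objs
            o$adhesion_id <- ids
            o$t_index <- t - 1L
            obsList[[length(obsList) + 1L]] <- o
        }
        activeIds <- ids
        prevObjs <- objs
    }
    obs <- if (length(obsList)) do.call(rbind, obsList) else
        cbind(data.frame(adhesion_id = integer(), t_index = integer()),
              stats::setNames(as.data.frame(
                  matrix(numeric(), 0, length(.objectColumns))),
                  .objectColumns))
    obs <- obs[, c("adhesion_id", "t_index", "centroid_x_px",
                   "centroid_y_px", "centroid_z_index", "z_planes",
                   "area_um2", "integrated_intensity",
                   "integrated_intensity_raw")]
    obs <- obs[order(obs$adhesion_id, obs$t_index), , drop = FALSE]
    rownames(obs) <- NULL
    new("AdhesionTrackSet", observations = obs, dtS = dtS,
        pixelSizeUm = pixelSizeUm, dzUm = dzUm)
}

#' Build adhesion tracks from per-frame regions
#'
#' Links consecutive frames with [linkFrames()] semantics and assigns
#' persistent adhesion IDs in order of first appearance (frame-major,
#' then label order). A region unmatched in the next frame ends its
#' track; there is no gap closing, so a missed detection terminates a
#' track and a redetection starts a new ID.
#'
#' @param regionSets list of [RegionSet-class], one per timepoint.
#' @param dtS seconds between frames.
#' @param maxLinkUm linking distance cap in micrometres (default 2).
#' @return an [AdhesionTrackSet-class].
#' @export
buildTracks <- function(regionSets, dtS, maxLinkUm = 2.0) {
    stopifnot(length(regionSets) >= 1L)
    ps <- pixelSize(regionSets[[1L]])
    objectsByT <- lapply(regionSets, regionsToObjects)
    linkObjects(objectsByT, dtS, ps, NA_real_, maxLinkUm)
}

#' Merge per-z-plane regions into 3D adhesions
#'
#' Adhesions are identified in each z-plane; regions in adjacent planes
#' whose lateral centroid distance is within `zLinkRadiusUm` belong to
#' the same adhesion (transitive closure across consecutive planes; only
#' adjacent planes are linked directly). Each 3D object reports the mean
#' of its member centroids, the mean of its member integrated intensities
#' (the z-averaged intensity), and the maximal single-plane area.
#'
#' @param regionSetsByZ list of [RegionSet-class], ordered by z, for one
#'   timepoint.
#' @param zLinkRadiusUm lateral merge radius in micrometres (default 1).
#' @return data.frame of 3D objects with centroid (px, plus 0-based
#'   `centroid_z_index`), `z_planes` (semicolon-joined 0-based planes),
#'   `area_um2`, `integrated_intensity`, `integrated_intensity_raw`.
#' @export
groupZ <- function(regionSetsByZ, zLinkRadiusUm = 1.0) {
    stopifnot(length(regionSetsByZ) >= 1L)
    ps <- pixelSize(regionSetsByZ[[1L]])
    nodes <- list()
    for (z in seq_along(regionSetsByZ)) {
        rt <- regionTable(regionSetsByZ[[z]])
        if (nrow(rt) > 0) {
            rt$z <- z
            nodes[[length(nodes) + 1L]] <- rt
        }
    }
    if (!length(nodes)) {
        return(stats::setNames(as.data.frame(
            matrix(numeric(), 0, length(.objectColumns))), .objectColumns))
    }
    nd <- do.call(rbind, nodes)
    nn <- nrow(nd)
    parent <- seq_len(nn)
    findRoot <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
    }
    for (a in seq_len(nn)) for (b in seq_len(nn)) {
        if (b > a && nd$z[b] - nd$z[a] == 1L) {
            dx <- (nd$centroid_x_px[a] - nd$centroid_x_px[b]) * ps
            dy <- (nd$centroid_y_px[a] - nd$centroid_y_px[b]) * ps
            if (sqrt(dx^2 + dy^2) <= zLinkRadiusUm) {
                ra <- findRoot(a); rb <- findRoot(b)
                if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
            }
        }
    }
    roots <- vapply(seq_len(nn), findRoot, integer(1))
    groups <- split(seq_len(nn), roots)
    ## deterministic object order: lowest z, then label, of each group
    firstKey <- vapply(groups, function(ix)
        min(nd$z[ix] * 1e6 + nd$label[ix]), numeric(1))
    groups <- groups[order(firstKey)]
    out <- do.call(rbind, lapply(seq_along(groups), function(g) {
        ix <- groups[[g]]
        data.frame(label = g,
                   x_um = mean(nd$centroid_x_px[ix]) * ps,
                   y_um = mean(nd$centroid_y_px[ix]) * ps,
                   z_um = NA_real_,  # filled by caller with dz
                   centroid_x_px = mean(nd$centroid_x_px[ix]),
                   centroid_y_px = mean(nd$centroid_y_px[ix]),
                   centroid_z_index = mean(nd$z[ix] - 1),
                   z_planes = paste(sort(nd$z[ix] - 1L), collapse = ";"),
                   area_um2 = max(nd$area_um2[ix]),
                   integrated_intensity = mean(nd$integrated_intensity[ix]),
                   integrated_intensity_raw =
                       mean(nd$integrated_intensity_raw[ix]))
    }))
    rownames(out) <- NULL
    out
}

#' Segment and track a whole movie
#'
#' The full detection-plus-tracking pipeline. Planar movies: each frame
#' is preprocessed and segmented, then regions are linked through time.
#' Volumetric movies: each z-plane of each timepoint is segmented, the
#' per-plane regions are merged into 3D adhesions with [groupZ()], and
#' the 3D objects are linked through time by nearest 3D centroid (lateral
#' distances in um, z via the z-step), so adhesions moving through
#' different focal planes keep one identity. The same split rule applies
#' in both modes.
#'
#' @param stack an [ImageStack-class].
#' @param preCfg a [preprocessConfig()].
#' @param segCfg a [segmentConfig()].
#' @param trkCfg a [trackConfig()].
#' @return list with `tracks` (an [AdhesionTrackSet-class] including all
#'   tracks; apply [filterTracks()] for reporting), `regionSets` (planar:
#'   per-frame [RegionSet-class]; volumetric: per-frame list over z), and
#'   `counts` (detected objects per timepoint).
#' @export
trackStack <- function(stack, preCfg = preprocessConfig(),
                       segCfg = segmentConfig(), trkCfg = trackConfig()) {
    stopifnot(is(stack, "ImageStack"))
    ps <- pixelSize(stack)
    if (!isVolumetric(stack)) {
        regionSets <- lapply(seq_len(nFrames(stack)), function(t)
            segmentFrame(getFrame(stack, t), ps, preCfg, segCfg)$regions)
        tracks <- buildTracks(regionSets, frameInterval(stack),
                              trkCfg$maxLinkUm)
        counts <- vapply(regionSets, nRegions, integer(1))
        return(list(tracks = tracks, regionSets = regionSets,
                    counts = counts))
    }
    dz <- zStep(stack)
    regionSets <- list()
    objectsByT <- list()
    for (t in seq_len(nFrames(stack))) {
        byZ <- lapply(seq_len(nPlanes(stack)), function(z)
            segmentFrame(getFrame(stack, t, z), ps, preCfg, segCfg)$regions)
        regionSets[[t]] <- byZ
        objs <- groupZ(byZ, trkCfg$zLinkRadiusUm)
        if (nrow(objs) > 0) objs$z_um <- objs$centroid_z_index * dz
        objectsByT[[t]] <- objs
    }
    tracks <- linkObjects(objectsByT, frameInterval(stack), ps, dz,
                          trkCfg$maxLinkUm)
    counts <- vapply(objectsByT, nrow, integer(1))
    list(tracks = tracks, regionSets = regionSets, counts = counts)
}

#' Drop short tracks
#'
#' Reporting filter: keeps tracks with at least `minObservations`
#' observed timepoints (default 3, matching [trackConfig()]).
#'
#' @param tracks an [AdhesionTrackSet-class].
#' @param minObservations minimum observations per reported track.
#' @return a filtered [AdhesionTrackSet-class] (IDs are preserved, not
#'   renumbered).
#' @export
filterTracks <- function(tracks, minObservations = 3L) {
    stopifnot(is(tracks, "AdhesionTrackSet"))
    obs <- tracks@observations
    n <- table(obs$adhesion_id)
    keep <- as.integer(names(n)[n >= minObservations])
    obs <- obs[obs$adhesion_id %in% keep, , drop = FALSE]
    rownames(obs) <- NULL
    methods::initialize(tracks, observations = obs)
}

#' @describeIn AdhesionTrackSet-class number of tracks.
#' @param x an `AdhesionTrackSet`.
#' @export
setMethod("nTracks", "AdhesionTrackSet", function(x)
    length(unique(x@observations$adhesion_id)))

#' @describeIn AdhesionTrackSet-class sorted vector of adhesion IDs.
#' @export
setMethod("trackIds", "AdhesionTrackSet", function(x)
    sort(unique(x@observations$adhesion_id)))

#' @describeIn AdhesionTrackSet-class the observation data.frame; with
#'   `id`, only that adhesion's time-ordered observations.
#' @param ... for `observations`: optional `id`, one adhesion ID.
#' @export
setMethod("observations", "AdhesionTrackSet", function(x, id = NULL) {
    obs <- x@observations
    if (!is.null(id)) obs <- obs[obs$adhesion_id == id, , drop = FALSE]
    obs[order(obs$adhesion_id, obs$t_index), , drop = FALSE]
})

#' @describeIn AdhesionTrackSet-class named vector of lifetimes in
#'   minutes: (number of observed frames) x dt. A single-frame detection
#'   has lifetime dt, not zero ("total time an adhesion was observed").
#' @export
setMethod("lifetimes", "AdhesionTrackSet", function(x) {
    obs <- x@observations
    n <- table(obs$adhesion_id)
    out <- as.numeric(n) * x@dtS / 60
    names(out) <- names(n)
    out[order(as.integer(names(out)))]
})

#' @describeIn AdhesionTrackSet-class frame interval in seconds.
#' @export
setMethod("frameInterval", "AdhesionTrackSet", function(x) x@dtS)

#' @describeIn AdhesionTrackSet-class micrometres per pixel.
#' @export
setMethod("pixelSize", "AdhesionTrackSet", function(x) x@pixelSizeUm)

setMethod("show", "AdhesionTrackSet", function(object) {
    obs <- object@observations
    cat(sprintf("AdhesionTrackSet: %d tracks, %d observations, dt = %.4g s\n",
                nTracks(object), nrow(obs), object@dtS))
    if (nrow(obs) > 0) {
        lt <- lifetimes(object)
        cat(sprintf("  lifetimes: %.3g-%.3g min (mean %.3g)\n",
                    min(lt), max(lt), mean(lt)))
    }
})

#' Convert tracks to the export schema
#'
#' Produces the fixed-column track table
#' (`adhesion_id,t_index,time_min,centroid_x_px,centroid_y_px,centroid_z_index,area_um2,integrated_intensity`)
#' used by [writeTrackTable()].
#'
#' @param tracks an [AdhesionTrackSet-class].
#' @param intensity `"corrected"` (default) or `"raw"` integrated
#'   intensities.
#' @return data.frame in the export schema.
#' @export
asTrackTable <- function(tracks, intensity = c("corrected", "raw")) {
    intensity <- match.arg(intensity)
    obs <- observations(tracks)
    data.frame(adhesion_id = obs$adhesion_id,
               t_index = obs$t_index,
               time_min = obs$t_index * tracks@dtS / 60,
               centroid_x_px = obs$centroid_x_px,
               centroid_y_px = obs$centroid_y_px,
               centroid_z_index = obs$centroid_z_index,
               area_um2 = obs$area_um2,
               integrated_intensity = if (intensity == "corrected")
                   obs$integrated_intensity else obs$integrated_intensity_raw)
}
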