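#' @include track.R
NULL

#' An intensity trace for one turnover phase
#'
#' A per-adhesion series of background-corrected integrated intensities
#' covering one assembly or disassembly phase. The semilog fit needs at
#' least 3 points and strictly positive intensities (log-domain
#' requirement).
#'
#' @param timesMin strictly increasing times in minutes.
#' @param intensities positive intensities, same length.
#' @param phase `"assembly"` or `"disassembly"`.
#' @param adhesionId optional source adhesion ID.
#' @return a list of class `intensityTrace`.
#' @export
intensityTrace <- function(timesMin, intensities,
                           phase = c("assembly", "disassembly"),
                           adhesionId = NA_integer_) {
    phase <- match.arg(phase)
    if (length(timesMin) != length(intensities))
        stop("times and intensities differ in length", call. = FALSE)
    if (length(timesMin) < 3L)
        stop("a trace needs at least 3 points", call. = FALSE)
    if (any(diff(timesMin) <= 0))
        stop("times must be strictly increasing", call. = FALSE)
    if (any(!is.finite(intensities)) || any(intensities <= 0))
        stop("intensities must be positive and finite", call. = FALSE)
    structure(list(timesMin = as.numeric(timesMin),
                   intensities = as.numeric(intensities),
                   phase = phase,
                   adhesionId = as.integer(adhesionId)),
              class = "intensityTrace")
}

#' Subtract an adjacent background region
#'
#' Mirrors the manual workflow: a duplicate region placed adjacent to the
#' adhesion (inside the cell, adhesion-free) provides a background series
#' that is subtracted timepoint by timepoint. Timepoints whose corrected
#' value is not positive cannot enter the log-domain fit; they are
#' flagged invalid and excluded downstream rather than aborting the
#' trace.
#'
#' @param adhesionIntensities,backgroundIntensities equal-length numeric
#'   series measured over regions of the same area.
#' @return list with `values` (the differences) and `valid` (logical,
#'   TRUE where the difference is > 0).
#' @examples
#' subtractAdjacentBackground(c(110, 120), c(10, 10))
#' @export
subtractAdjacentBackground <- function(adhesionIntensities,
                                       backgroundIntensities) {
    if (length(adhesionIntensities) != length(backgroundIntensities))
        stop("series lengths differ", call. = FALSE)
    v <- adhesionIntensities - backgroundIntensities
    list(values = v, valid = is.finite(v) & v > 0)
}

## Closed path shared by both phases: OLS of y on t, packaged as a
## KineticsFit. y is ln(I/I0) (assembly) or ln(I0/I) (disassembly).
fitSemilog <- function(trace, phase) {
    if (!inherits(trace, "intensityTrace"))
        stop("expected an intensityTrace", call. = FALSE)
    if (trace$phase != phase)
        stop(sprintf("trace phase is '%s', expected '%s'",
                     trace$phase, phase), call. = FALSE)
    t <- trace$timesMin
    I0 <- trace$intensities[1L]
    y <- if (phase == "assembly") log(trace$intensities / I0)
         else log(I0 / trace$intensities)
    fit <- stats::lm(y ~ t)
    k <- unname(stats::coef(fit)[2L])
    b <- unname(stats::coef(fit)[1L])
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
    ## numerical guard: a perfect fit can give 1 + eps / tiny negatives
    if (is.finite(r2)) r2 <- min(max(r2, 0), 1)
    conv <- is.finite(k) && k > 0
    new("KineticsFit",
        adhesionId = trace$adhesionId,
        phase = phase,
        kPerMin = k,
        tHalfMin = if (conv) log(2) / k else NA_real_,
        rSquared = r2,
        intercept = b,
        nPoints = length(t),
        tStartMin = t[1L],
        converged = conv)
}

#' Fit assembly kinetics
#'
#' Ordinary least-squares line through (t, ln(I/I0)), where I0 is the
#' first intensity of the trace: the slope is the apparent first-order
#' assembly rate constant k (per minute) and t1/2 = ln(2)/k. A
#' non-positive slope means the trace is not assembling; the fit is
#' returned flagged (`converged = FALSE`, no half-life) rather than
#' reporting a negative t1/2.
#'
#' @param trace an [intensityTrace()] with phase `"assembly"`.
#' @return a [KineticsFit-class].
#' @examples
#' t <- 0:10
#' tr <- intensityTrace(t, 100 * exp(0.1 * t), "assembly")
#' fitAssembly(tr)
#' @export
fitAssembly <- function(trace) fitSemilog(trace, "assembly")

#' Fit disassembly kinetics
#'
#' Ordinary least-squares line through (t, ln(I0/I)); for a decaying
#' trace the slope k is positive and t1/2 = ln(2)/k. Algebraically,
#' ln(I0/I) = -ln(I/I0), so this equals the assembly fit of the inverted
#' trace with the slope sign flipped.
#'
#' @param trace an [intensityTrace()] with phase `"disassembly"`.
#' @return a [KineticsFit-class].
#' @export
fitDisassembly <- function(trace) fitSemilog(trace, "disassembly")

#' Half-life from a rate constant
#'
#' t1/2 = ln(2)/k, where k is the apparent first-order rate constant in
#' inverse minutes.
#'
#' @param kPerMin rate constant (> 0), per minute.
#' @return half-life in minutes.
#' @examples
#' halfLife(0.1)  # ~6.93 min
#' @export
halfLife <- function(kPerMin) {
    if (any(!is.finite(kPerMin)) || any(kPerMin <= 0))
        stop("k must be > 0", call. = FALSE)
    log(2) / kPerMin
}

## Centered 3-point moving average; ends use the available 2-point window.
movingAverage3 <- function(x) {
    n <- length(x)
    if (n < 3L) return(x)
    out <- x
    out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
    out[1] <- mean(x[1:2])
    out[n] <- mean(x[(n - 1):n])
    out
}

## Maximal runs (as start/end indices) where diffs satisfy `ok`.
maximalRuns <- function(ok) {
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values)
    ## a run over diffs i..j covers points i..(j+1)
    data.frame(start = starts[keep], end = ends[keep] + 1L)
}

#' Extract monotone assembly/disassembly phases from a track
#'
#' Automated stand-in for the manual selection of assembling and
#' disassembling adhesions: the intensity series is smoothed with a
#' 3-point moving average and maximal runs of at least `minRun`
#' consecutive timepoints with monotonically non-decreasing (assembly) or
#' non-increasing (disassembly) smoothed intensity are emitted as traces
#' (of the original, unsmoothed intensities). Where candidate runs
#' overlap in more than a shared endpoint, the longer run wins. For full
#' parity with a manual workflow, supply explicit windows to
#' [fitTrackKinetics()] instead.
#'
#' @param timesMin observation times in minutes.
#' @param intensities positive intensity series.
#' @param minRun minimum run length in timepoints (default 5).
#' @param adhesionId optional source adhesion ID carried into the traces.
#' @return list of [intensityTrace()] objects (possibly empty).
#' @export
extractPhases <- function(timesMin, intensities, minRun = 5L,
                          adhesionId = NA_integer_) {
    stopifnot(length(timesMin) == length(intensities))
    n <- length(timesMin)
    if (n < max(3L, minRun)) return(list())
    s <- movingAverage3(intensities)
    d <- diff(s)
    up <- maximalRuns(d >= 0); up$phase <- rep("assembly", nrow(up))
    dn <- maximalRuns(d <= 0); dn$phase <- rep("disassembly", nrow(dn))
    cands <- rbind(up, dn)
    cands <- cands[cands$end - cands$start + 1L >= minRun, , drop = FALSE]
    if (nrow(cands) == 0L) return(list())
    len <- cands$end - cands$start + 1L
    ord <- order(-len, cands$start,
                 match(cands$phase, c("assembly", "disassembly")))
    cands <- cands[ord, , drop = FALSE]
    accepted <- cands[0, , drop = FALSE]
    for (i in seq_len(nrow(cands))) {
        ov <- vapply(seq_len(nrow(accepted)), function(j) {
            lo <- max(cands$start[i], accepted$start[j])
            hi <- min(cands$end[i], accepted$end[j])
            max(0L, hi - lo + 1L)
        }, integer(1))
        if (all(ov <= 1L)) accepted <- rbind(accepted, cands[i, ])
    }
    accepted <- accepted[order(accepted$start), , drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(accepted))) {
        ix <- accepted$start[i]:accepted$end[i]
        ix <- ix[intensities[ix] > 0]
        if (length(ix) >= max(3L, minRun))
            out[[length(out) + 1L]] <- intensityTrace(
                timesMin[ix], intensities[ix], accepted$phase[i], adhesionId)
    }
    out
}

#' Fit turnover kinetics for every track
#'
#' Runs phase extraction (or uses explicit per-adhesion windows) and fits
#' assembly/disassembly kinetics for each phase of each track.
#'
#' @param tracks an [AdhesionTrackSet-class].
#' @param minRun minimum phase length in timepoints (default 5).
#' @param intensity `"raw"` (default) or `"corrected"`: which integrated
#'   intensity series to fit. Raw-image intensities preserve exponential
#'   amplitude changes exactly; the division-corrected image compresses
#'   them (see the package vignette).
#' @param windows optional manual phase windows, a data.frame with
#'   columns `adhesion_id`, `phase`, `t_start_index`, `t_end_index`
#'   (inclusive 0-based frame indices), bypassing automatic extraction.
#' @return data.frame with columns `adhesion_id`, `phase`, `t_start_min`,
#'   `n_points`, `k_per_min`, `t_half_min`, `r_squared`, `intercept`.
#'   Non-converged fits keep their slope with `t_half_min = NA`.
#' @export
fitTrackKinetics <- function(tracks, minRun = 5L,
                             intensity = c("raw", "corrected"),
                             windows = NULL) {
    stopifnot(is(tracks, "AdhesionTrackSet"))
    intensity <- match.arg(intensity)
    col <- if (intensity == "raw") "integrated_intensity_raw"
           else "integrated_intensity"
    rows <- list()
    addFit <- function(f) {
        rows[[length(rows) + 1L]] <<- data.frame(
            adhesion_id = f@adhesionId, phase = f@phase,
            t_start_min = f@tStartMin, n_points = f@nPoints,
            k_per_min = f@kPerMin, t_half_min = f@tHalfMin,
            r_squared = f@rSquared, intercept = f@intercept)
    }
    for (id in trackIds(tracks)) {
        obs <- observations(tracks, id = id)
        tm <- obs$t_index * tracks@dtS / 60
        I <- obs[[col]]
        traces <- if (is.null(windows)) {
            extractPhases(tm, I, minRun = minRun, adhesionId = id)
        } else {
            w <- windows[windows$adhesion_id == id, , drop = FALSE]
            lapply(seq_len(nrow(w)), function(i) {
                ix <- which(obs$t_index >= w$t_start_index[i] &
                            obs$t_index <= w$t_end_index[i] & I > 0)
                if (length(ix) < 3L)
                    stop("manual window for adhesion ", id,
                         " has fewer than 3 valid points", call. = FALSE)
                intensityTrace(tm[ix], I[ix], w$phase[i], id)
            })
        }
        for (tr in traces)
            addFit(if (tr$phase == "assembly") fitAssembly(tr)
                   else fitDisassembly(tr))
    }
    if (!length(rows))
        return(data.frame(adhesion_id = integer(), phase = character(),
                          t_start_min = numeric(), n_points = integer(),
                          k_per_min = numeric(), t_half_min = numeric(),
                          r_squared = numeric(), intercept = numeric()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Summarize a tracked movie
#'
#' Adhesion-level summaries: count, mean and SEM of lifetime (occupancy
#' time) and of adhesion size (a track's mean area over its
#' observations), lifetime and size histograms (as percent of total
#' adhesions per bin), and mean size per lifetime bin. With a single
#' track the SEMs are reported as `NA`.
#'
#' @param tracks an [AdhesionTrackSet-class] with at least one track.
#' @param lifetimeBinMin lifetime histogram bin width in minutes
#'   (default 2).
#' @param sizeBinUm2 size histogram bin width in um2 (default 2).
#' @return list of class `trackSummary`: `nAdhesions`, `meanLifetimeMin`,
#'   `semLifetimeMin`, `meanAreaUm2`, `semAreaUm2`, `lifetimeHist`,
#'   `sizeHist`, `sizeVsLifetime`.
#' @export
summarizeTracks <- function(tracks, lifetimeBinMin = 2, sizeBinUm2 = 2) {
    stopifnot(is(tracks, "AdhesionTrackSet"))
    if (nTracks(tracks) == 0L) stop("no tracks to summarize", call. = FALSE)
    lt <- lifetimes(tracks)
    obs <- tracks@observations
    size <- vapply(split(obs$area_um2, obs$adhesion_id), mean, numeric(1))
    size <- size[order(as.integer(names(size)))]
    sem <- function(x) if (length(x) > 1L)
        stats::sd(x) / sqrt(length(x)) else NA_real_
    histTable <- function(x, width) {
        edges <- seq(0, width * ceiling(max(x) / width + 1e-12), by = width)
        if (length(edges) < 2L) edges <- c(0, width)
        cnt <- tabulate(findInterval(x, edges, left.open = TRUE),
                        length(edges) - 1L)
        data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
                   count = cnt, percent = 100 * cnt / length(x))
    }
    ltEdges <- seq(0, lifetimeBinMin * ceiling(max(lt) / lifetimeBinMin),
                   by = lifetimeBinMin)
    bin <- findInterval(lt, ltEdges, left.open = TRUE)
    svl <- do.call(rbind, lapply(sort(unique(bin)), function(b)
        data.frame(lifetime_bin_lo = ltEdges[b],
                   lifetime_bin_hi = ltEdges[b] + lifetimeBinMin,
                   n_tracks = sum(bin == b),
                   mean_size_um2 = mean(size[bin == b]))))
    structure(list(nAdhesions = length(lt),
                   meanLifetimeMin = mean(lt), semLifetimeMin = sem(lt),
                   meanAreaUm2 = mean(size), semAreaUm2 = sem(size),
                   lifetimeHist = histTable(lt, lifetimeBinMin),
                   sizeHist = histTable(size, sizeBinUm2),
                   sizeVsLifetime = svl),
              class = "trackSummary")
}

#' @export
print.trackSummary <- function(x, ...) {
    fmtSem <- function(m, s) if (is.na(s)) sprintf("%.3g (SEM n/a)", m)
                             else sprintf("%.3g +/- %.2g", m, s)
    cat("Adhesion summary\n")
    cat("  n adhesions:   ", x$nAdhesions, "\n")
    cat("  lifetime (min):", fmtSem(x$meanLifetimeMin, x$semLifetimeMin), "\n")
    cat("  size (um2):    ", fmtSem(x$meanAreaUm2, x$semAreaUm2), "\n")
    invisible(x)
}

#' Write a kinetics table to CSV
#'
#' Fixed header
#' `adhesion_id,phase,t_start_min,n_points,k_per_min,t_half_min,r_squared,intercept`,
#' sorted by adhesion then phase start; deterministic bytes.
#'
#' @param fits data.frame from [fitTrackKinetics()].
#' @param path output CSV path.
#' @param comments leading `# ` comment lines.
#' @return the path, invisibly.
#' @export
writeKineticsTable <- function(fits, path, comments = character()) {
    need <- c("adhesion_id", "phase", "t_start_min", "n_points",
              "k_per_min", "t_half_min", "r_squared", "intercept")
    if (!identical(names(fits), need))
        stop("kinetics table must have columns: ",
             paste(need, collapse = ","), call. = FALSE)
    fits <- fits[order(fits$adhesion_id, fits$t_start_min), , drop = FALSE]
    writeCsvDeterministic(fits, path, comments)
}

setMethod("show", "KineticsFit", function(object) {
    cat(sprintf("KineticsFit (%s%s): ", object@phase,
                if (is.na(object@adhesionId)) ""
                else sprintf(", adhesion %d", object@adhesionId)))
    if (object@converged)
        cat(sprintf("k = %.4g /min, t1/2 = %.4g min, R2 = %.4g (n = %d)\n",
                    object@kPerMin, object@tHalfMin, object@rSquared,
                    object@nPoints))
    else
        cat(sprintf("not converted (slope %.4g <= 0, n = %d)\n",
                    object@kPerMin, object@nPoints))
})
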