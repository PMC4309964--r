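#' @include utils.R
NULL

#' Preprocessing configuration
#'
#' Parameters for the noise-suppression and illumination-correction steps
#' applied to every frame (and every z-plane) before segmentation.
#'
#' `lowpassKernelPx` should be large relative to the adhesion diameter so
#' the low-pass image estimates the background rather than the adhesions
#' themselves; with adhesions of a few um2 sampled at 0.1-0.3 um/px, the
#' 51 px default is comfortably above adhesion scale. This is guidance,
#' not enforced.
#'
#' @param gaussianSigmaPx Gaussian smoothing sigma in pixels (>= 0;
#'   0 disables smoothing). Default 1.
#' @param lowpassKernelPx side of the uniform (box-mean) low-pass filter,
#'   odd integer >= 3. Default 51.
#' @param epsilon guard added to the low-pass image before division.
#'   `NA` (default) means 1e-6 x max(frame), resolved per frame so the
#'   correction stays invariant to global intensity rescaling.
#' @param lowpassType `"box"` (default) or `"gaussian"` (sigma =
#'   lowpassKernelPx / 4) for the low-pass stage.
#' @return a validated list of class `preprocessConfig`.
#' @examples
#' cfg <- preprocessConfig(gaussianSigmaPx = 1, lowpassKernelPx = 25)
#' @export
preprocessConfig <- function(gaussianSigmaPx = 1.0, lowpassKernelPx = 51L,
                             epsilon = NA_real_,
                             lowpassType = c("box", "gaussian")) {
    lowpassType <- match.arg(lowpassType)
    if (!is.finite(gaussianSigmaPx) || gaussianSigmaPx < 0)
        stop("gaussianSigmaPx must be >= 0", call. = FALSE)
    stopIfNotOddKernel(lowpassKernelPx, "lowpass kernel")
    if (!is.na(epsilon) && (!is.finite(epsilon) || epsilon <= 0))
        stop("epsilon must be positive (or NA for the per-frame default)",
             call. = FALSE)
    structure(list(gaussianSigmaPx = gaussianSigmaPx,
                   lowpassKernelPx = as.integer(lowpassKernelPx),
                   epsilon = epsilon,
                   lowpassType = lowpassType),
              class = "preprocessConfig")
}

#' Gaussian smoothing of a frame
#'
#' Separable Gaussian convolution with mirror (symmetric) border padding.
#' The kernel is truncated at 4 sigma and normalized to unit sum, so
#' constant regions are preserved exactly. `sigmaPx = 0` returns the input
#' unchanged.
#'
#' @param frame 2D numeric matrix `[y, x]`.
#' @param sigmaPx Gaussian sigma in pixels (>= 0).
#' @return smoothed matrix, same shape.
#' @examples
#' f <- matrix(0, 9, 9); f[5, 5] <- 1
#' g <- gaussianSmooth(f, 1)
#' sum(g)  # unit mass preserved
#' @export
gaussianSmooth <- function(frame, sigmaPx) {
    frame <- asFrameMatrix(frame)
    if (length(sigmaPx) != 1L || !is.finite(sigmaPx) || sigmaPx < 0)
        stop("sigmaPx must be a single number >= 0", call. = FALSE)
    if (sigmaPx == 0) return(frame)
    r <- max(1L, as.integer(ceiling(4 * sigmaPx)))
    w <- stats::dnorm(seq(-r, r), sd = sigmaPx)
    w <- w / sum(w)
    n <- nrow(frame); p <- ncol(frame)
    ## columns pass (along y)
    pad <- frame[reflectIndex(seq(1L - r, n + r), n), , drop = FALSE]
    out <- matrix(0, n, p)
    for (u in seq_along(w))
        out <- out + w[u] * pad[u:(u + n - 1L), , drop = FALSE]
    ## rows pass (along x)
    pad <- out[, reflectIndex(seq(1L - r, p + r), p), drop = FALSE]
    out <- matrix(0, n, p)
    for (u in seq_along(w))
        out <- out + w[u] * pad[, u:(u + p - 1L), drop = FALSE]
    out
}

#' Uniform (box) mean filter
#'
#' Sliding-window mean of side `kernelPx` with mirror border padding,
#' computed with a summed-area table. This is both the low-pass stage of
#' the illumination correction and the local-mean image of the adaptive
#' threshold.
#'
#' @param frame 2D numeric matrix.
#' @param kernelPx window side, odd integer >= 3 (may exceed the frame
#'   size; mirroring tiles as needed).
#' @return matrix of local means, same shape.
#' @export
boxMean <- function(frame, kernelPx) {
    frame <- asFrameMatrix(frame)
    k <- stopIfNotOddKernel(kernelPx, "box-mean kernel")
    r <- (k - 1L) %/% 2L
    pad <- padReflect(frame, r)
    ## summed-area table with a zero first row/column
    S <- rbind(0, apply(pad, 2, cumsum))
    S <- cbind(0, t(apply(S, 1, cumsum)))
    n <- nrow(frame); p <- ncol(frame)
    i1 <- seq_len(n); i2 <- i1 + k - 1L
    j1 <- seq_len(p); j2 <- j1 + k - 1L
    (S[i2 + 1L, j2 + 1L, drop = FALSE] - S[i1, j2 + 1L, drop = FALSE] -
     S[i2 + 1L, j1, drop = FALSE] + S[i1, j1, drop = FALSE]) / (k * k)
}

#' Correct uneven background illumination
#'
#' Divides the (already smoothed) frame by a low-pass filtered version of
#' itself, plus a small guard epsilon. Background regions map to values
#' near 1 and bright structures to values above 1, flattening slow
#' illumination gradients. Because numerator and denominator scale
#' together, the output is invariant to global multiplicative rescaling of
#' the input (up to epsilon effects).
#'
#' @param frame smoothed 2D matrix.
#' @param cfg a [preprocessConfig()].
#' @return corrected matrix, same shape.
#' @examples
#' f <- matrix(100, 16, 16)
#' cc <- correctIllumination(f, preprocessConfig(lowpassKernelPx = 5))
#' range(cc)  # ~1 everywhere
#' @export
correctIllumination <- function(frame, cfg = preprocessConfig()) {
    frame <- asFrameMatrix(frame)
    eps <- if (is.na(cfg$epsilon)) {
        m <- max(frame)
        if (m > 0) 1e-6 * m else 1e-12
    } else cfg$epsilon
    lp <- if (cfg$lowpassType == "box") {
        boxMean(frame, cfg$lowpassKernelPx)
    } else {
        gaussianSmooth(frame, cfg$lowpassKernelPx / 4)
    }
    frame / (lp + eps)
}

#' Smooth and illumination-correct one frame
#'
#' Applies [gaussianSmooth()] then [correctIllumination()], the
#' frame-level preprocessing used by the full pipeline.
#'
#' @param frame raw 2D frame.
#' @param cfg a [preprocessConfig()].
#' @return list with elements `smoothed` and `corrected`.
#' @export
preprocessFrame <- function(frame, cfg = preprocessConfig()) {
    sm <- gaussianSmooth(frame, cfg$gaussianSigmaPx)
    list(smoothed = sm, corrected = correctIllumination(sm, cfg))
}
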