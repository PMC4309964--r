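#' @include AllClasses.R
NULL

## Mirror (symmetric, edge-repeating) index folding: maps any integer
## position, arbitrarily far outside 1..n, onto 1..n. Period is 2n:
## ... 2 1 | 1 2 .. n | n .. 2 1 | 1 2 ...
## Works for padding wider than the image, which happens routinely when a
## 51-px low-pass kernel meets a small frame.
reflectIndex <- function(i, n) {
    if (n == 1L) return(rep(1L, length(i)))
    j <- (i - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
}

## Pad a matrix by py rows / px cols on each side with mirrored content.
padReflect <- function(m, py, px = py) {
    ri <- reflectIndex(seq(1L - py, nrow(m) + py), nrow(m))
    ci <- reflectIndex(seq(1L - px, ncol(m) + px), ncol(m))
    m[ri, ci, drop = FALSE]
}

## Shift a matrix by (dy, dx), filling vacated cells.
shiftMat <- function(m, dy, dx, fill = 0) {
    n <- nrow(m); p <- ncol(m)
    out <- matrix(fill, n, p)
    ys <- max(1, 1 + dy):min(n, n + dy)
    xs <- max(1, 1 + dx):min(p, p + dx)
    if (length(ys) && length(xs))
        out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
    out
}

## Min-max normalize to [0,1]; a constant matrix maps to all zeros.
normalize01 <- function(m) {
    r <- range(m)
    if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0
}

stopIfNotOddKernel <- function(k, what = "kernel") {
    if (length(k) != 1L || !is.finite(k) || k < 3 || k %% 2 != 1)
        stop(what, " size must be an odd integer >= 3, got ", k,
             call. = FALSE)
    invisible(as.integer(k))
}

asFrameMatrix <- function(frame) {
    if (!is.matrix(frame)) stop("frame must be a 2D matrix", call. = FALSE)
    storage.mode(frame) <- "double"
    frame
}

## 3x5 bitmap digits for ID overlays (1 = lit pixel), row-major strings.
.digitFont <- local({
    rows <- list(
        "0" = c("111", "101", "101", "101", "111"),
        "1" = c("010", "110", "010", "010", "111"),
        "2" = c("111", "001", "111", "100", "111"),
        "3" = c("111", "001", "111", "001", "111"),
        "4" = c("101", "101", "111", "001", "001"),
        "5" = c("111", "100", "111", "001", "111"),
        "6" = c("111", "100", "111", "101", "111"),
        "7" = c("111", "001", "010", "010", "010"),
        "8" = c("111", "101", "111", "101", "111"),
        "9" = c("111", "101", "111", "001", "111"))
    lapply(rows, function(r)
        matrix(as.integer(unlist(strsplit(r, ""))) , 5, 3, byrow = TRUE))
})

## Stamp an integer onto an RGB array [y,x,3] near (y0, x0), 1-based.
## Digits are 3x5 with a 1-px gap; pixels outside the image are clipped.
drawNumber <- function(rgb, value, y0, x0, col = c(1, 1, 0)) {
    digits <- strsplit(as.character(as.integer(value)), "")[[1]]
    x <- as.integer(round(x0))
    y <- as.integer(round(y0))
    for (d in digits) {
        bm <- .digitFont[[d]]
        for (r in seq_len(5)) for (cc in seq_len(3)) {
            if (bm[r, cc] == 1L) {
                yy <- y + r - 1L; xx <- x + cc - 1L
                if (yy >= 1 && yy <= dim(rgb)[1] &&
                    xx >= 1 && xx <= dim(rgb)[2])
                    rgb[yy, xx, ] <- col
            }
        }
        x <- x + 4L
    }
    rgb
}

## Format numerics for CSV output: plain integers stay integral, reals get
## up to 10 significant digits (comfortably beyond the 6 the tables
## guarantee), NA becomes an empty field. Deterministic across runs.
formatCsvValue <- function(x) {
    if (is.integer(x)) {
        out <- as.character(x)
    } else if (is.numeric(x)) {
        out <- vapply(x, function(v) {
            if (!is.finite(v)) return("")
            if (v == round(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
            sprintf("%.10g", v)
        }, character(1))
    } else {
        out <- as.character(x)
    }
    out[is.na(x)] <- ""
    out
}

writeCsvDeterministic <- function(df, path, comments = character()) {
    con <- file(path, open = "wb")  # binary: byte-identical across platforms
    on.exit(close(con))
    for (cm in comments) writeLines(paste0("# ", cm), con, sep = "\n")
    writeLines(paste(names(df), collapse = ","), con, sep = "\n")
    if (nrow(df) > 0) {
        cols <- lapply(df, formatCsvValue)
        writeLines(do.call(paste, c(cols, sep = ",")), con, sep = "\n")
    }
    invisible(path)
}
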