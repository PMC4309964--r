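# Independent brute-force reference implementations used as oracles.
# Deliberately naive (explicit loops, no shared code with the package)
# so they stand on their own.

# Mirror folding of an out-of-range index onto 1..n, by walking.
oracleFold <- function(i, n) {
    while (i < 1 || i > n) {
        if (i < 1) i <- 1 - i      # reflect about 0.5: 0 -> 1, -1 -> 2
        if (i > n) i <- 2 * n - i + 1
    }
    i
}

# Direct O(n^2 k^2) 2D convolution with mirror padding.
oracleConvolve <- function(frame, kernel) {
    n <- nrow(frame); p <- ncol(frame)
    kr <- (nrow(kernel) - 1) / 2; kc <- (ncol(kernel) - 1) / 2
    out <- matrix(0, n, p)
    for (i in seq_len(n)) for (j in seq_len(p)) {
        acc <- 0
        for (a in -kr:kr) for (b in -kc:kc) {
            ii <- oracleFold(i + a, n)
            jj <- oracleFold(j + b, p)
            acc <- acc + kernel[a + kr + 1, b + kc + 1] * frame[ii, jj]
        }
        out[i, j] <- acc
    }
    out
}

oracleBoxMean <- function(frame, k) {
    oracleConvolve(frame, matrix(1 / (k * k), k, k))
}

oracleGaussianKernel <- function(sigma) {
    r <- max(1L, as.integer(ceiling(4 * sigma)))
    w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    w <- w / sum(w)
    outer(w, w)
}

oracleGaussianSmooth <- function(frame, sigma) {
    oracleConvolve(frame, oracleGaussianKernel(sigma))
}

oracleCorrectIllumination <- function(frame, kernelPx, epsilon) {
    frame / (oracleBoxMean(frame, kernelPx) + epsilon)
}

oracleLocalThreshold <- function(frame, kernelPx, offset) {
    frame > oracleBoxMean(frame, kernelPx) + offset
}

# Queue-based flood fill labeling, raster scan order.
oracleLabel <- function(mask, connectivity = 8) {
    n <- nrow(mask); p <- ncol(mask)
    lab <- matrix(0L, n, p)
    nb <- if (connectivity == 4)
        list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    else
        list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
             c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
    cur <- 0L
    for (i in seq_len(n)) for (j in seq_len(p)) {
        if (mask[i, j] && lab[i, j] == 0L) {
            cur <- cur + 1L
            queue <- list(c(i, j))
            lab[i, j] <- cur
            while (length(queue) > 0) {
                q <- queue[[1]]; queue <- queue[-1]
                for (s in nb) {
                    y <- q[1] + s[1]; x <- q[2] + s[2]
                    if (y >= 1 && y <= n && x >= 1 && x <= p &&
                        mask[y, x] && lab[y, x] == 0L) {
                        lab[y, x] <- cur
                        queue[[length(queue) + 1]] <- c(y, x)
                    }
                }
            }
        }
    }
    lab
}

oracleFilterSmall <- function(mask, pixelSizeUm, minAreaUm2, connectivity) {
    lab <- oracleLabel(mask, connectivity)
    keep <- matrix(FALSE, nrow(mask), ncol(mask))
    if (max(lab) == 0) return(keep)
    for (l in seq_len(max(lab))) {
        px <- sum(lab == l)
        if (px * pixelSizeUm^2 >= minAreaUm2) keep[lab == l] <- TRUE
    }
    keep
}

# Exhaustive between-class-variance scan over all midpoints between
# sorted unique values; returns the best cut value.
oracleOtsu <- function(values) {
    u <- sort(unique(values))
    best <- -Inf; thr <- u[1]
    for (i in seq_len(length(u) - 1)) {
        cand <- (u[i] + u[i + 1]) / 2
        lo <- values[values < cand]; hi <- values[values >= cand]
        w0 <- length(lo); w1 <- length(hi)
        bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
        if (bcv > best) {
            best <- bcv
            thr <- cand
        }
    }
    thr
}

# Exhaustive assignment: among pairings under the cap that match the
# maximum number of pairs, the one with minimal total distance.
# Returns a 2-column matrix (prev, next).
oracleAssignment <- function(prevUm, nextUm, cap) {
    np <- nrow(prevUm); nn <- nrow(nextUm)
    d <- matrix(Inf, np, nn)
    for (i in seq_len(np)) for (j in seq_len(nn))
        d[i, j] <- sqrt(sum((prevUm[i, ] - nextUm[j, ])^2))
    best <- NULL; bestN <- -1L; bestCost <- Inf
    # enumerate all injective partial assignments via recursion
    recurse <- function(i, used, pairs, cost) {
        if (i > np) {
            n <- nrow(pairs)
            if (n > bestN || (n == bestN && cost < bestCost)) {
                best <<- pairs; bestN <<- n; bestCost <<- cost
            }
            return(invisible())
        }
        recurse(i + 1L, used, pairs, cost)  # leave i unmatched
        for (j in seq_len(nn)) {
            if (!used[j] && d[i, j] <= cap) {
                u <- used; u[j] <- TRUE
                recurse(i + 1L, u, rbind(pairs, c(i, j)), cost + d[i, j])
            }
        }
    }
    recurse(1L, rep(FALSE, nn), matrix(integer(), 0, 2), 0)
    best
}

# Closed-form OLS slope/intercept (Sxy/Sxx), independent of lm().
oracleOls <- function(x, y) {
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Exhaustive monotone-run scan: longest run of >= minRun points whose
# consecutive smoothed values are all non-decreasing (dir = 1) or
# non-increasing (dir = -1).
oracleMonotoneRuns <- function(s, minRun, dir) {
    n <- length(s)
    runs <- list()
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
        ok <- TRUE
        for (i in a:(b - 1))
            if (dir * (s[i + 1] - s[i]) < 0) { ok <- FALSE; break }
        if (ok && b - a + 1 >= minRun) {
            maximal <- TRUE
            if (a > 1 && dir * (s[a] - s[a - 1]) >= 0) maximal <- FALSE
            if (b < n && dir * (s[b + 1] - s[b]) >= 0) maximal <- FALSE
            if (maximal) runs[[length(runs) + 1]] <- c(a, b)
        }
    }
    runs
}

randomFrame <- function(ny = NULL, nx = NULL, lo = 0, hi = 100) {
    if (is.null(ny)) ny <- sample(4:16, 1)
    if (is.null(nx)) nx <- sample(4:16, 1)
    matrix(runif(ny * nx, lo, hi), ny, nx)
}
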