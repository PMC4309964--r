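makeTrackSet <- function(obsList, dtS = 60) {
    obs <- do.call(rbind, lapply(seq_along(obsList), function(i) {
        o <- obsList[[i]]
        data.frame(adhesion_id = i, t_index = seq_along(o$area) - 1L,
                   centroid_x_px = 0, centroid_y_px = 0,
                   centroid_z_index = NA_real_, z_planes = "",
                   area_um2 = o$area,
                   integrated_intensity = o$I,
                   integrated_intensity_raw = o$I)
    }))
    new("AdhesionTrackSet", observations = obs, dtS = dtS,
        pixelSizeUm = 0.2, dzUm = NA_real_)
}

test_that("adjacent-background subtraction flags non-positive points", {
    r <- subtractAdjacentBackground(c(110, 120), c(10, 10))
    expect_equal(r$values, c(100, 110))
    expect_true(all(r$valid))

    same <- subtractAdjacentBackground(c(50, 60, 70), c(50, 60, 70))
    expect_false(any(same$valid))

    zero <- subtractAdjacentBackground(c(5, 6), c(0, 0))
    expect_equal(zero$values, c(5, 6))

    expect_error(subtractAdjacentBackground(1:3, 1:2), "length")
})

test_that("noiseless exponentials are recovered exactly", {
    t <- 0:10
    fa <- fitAssembly(intensityTrace(t, 100 * exp(0.1 * t), "assembly"))
    expect_equal(fa@kPerMin, 0.1, tolerance = 1e-12)
    expect_equal(fa@rSquared, 1, tolerance = 1e-12)
    expect_equal(fa@tHalfMin, log(2) / 0.1, tolerance = 1e-12)
    expect_true(fa@converged)

    t2 <- seq(0, 28, by = 2)
    fd <- fitDisassembly(intensityTrace(t2, 500 * exp(-0.05 * t2),
                                        "disassembly"))
    expect_equal(fd@kPerMin, 0.05, tolerance = 1e-12)
    expect_equal(fd@tHalfMin, log(2) / 0.05, tolerance = 1e-10)
    expect_equal(fd@rSquared, 1, tolerance = 1e-12)

    ## t_half * k = ln(2) across a grid of rates
    for (k in c(0.01, 0.05, 0.2, 0.7, 1)) {
        f <- fitAssembly(intensityTrace(0:6, 10 * exp(k * (0:6)),
                                        "assembly"))
        expect_equal(f@kPerMin, k, tolerance = 1e-10)
        expect_equal(f@tHalfMin * f@kPerMin, log(2), tolerance = 1e-12)
    }
})

test_that("degenerate traces are flagged, not converted", {
    fc <- fitAssembly(intensityTrace(0:5, rep(40, 6), "assembly"))
    expect_false(fc@converged)
    expect_equal(fc@kPerMin, 0)
    expect_true(is.na(fc@tHalfMin))

    expect_error(intensityTrace(0:1, c(1, 2), "assembly"), "3 points")
    expect_error(intensityTrace(0:3, c(1, 2, -1, 3), "assembly"),
                 "positive")
    expect_error(fitAssembly(intensityTrace(0:3, exp(0:3), "disassembly")),
                 "phase")
})

test_that("noisy fits equal the closed-form OLS oracle", {
    set.seed(21)
    t <- seq(0, 14)
    I <- 100 * exp(0.2 * t) * exp(rnorm(15, sd = 0.05))
    f <- fitAssembly(intensityTrace(t, I, "assembly"))
    o <- oracleOls(t, log(I / I[1]))
    expect_equal(f@kPerMin, unname(o["slope"]), tolerance = 1e-10)
    expect_equal(f@intercept, unname(o["intercept"]), tolerance = 1e-10)
})

test_that("disassembly is the mirrored assembly fit", {
    set.seed(22)
    t <- 0:9
    I <- 300 * exp(-0.12 * t) * exp(rnorm(10, sd = 0.03))
    fd <- fitDisassembly(intensityTrace(t, I, "disassembly"))
    ## inverted trace I0^2 / I turns decay into growth with the same k
    fa <- fitAssembly(intensityTrace(t, I[1]^2 / I, "assembly"))
    expect_equal(fd@kPerMin, fa@kPerMin, tolerance = 1e-12)
    expect_equal(fd@rSquared, fa@rSquared, tolerance = 1e-12)
})

test_that("kinetics are invariant to intensity rescaling", {
    set.seed(23)
    t <- 0:11
    I <- 80 * exp(0.15 * t) * exp(rnorm(12, sd = 0.04))
    f1 <- fitAssembly(intensityTrace(t, I, "assembly"))
    for (c in c(1e-3, 7, 1e4)) {
        f2 <- fitAssembly(intensityTrace(t, c * I, "assembly"))
        expect_equal(f2@kPerMin, f1@kPerMin, tolerance = 1e-12)
        expect_equal(f2@tHalfMin, f1@tHalfMin, tolerance = 1e-12)
        expect_equal(f2@rSquared, f1@rSquared, tolerance = 1e-12)
    }
})

test_that("half-life follows t1/2 = ln(2)/k", {
    expect_equal(halfLife(log(2)), 1)
    expect_equal(halfLife(0.1), 6.931472, tolerance = 1e-6)
    expect_error(halfLife(0), "> 0")
    expect_error(halfLife(-0.1), "> 0")
})

test_that("phase extraction finds monotone runs and rejects noise", {
    t <- 0:9
    rising <- exp(0.2 * t)
    ph <- extractPhases(t, rising, minRun = 5)
    expect_length(ph, 1)
    expect_equal(ph[[1]]$phase, "assembly")
    expect_length(ph[[1]]$timesMin, 10)

    updown <- c(exp(0.3 * (0:5)), exp(0.3 * 5) * exp(-0.25 * (1:6)))
    ph2 <- extractPhases(seq_along(updown) - 1, updown, minRun = 5)
    expect_length(ph2, 2)
    expect_setequal(vapply(ph2, `[[`, "", "phase"),
                    c("assembly", "disassembly"))

    set.seed(24)
    noise <- 100 * exp(rnorm(12, sd = 0.05))
    ph3 <- extractPhases(0:11, noise, minRun = 6)
    ## cross-check against the exhaustive monotone-run oracle on the
    ## same smoothed series
    s <- AdhesionDynamics:::movingAverage3(noise)
    nOracle <- length(oracleMonotoneRuns(s, 6, 1)) +
        length(oracleMonotoneRuns(s, 6, -1))
    expect_equal(length(ph3), nOracle)
    expect_length(ph3, 0)
})

test_that("track summaries report counts, SEMs and histograms", {
    ## lifetimes 4 and 6 min at dt = 60 s
    ts <- makeTrackSet(list(list(area = rep(2, 4), I = exp(1:4)),
                            list(area = rep(4, 6), I = exp(6:1))))
    s <- summarizeTracks(ts)
    expect_equal(s$nAdhesions, 2L)
    expect_equal(s$meanLifetimeMin, 5)
    expect_equal(s$semLifetimeMin, 1)      # sd({4,6})/sqrt(2) = 1
    expect_equal(s$meanAreaUm2, 3)
    expect_equal(sum(s$lifetimeHist$count), 2)
    expect_equal(sum(s$lifetimeHist$percent), 100)
    expect_equal(sum(s$sizeVsLifetime$n_tracks), 2)

    one <- makeTrackSet(list(list(area = rep(5, 4), I = exp(1:4))))
    s1 <- summarizeTracks(one)
    expect_equal(s1$meanLifetimeMin, 4)
    expect_true(is.na(s1$semLifetimeMin))
})

test_that("manual windows bypass automatic phase extraction", {
    t <- 0:11
    I <- c(100 * exp(0.2 * (0:6)), 100 * exp(0.2 * 6) * exp(-0.1 * (1:5)))
    ts <- makeTrackSet(list(list(area = rep(2, 12), I = I)))
    win <- data.frame(adhesion_id = 1L, phase = "assembly",
                      t_start_index = 0L, t_end_index = 6L)
    fits <- fitTrackKinetics(ts, windows = win)
    expect_equal(nrow(fits), 1L)
    expect_equal(fits$k_per_min, 0.2, tolerance = 1e-10)
    expect_equal(fits$n_points, 7L)
})
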