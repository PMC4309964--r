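test_that("empty and static scenes render exactly", {
    sc <- sceneSpec(16, 16, 3, background = list(constant = 7),
                    noiseSd = 0)
    mov <- renderMovie(sc)
    expect_true(all(mov$stack@data == 7))
    expect_equal(nrow(mov$truth$tracks), 0L)

    st <- sceneSpec(32, 32, 4,
                    blobs = list(blobSpec(x0 = 16, y0 = 16,
                                          amplitude0 = 100)),
                    background = list(constant = 5), noiseSd = 0)
    movS <- renderMovie(st)
    ii <- movS$truth$tracks$integrated_intensity
    expect_true(all(abs(ii - ii[1]) < 1e-9))
    expect_equal(movS$truth$kinetics$k_per_min, 0)
    expect_equal(movS$truth$kinetics$phase, "static")
    ## frames identical when nothing moves or grows
    expect_equal(movS$stack@data[, , 1], movS$stack@data[, , 4])
})

test_that("exponential amplitude gives the analytic half-life in truth", {
    sc <- sceneSpec(32, 32, 5,
                    blobs = list(blobSpec(x0 = 16, y0 = 16,
                                          amplitude0 = 100, kPerMin = 0.1)),
                    noiseSd = 0)
    mov <- renderMovie(sc)
    expect_equal(mov$truth$kinetics$t_half_min, log(2) / 0.1,
                 tolerance = 1e-12)
    expect_equal(mov$truth$kinetics$phase, "assembly")
    amp <- mov$truth$tracks$amplitude
    expect_equal(amp, 100 * exp(0.1 * (0:4)), tolerance = 1e-12)
})

test_that("a fixed seed reproduces the movie bit for bit", {
    mk <- function() renderMovie(sceneSpec(
        24, 24, 4,
        blobs = list(blobSpec(x0 = 12, y0 = 12, amplitude0 = 200)),
        noiseSd = 4, seed = 99))
    a <- mk(); b <- mk()
    expect_identical(a$stack@data, b$stack@data)
    expect_identical(a$truth$tracks, b$truth$tracks)
    ## different seed, different noise
    c <- renderMovie(sceneSpec(
        24, 24, 4,
        blobs = list(blobSpec(x0 = 12, y0 = 12, amplitude0 = 200)),
        noiseSd = 4, seed = 100))
    expect_false(identical(a$stack@data, c$stack@data))
})

test_that("rendered mass matches the analytic Gaussian integral", {
    b <- blobSpec(x0 = 24, y0 = 20, amplitude0 = 150, sigmaXPx = 2.2,
                  sigmaYPx = 1.6, thetaRad = 0.4)
    sc <- sceneSpec(48, 48, 1, blobs = list(b),
                    background = list(constant = 10), noiseSd = 0)
    fr <- getFrame(renderMovie(sc)$stack, 1)
    mass <- sum(fr) - 10 * length(fr)
    analytic <- 150 * 2 * pi * 2.2 * 1.6
    expect_lt(abs(mass - analytic) / analytic, 0.005)
})

test_that("split events record the expected ID keeper", {
    base <- sceneSpec(48, 48, 6, background = list(constant = 10),
                      noiseSd = 0)
    parent <- blobSpec(x0 = 24, y0 = 24, amplitude0 = 300, sigmaXPx = 1.6)
    ev <- renderSplitEvent(base, parent,
                           offsets = rbind(c(1, 0), c(5, 0)),
                           splitFrame = 3L)
    expect_equal(ev$truth$split$keeper_child, 1L)
    expect_false(ev$truth$split$tie)
    expect_true(ev$truth$split$detectable)
    ## parent dies at the split; children are born there
    t2 <- ev$truth$tracks
    expect_equal(max(t2$t_index[t2$truth_id == 1]), 2L)
    expect_equal(min(t2$t_index[t2$truth_id == 2]), 3L)

    sym <- renderSplitEvent(base, parent,
                            offsets = rbind(c(0, 3), c(0, -3)),
                            splitFrame = 3L)
    expect_true(sym$truth$split$tie)
    expect_true(is.na(sym$truth$split$keeper_child))

    noisy <- sceneSpec(48, 48, 6, background = list(constant = 10),
                       noiseSd = 200)
    dim <- renderSplitEvent(noisy, blobSpec(x0 = 24, y0 = 24,
                                            amplitude0 = 100,
                                            sigmaXPx = 1.6),
                            offsets = rbind(c(1, 0), c(4, 0)),
                            splitFrame = 3L)
    expect_false(dim$truth$split$detectable)
})

test_that("z-membership follows the 10% amplitude cutoff", {
    b <- blobSpec(x0 = 16, y0 = 16, z0 = 3, amplitude0 = 200,
                  sigmaZPlanes = 0.5)
    sc <- sceneSpec(32, 32, 1, blobs = list(b), nPlanes = 7,
                    background = list(constant = 0), noiseSd = 0)
    mov <- renderZMovie(sc)
    expect_equal(mov$truth$tracks$z_planes, "2;3;4")
    expect_equal(mov$truth$tracks$centroid_z_index, 3)
    ## z-averaged intensity = mean over the three member planes
    w <- exp(-c(1, 0, 1) / (2 * 0.25))
    fr <- getFrame(mov$stack, 1, 4)       # center plane (0-based 3)
    expect_equal(mov$truth$tracks$integrated_intensity,
                 sum(fr) * mean(c(w[1], 1, w[3])), tolerance = 1e-9)

    drift <- blobSpec(x0 = 16, y0 = 16, z0 = 1, driftZ = 1,
                      amplitude0 = 200)
    scd <- sceneSpec(32, 32, 4, blobs = list(drift), nPlanes = 7,
                     background = list(constant = 0), noiseSd = 0)
    td <- renderZMovie(scd)$truth$tracks
    expect_equal(td$centroid_z_index, 1:4)

    expect_error(renderZMovie(sceneSpec(16, 16, 2)), "nPlanes")
})

test_that("tracking quality does not degrade as SNR rises", {
    mkNoisy <- function(sd) {
        blobs <- list(blobSpec(x0 = 12, y0 = 12, amplitude0 = 250,
                               sigmaXPx = 1.7),
                      blobSpec(x0 = 36, y0 = 36, amplitude0 = 250,
                               sigmaXPx = 1.7))
        sc <- sceneSpec(48, 48, 6, blobs = blobs,
                        background = list(constant = 40), noiseSd = sd,
                        seed = 31)
        mov <- renderMovie(sc)
        tr <- trackStack(mov$stack, synthPreCfg(), synthSegCfg(),
                         trackConfig())
        scoreTracking(tr$tracks, mov$truth$tracks)
    }
    scores <- vapply(c(40, 10, 0.5), mkNoisy, logical(1))
    ## once tracking succeeds at some noise level it keeps succeeding
    ## at every lower level
    firstGood <- match(TRUE, scores)
    if (!is.na(firstGood))
        expect_true(all(scores[firstGood:length(scores)]))
    expect_true(scores[3])   # near-noiseless must succeed
})
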