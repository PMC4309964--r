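# Minimal RegionSet fixture: one single-pixel region per row of `xy`
# (centroids set explicitly, label image kept consistent).
makeRS <- function(xy, ps = 1, intensity = NULL) {
    xy <- rbind(xy)
    n <- nrow(xy)
    if (is.null(intensity)) intensity <- rep(1, n)
    lab <- matrix(0L, max(n, 2), max(n, 2))
    for (i in seq_len(n)) lab[i, 1] <- i
    reg <- data.frame(label = seq_len(n), n_pixels = 1L, area_um2 = ps^2,
                      centroid_x_px = xy[, 1], centroid_y_px = xy[, 2],
                      integrated_intensity = intensity,
                      integrated_intensity_raw = intensity)
    new("RegionSet", labels = lab, regions = reg[seq_len(n), , drop = FALSE],
        pixelSizeUm = ps)
}

emptyRS <- function(ps = 1)
    labelAndMeasure(matrix(FALSE, 2, 2), matrix(0, 2, 2), ps)

test_that("frame linking matches nearest neighbours under the cap", {
    a <- makeRS(rbind(c(3, 4), c(10, 2)))
    idlink <- linkFrames(a, a, maxLinkUm = 2)
    expect_equal(idlink$matches$prev_label, idlink$matches$next_label)
    expect_length(idlink$births, 0)
    expect_length(idlink$terminated, 0)
    expect_true(all(idlink$matches$distance_um == 0))

    prev <- makeRS(c(0, 0))
    nxt <- makeRS(rbind(c(0, 1), c(0, 5)))
    lk <- linkFrames(prev, nxt, maxLinkUm = 100)
    expect_equal(lk$matches$prev_label, 1L)
    expect_equal(lk$matches$next_label, 1L)   # the closer candidate
    expect_equal(lk$births, 2L)

    lk2 <- linkFrames(prev, emptyRS(), maxLinkUm = 2)
    expect_equal(nrow(lk2$matches), 0L)
    expect_equal(lk2$terminated, 1L)

    ## pairs beyond the cap are never matched
    far <- linkFrames(makeRS(c(0, 0)), makeRS(c(30, 0)), maxLinkUm = 2)
    expect_equal(nrow(far$matches), 0L)
    expect_equal(far$births, 1L)
})

test_that("split rule: closest child keeps the parent's ID", {
    sp <- resolveSplit(c(10, 10), rbind(c(10, 11), c(10, 16)), c(1L, 2L))
    expect_equal(sp$keeper, 1L)
    expect_equal(sp$newIds, 2L)

    tie <- resolveSplit(c(5, 5), rbind(c(5, 7), c(5, 3)), c(1L, 2L))
    expect_equal(tie$keeper, 1L)     # equidistant: lower label wins

    single <- resolveSplit(c(1, 1), rbind(c(2, 1)), 7L)
    expect_equal(single$keeper, 7L)
    expect_length(single$newIds, 0)
})

test_that("tracks carry IDs by first appearance, lifetimes by occupancy", {
    ## one blob present in all 10 frames, dt = 60 s -> lifetime 10 min
    rs <- lapply(1:10, function(t) makeRS(c(5, 5)))
    tr <- buildTracks(rs, dtS = 60)
    expect_equal(nTracks(tr), 1L)
    expect_equal(unname(lifetimes(tr)), 10)

    ## present frames 0-4 only -> 5 observations, lifetime 5 dt
    rs2 <- c(lapply(1:5, function(t) makeRS(c(5, 5))),
             lapply(1:5, function(t) emptyRS()))
    tr2 <- buildTracks(rs2, dtS = 45)
    expect_equal(nrow(observations(tr2)), 5L)
    expect_equal(unname(lifetimes(tr2)), 5 * 45 / 60)

    ## two never-overlapping blobs get distinct IDs
    rs3 <- c(lapply(1:3, function(t) makeRS(c(2, 2))),
             list(emptyRS()),
             lapply(1:3, function(t) makeRS(c(2, 2))))
    tr3 <- buildTracks(rs3, dtS = 60)
    expect_equal(nTracks(tr3), 2L)
    expect_equal(trackIds(tr3), 1:2)
    ## a single-frame gap ends the first track (no gap closing)
    expect_equal(max(observations(tr3, id = 1)$t_index), 2)
    expect_equal(min(observations(tr3, id = 2)$t_index), 4)
})

test_that("every surviving region lands in exactly one observation", {
    for (seed in c(101, 102)) {
        sc <- makeTrackingScene(seed, nFrames = 6L, nBlobsRange = c(4L, 9L))
        mov <- renderMovie(sc)
        tr <- trackStack(mov$stack, synthPreCfg(), synthSegCfg(),
                         trackConfig())
        expect_equal(nrow(observations(tr$tracks)), sum(tr$counts))
        ## each ID appears at most once per timepoint
        obs <- observations(tr$tracks)
        expect_false(anyDuplicated(paste(obs$adhesion_id, obs$t_index)) > 0)
    }
})

test_that("greedy matching tracks the exhaustive min-sum assignment", {
    set.seed(15)
    agree <- 0L; trials <- 200L
    for (i in seq_len(trials)) {
        ## consecutive-frame instances: next = prev displaced, with
        ## occasional births and deaths
        np <- sample(1:4, 1)
        p <- matrix(runif(np * 2, 0, 10), np, 2)
        q <- p + matrix(rnorm(np * 2, sd = 0.8), np, 2)
        if (runif(1) < 0.3 && np > 1) q <- q[-sample(np, 1), , drop = FALSE]
        if (runif(1) < 0.3) q <- rbind(q, runif(2, 0, 10))
        cap <- 4
        g <- AdhesionDynamics:::greedyMatch(p, q, cap)
        o <- oracleAssignment(p, q, cap)
        same <- nrow(g) == nrow(o) &&
            (nrow(g) == 0 ||
             identical(g[order(g[, 1]), , drop = FALSE],
                       {colnames(o) <- c("prev", "next")
                        o[order(o[, 1]), , drop = FALSE]}))
        agree <- agree + same
    }
    expect_gte(agree / trials, 0.95)

    ## exact whenever spacing > 2 x displacement
    for (i in 1:50) {
        n <- sample(2:4, 1)
        base <- cbind(seq_len(n) * 5, rep(0, n))   # spacing 5
        disp <- matrix(runif(n * 2, -1, 1), n, 2)  # |disp| < 2.5/... safe
        q <- base + disp
        g <- AdhesionDynamics:::greedyMatch(base, q, cap = 4)
        expect_equal(nrow(g), n)
        expect_equal(g[, "prev"], g[, "next"])
    }
})

test_that("z-grouping merges adjacent planes and averages intensities", {
    planes <- c(lapply(1:3, function(z) emptyRS(ps = 0.2)),
                list(makeRS(c(10, 10), ps = 0.2, intensity = 100),
                     makeRS(c(10, 10), ps = 0.2, intensity = 200),
                     makeRS(c(10, 10), ps = 0.2, intensity = 300)),
                list(emptyRS(ps = 0.2)))
    obj <- groupZ(planes, zLinkRadiusUm = 1)
    expect_equal(nrow(obj), 1L)
    expect_equal(obj$integrated_intensity, 200)  # mean of member planes
    expect_equal(obj$z_planes, "3;4;5")
    expect_equal(obj$centroid_z_index, 4)

    ## single-plane adhesion keeps its own measurements
    one <- c(lapply(1:2, function(z) emptyRS(ps = 0.2)),
             list(makeRS(c(4, 4), ps = 0.2, intensity = 55)),
             lapply(1:2, function(z) emptyRS(ps = 0.2)))
    o1 <- groupZ(one, 1)
    expect_equal(nrow(o1), 1L)
    expect_equal(o1$integrated_intensity, 55)
    expect_equal(o1$z_planes, "2")

    ## laterally distant regions in the same planes stay separate
    two <- list(makeRS(rbind(c(2, 2), c(40, 40)), ps = 0.2),
                makeRS(rbind(c(2, 2), c(40, 40)), ps = 0.2))
    expect_equal(nrow(groupZ(two, 1)), 2L)
})

test_that("3D tracking follows adhesions drifting through focal planes", {
    mkZScene <- function(blobs, w = 48, t = 3)
        sceneSpec(w, w, t, blobs = blobs, nPlanes = 7, dzUm = 0.5,
                  background = list(constant = 0), noiseSd = 0)
    ## one blob drifting one plane per frame: a single persistent track
    sc <- mkZScene(list(blobSpec(x0 = 20, y0 = 20, z0 = 2, driftZ = 1,
                                 amplitude0 = 300, sigmaXPx = 1.7)))
    tr <- trackStack(renderMovie(sc)$stack, synthPreCfg(), synthSegCfg(),
                     trackConfig())
    expect_equal(nTracks(tr$tracks), 1L)
    obs <- observations(tr$tracks)
    expect_equal(nrow(obs), 3L)
    expect_equal(obs$centroid_z_index, c(2, 3, 4))

    ## a lateral jump beyond the cap severs the track
    scJ <- mkZScene(list(blobSpec(x0 = 4, y0 = 24, z0 = 3, driftX = 15,
                                  amplitude0 = 300, sigmaXPx = 1.7)))
    trJ <- trackStack(renderMovie(scJ)$stack, synthPreCfg(), synthSegCfg(),
                      trackConfig())
    expect_equal(nTracks(trJ$tracks), 3L)

    ## two laterally distant parallel drifters never swap IDs
    scP <- mkZScene(list(
        blobSpec(x0 = 12, y0 = 24, z0 = 1, driftZ = 1, amplitude0 = 300,
                 sigmaXPx = 1.7),
        blobSpec(x0 = 36, y0 = 24, z0 = 1, driftZ = 1, amplitude0 = 300,
                 sigmaXPx = 1.7)))
    movP <- renderMovie(scP)
    trP <- trackStack(movP$stack, synthPreCfg(), synthSegCfg(),
                      trackConfig())
    expect_equal(nTracks(trP$tracks), 2L)
    obsP <- observations(trP$tracks)
    for (id in 1:2) {
        oi <- obsP[obsP$adhesion_id == id, ]
        expect_equal(nrow(oi), 3L)
        expect_lt(diff(range(oi$centroid_x_px)), 1)  # no swap
    }
})

test_that("short tracks are dropped only at reporting time", {
    rs <- c(lapply(1:2, function(t) makeRS(rbind(c(2, 2), c(9, 9)))),
            lapply(1:3, function(t) makeRS(c(2, 2))))
    tr <- buildTracks(rs, dtS = 60)
    expect_equal(nTracks(tr), 2L)
    kept <- filterTracks(tr, minObservations = 3L)
    expect_equal(nTracks(kept), 1L)
    expect_equal(trackIds(kept), 1L)
})
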