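test_that("local threshold: strict inequality, point detection, limit cases", {
    cfg3 <- segmentConfig(localKernelPx = 3)
    cc <- matrix(4, 7, 7)
    expect_false(any(localThresholdAdhesions(cc, cfg3)))

    f <- matrix(1, 5, 5); f[3, 3] <- 10
    m <- localThresholdAdhesions(f, cfg3)
    expect_equal(m, oracleLocalThreshold(f, 3, 0))
    expect_identical(which(m), which(matrix(seq_len(25), 5, 5) == 13))

    big <- segmentConfig(localKernelPx = 3, localOffset = 1e18)
    expect_false(any(localThresholdAdhesions(randomFrame(8, 8), big)))
})

test_that("raising the local offset never adds adhesion pixels", {
    set.seed(11)
    for (rep in 1:10) {
        f <- randomFrame()
        offs <- sort(runif(3, 0, 5))
        masks <- lapply(offs, function(o) localThresholdAdhesions(
            f, segmentConfig(localKernelPx = 5, localOffset = o)))
        expect_true(all(masks[[2]] <= masks[[1]]))
        expect_true(all(masks[[3]] <= masks[[2]]))
    }
})

test_that("global threshold and Otsu separate intensity classes", {
    f <- matrix(c(1, 1, 2, 9), 2, 2)
    expect_equal(globalThresholdCell(f, segmentConfig(cellThreshold = 2)),
                 matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
    pos <- randomFrame(6, 6, lo = 1, hi = 9)
    expect_true(all(globalThresholdCell(pos,
                                        segmentConfig(cellThreshold = 0))))

    bi <- matrix(c(rep(10, 100), rep(100, 100)), 10, 20)
    thr <- otsuThreshold(bi)
    expect_gt(thr, 10); expect_lt(thr, 100)
    m <- globalThresholdCell(bi, segmentConfig(cellThreshold = "otsu"))
    expect_identical(m, bi == 100)
    ## exhaustive between-class-variance oracle lands in the same gap
    ot <- oracleOtsu(as.vector(bi))
    expect_gt(ot, 10); expect_lt(ot, 100)
})

test_that("mask combination is logical AND", {
    a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
    ones <- matrix(TRUE, 2, 2); zeros <- matrix(FALSE, 2, 2)
    expect_identical(combineMasks(a, ones), a)
    expect_false(any(combineMasks(a, zeros)))
    expect_false(any(combineMasks(a, !a)))
    expect_error(combineMasks(a, matrix(TRUE, 3, 2)), "shape")
})

test_that("area filter enforces the 1 um2 cutoff (16 px at 0.25 um/px)", {
    m <- matrix(FALSE, 12, 24)
    m[2:4, 2:6] <- TRUE               # 15 px -> 0.9375 um2, removed
    m[7:10, 10:13] <- TRUE            # 16 px -> exactly 1 um2, kept
    out <- filterSmallObjects(m, pixelSizeUm = 0.25, minAreaUm2 = 1)
    expect_false(any(out[2:4, 2:6]))
    expect_true(all(out[7:10, 10:13]))

    expect_false(any(filterSmallObjects(matrix(FALSE, 5, 5), 0.25)))
})

test_that("connectivity decides whether diagonal pixels form one object", {
    m <- matrix(FALSE, 6, 6)
    m[2, 2] <- TRUE; m[3, 3] <- TRUE
    expect_equal(max(labelComponents(m, 4)), 2L)
    expect_equal(max(labelComponents(m, 8)), 1L)
    ## 2 px at 0.25 um/px = 0.125 um2 < 1: removed under either rule
    expect_false(any(filterSmallObjects(m, 0.25, 1, connectivity = 4)))
    expect_false(any(filterSmallObjects(m, 0.25, 1, connectivity = 8)))
    ## but kept when the threshold drops below 2 px worth of area
    expect_true(any(filterSmallObjects(m, 0.25, 0.1, connectivity = 8)))
})

test_that("labeling matches the flood-fill oracle on random masks", {
    set.seed(12)
    for (rep in 1:20) {
        m <- matrix(runif(16 * 16) < 0.35, 16, 16)
        for (conn in c(4, 8)) {
            expect_identical(labelComponents(m, conn),
                             oracleLabel(m, conn))
        }
    }
})

test_that("4-connectivity labeling agrees with EBImage::bwlabel", {
    set.seed(16)
    for (rep in 1:5) {
        m <- matrix(runif(14 * 14) < 0.3, 14, 14)
        ours <- labelComponents(m, 4)
        ref <- EBImage::bwlabel(m * 1L)
        expect_equal(max(ours), max(ref))
        ## same partition: one-to-one correspondence between label sets
        key <- paste(ours[m], ref[m])
        expect_equal(length(unique(key)), max(ours))
    }
})

test_that("label-and-measure reports centroids, areas and sums", {
    m <- matrix(FALSE, 5, 5)
    m[2:3, 2:3] <- TRUE              # rows/cols 1..2 in 0-based coords
    f <- matrix(5, 5, 5)
    rs <- labelAndMeasure(m, f, pixelSizeUm = 0.5)
    rt <- regionTable(rs)
    expect_equal(nrow(rt), 1L)
    expect_equal(rt$centroid_x_px, 1.5)
    expect_equal(rt$centroid_y_px, 1.5)
    expect_equal(rt$n_pixels, 4L)
    expect_equal(rt$area_um2, 4 * 0.25)
    expect_equal(rt$integrated_intensity, 20)

    expect_equal(nRegions(labelAndMeasure(matrix(FALSE, 4, 4),
                                          matrix(1, 4, 4), 0.2)), 0L)

    two <- matrix(FALSE, 8, 8)
    two[2:3, 2:3] <- TRUE; two[6:7, 5:6] <- TRUE
    rt2 <- regionTable(labelAndMeasure(two, matrix(1, 8, 8), 0.2))
    expect_identical(rt2$label, 1:2)
    expect_lt(rt2$centroid_y_px[1], rt2$centroid_y_px[2])
})

test_that("segmentation chain: final mask inside cell, areas above cutoff", {
    set.seed(13)
    sc <- makeTrackingScene(901, nFrames = 1L, nBlobsRange = c(4L, 8L))
    mov <- renderMovie(sc)
    res <- segmentFrame(getFrame(mov$stack, 1), pixelSize(mov$stack),
                        synthPreCfg(), synthSegCfg())
    expect_true(all(res$adhesionMask <= res$cellMask))
    rt <- regionTable(res$regions)
    expect_true(all(rt$area_um2 >= 1))
    expect_true(all(rt$integrated_intensity > 0))
})

test_that("segmentation chain equals a per-pixel brute-force reference", {
    set.seed(14)
    pre <- preprocessConfig(gaussianSigmaPx = 0.8, lowpassKernelPx = 7,
                            epsilon = 1e-6)
    seg <- segmentConfig(localKernelPx = 3, localOffset = 0.02,
                         cellThreshold = 0.5, minAreaUm2 = 0.08,
                         connectivity = 8, cellKeepLargest = FALSE,
                         cellFillHoles = FALSE)
    for (rep in 1:10) {
        f <- randomFrame()
        got <- segmentFrame(f, pixelSizeUm = 0.2, pre, seg)
        sm <- oracleGaussianSmooth(f, 0.8)
        corr <- oracleCorrectIllumination(sm, 7, 1e-6)
        adh <- oracleLocalThreshold(corr, 3, 0.02)
        cell <- corr >= 0.5
        mask <- oracleFilterSmall(adh & cell, 0.2, 0.08, 8)
        expect_identical(got$adhesionMask, mask)
        lab <- oracleLabel(mask, 8)
        expect_identical(labelImage(got$regions), lab)
    }
})
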