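# Shared synthetic-scene builders for tracking and pipeline tests.

# Preprocess/segment settings matched to the synthetic regime (flat-ish
# background ~40 counts, blob amplitudes 300-500, 0.2 um/px): corrected
# background sits near 1, so a 0.6 offset rejects read noise while blob
# cores (several-fold above background) stay detected. Cell threshold 0
# keeps the whole field (synthetic scenes frame no cell outline).
synthPreCfg <- function() preprocessConfig(gaussianSigmaPx = 1,
                                           lowpassKernelPx = 31L)
synthSegCfg <- function(offset = 0.6)
    segmentConfig(localKernelPx = 15L, localOffset = offset,
                  cellThreshold = 0, minAreaUm2 = 1, connectivity = 8L)

# A well-spaced multi-blob movie: blobs on a jittered grid (>= ~18 px
# apart), slow drift (< half the minimal spacing per frame), high SNR.
makeTrackingScene <- function(seed, nFrames = 10L, nBlobsRange = c(5L, 15L)) {
    set.seed(seed)
    grid <- expand.grid(x = c(14, 36, 58, 80), y = c(14, 36, 58, 80))
    nBlobs <- sample(nBlobsRange[1]:nBlobsRange[2], 1)
    cells <- sample(nrow(grid), nBlobs)
    blobs <- lapply(cells, function(ci) {
        ang <- runif(1, 0, 2 * pi)
        speed <- runif(1, 0, 0.3)          # px/frame; 0.06 um/frame
        blobSpec(x0 = grid$x[ci] + runif(1, -2, 2),
                 y0 = grid$y[ci] + runif(1, -2, 2),
                 driftX = speed * cos(ang), driftY = speed * sin(ang),
                 amplitude0 = runif(1, 300, 500),
                 ## decay bounded so every blob stays well above the
                 ## detection floor for the whole movie (high SNR)
                 kPerMin = runif(1, -0.04, 0.08),
                 sigmaXPx = runif(1, 1.5, 1.9),
                 sigmaYPx = runif(1, 1.5, 1.9))
    })
    sceneSpec(96, 96, nFrames, blobs = blobs,
              background = list(constant = 40, gradientX = 0.05),
              seed = seed)
}

# Match pipeline tracks against ground truth: every blob must be covered
# by exactly one adhesion ID over its whole lifetime, with no ID shared
# between blobs ("100% of IDs recovered without swaps").
scoreTracking <- function(tracks, truth, tolPx = 2.5) {
    obs <- observations(tracks)
    idsByBlob <- list()
    for (b in unique(truth$truth_id)) {
        tb <- truth[truth$truth_id == b, ]
        ids <- integer(0)
        for (r in seq_len(nrow(tb))) {
            o <- obs[obs$t_index == tb$t_index[r], , drop = FALSE]
            if (nrow(o) == 0) return(FALSE)
            d <- sqrt((o$centroid_x_px - tb$centroid_x_px[r])^2 +
                      (o$centroid_y_px - tb$centroid_y_px[r])^2)
            if (min(d) > tolPx) return(FALSE)
            ids <- c(ids, o$adhesion_id[which.min(d)])
        }
        if (length(unique(ids)) != 1L) return(FALSE)
        idsByBlob[[as.character(b)]] <- ids[1]
    }
    !anyDuplicated(unlist(idsByBlob))
}
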