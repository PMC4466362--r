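# Shared fixture builders. Everything is generated in code at test time.

# quick VoxelGrid around a plain array
vg <- function(arr, spacingNm = c(130, 30, 30), originNm = c(0, 0, 0),
               channel = "np") {
  new("VoxelGrid", data = arr, spacingNm = spacingNm, originNm = originNm,
      channel = channel)
}

# small STED-like field of view for point-source fixtures
spotGeom <- function(nz = 20, ny = 120, nx = 120) {
  list(dim = c(nz, ny, nx), spacingNm = c(130, 30, 30), originNm = c(0, 0, 0))
}

# noise-free render of point emitters at given (z, y, x) nm positions
renderSpots <- function(pos, brightness = 2e4, acq = stedAcquisition(),
                        geom = spotGeom(), noise = FALSE, seed = NULL) {
  em <- data.frame(zNm = pos[, 1], yNm = pos[, 2], xNm = pos[, 3],
                   brightness = brightness)
  renderChannel(em, acq, geom, noise = noise, seed = seed)
}

# small phantom used across tests (same proportions as the pipeline default)
testPhantom <- function() {
  buildPhantom(cellSemiAxesUm = c(7, 6, 4), nucleusSemiAxesUm = c(3, 2.5, 1.5))
}

# match detected objects against true emitter positions; returns the number
# of detections with a true emitter within `tolNm`
countMatched <- function(detected, truth, tolNm = 200) {
  if (nrow(detected) == 0 || nrow(truth) == 0) return(0L)
  d2 <- outer(detected$zNm, truth$zNm, "-")^2 +
    outer(detected$yNm, truth$yNm, "-")^2 +
    outer(detected$xNm, truth$xNm, "-")^2
  sum(sqrt(apply(d2, 1, min)) < tolNm)
}

# end-to-end ground-truth recovery run (the per-cell counting experiment):
# phantom cell, nIn internalized + nOut attached/substrate particles at
# >= 4x-PSF-FWHM anisotropic spacing, full default pipeline.
recoveryRun <- function(nIn, dNm, seed, nOut = 30) {
  cfg <- defaultRunConfig(
    seed = seed,
    particles = list(nInside = nIn, nOutside = nOut, clusterSizes = 1,
                     diameterNm = dNm, densityGcm3 = 1.8,
                     minSeparationNm = c(304, 2400)))
  res <- runPipeline(cfg, outDir = tempfile("npq_scene_"))
  gt <- res$groundTruth
  trueIn <- gt[gt$inside, ]
  flagged <- res$objects[res$objects$inside %in% TRUE, ]
  tp <- countMatched(flagged, trueIn)
  list(res = res, nFlagged = nrow(flagged), nTrue = nrow(trueIn),
       precision = if (nrow(flagged)) tp / nrow(flagged) else NA_real_,
       recall = tp / nrow(trueIn))
}

# exhaustive between-class-variance threshold search over the same 256-bin
# histogram otsuThreshold() uses: the brute-force oracle
otsuBruteForce <- function(x, nbins = 256) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), nbins)
  counts <- tabulate(bin, nbins)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  best <- -Inf; bestK <- 1L
  n <- sum(counts)
  for (k in seq_len(nbins - 1)) {
    w0 <- sum(counts[1:k]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / (w0 * n)
    mu1 <- sum(counts[(k + 1):nbins] * mids[(k + 1):nbins]) / (w1 * n)
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; bestK <- k }
  }
  breaks[bestK + 1]
}
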