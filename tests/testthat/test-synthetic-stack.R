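# Phantom geometry, emitter placement and the detector model.

test_that("voxelised phantom volume matches the analytic half-ellipsoid", {
  ph <- buildPhantom(cellSemiAxesUm = c(20, 15, 8),
                     nucleusSemiAxesUm = c(8, 6, 4))
  geom <- list(dim = c(90, 320, 420), spacingNm = c(100, 100, 100),
               originNm = c(-400, -15500, -20500))
  vox <- voxelizePhantom(ph, geom)
  volVox <- sum(vox) * prod(geom$spacingNm) / 1e9
  expect_equal(volVox, phantomVolumeUm3(ph), tolerance = 0.01)
  expect_equal(phantomVolumeUm3(ph), 2 / 3 * pi * 20 * 15 * 8)
})

test_that("a nucleus that does not fit inside the cell is rejected", {
  expect_error(buildPhantom(cellSemiAxesUm = c(7, 6, 4),
                            nucleusSemiAxesUm = c(8, 6, 4)),
               "nucleus")
  # too tall for the half-ellipsoid even though laterally fine
  expect_error(buildPhantom(cellSemiAxesUm = c(7, 6, 4),
                            nucleusSemiAxesUm = c(3, 2.5, 3),
                            nucleusCenterUm = c(0, 0, 2.5)),
               "nucleus")
})

test_that("emitter placement is deterministic, counted, and geometry-true", {
  ph <- testPhantom()
  p <- particleSpec(85)
  a <- sampleParticles(ph, 30, 10, particle = p, seed = 7)
  b <- sampleParticles(ph, 30, 10, particle = p, seed = 7)
  expect_identical(a, b)
  expect_identical(nrow(a), 40L)
  expect_identical(sum(a$inside), 30L)

  expect_identical(nrow(sampleParticles(ph, 0, 0, particle = p, seed = 1)), 0L)

  all100 <- sampleParticles(ph, 100, 0, particle = p, seed = 2)
  expect_identical(sum(all100$inside), 100L)

  # infeasible clearance
  expect_error(sampleParticles(buildPhantom(c(0.5, 0.5, 0.3), c(0.1, 0.1, 0.05)),
                               10, 0, particle = particleSpec(400), seed = 1),
               "fit|infeasible")
})

test_that("cluster members are placed in contact at one particle diameter", {
  ph <- testPhantom()
  em <- sampleParticles(ph, 12, 0, clusterSizes = 3,
                        particle = particleSpec(85), seed = 3)
  expect_identical(nrow(em), 12L)
  for (cid in unique(em$cluster)) {
    m <- em[em$cluster == cid, ]
    pd <- as.matrix(dist(m[, c("zNm", "yNm", "xNm")]))
    diag(pd) <- Inf
    # every member touches at least one neighbour at the contact distance
    expect_true(all(abs(apply(pd, 1, min) - 85) < 1))
    expect_true(all(pd[is.finite(pd)] >= 0.98 * 85))
  }
})

test_that("ground-truth inside flags agree with the voxelised interior", {
  ph <- testPhantom()
  em <- sampleParticles(ph, 40, 20, particle = particleSpec(85), seed = 5)
  geom <- list(dim = c(180, 280, 320), spacingNm = c(50, 50, 50),
               originNm = c(-500, -6900, -7800))
  vox <- voxelizePhantom(ph, geom)
  iz <- round((em$zNm - geom$originNm[1]) / 50) + 1
  iy <- round((em$yNm - geom$originNm[2]) / 50) + 1
  ix <- round((em$xNm - geom$originNm[3]) / 50) + 1
  inVox <- vox[cbind(iz, iy, ix)]
  expect_identical(sum(em$inside), sum(inVox))
  expect_identical(em$inside, unname(inVox))
})

test_that("ground-truth table merges emitters under the separation criterion", {
  em <- data.frame(zNm = c(0, 0, 0, 5000), yNm = c(0, 100, 4000, 0),
                   xNm = 0, brightness = 1, diameterNm = 85,
                   cluster = 1:4, inside = TRUE)
  gt <- groundTruthTable(em, separationNm = c(152, 1200))
  expect_identical(gt$expectedObject[1], gt$expectedObject[2])
  expect_identical(length(unique(gt$expectedObject)), 3L)
})

test_that("a contained emitter deposits exactly its brightness", {
  g <- renderSpots(matrix(c(1300, 1800, 1800), 1), brightness = 2e4)
  expect_equal(sum(voxelData(g)) - 5 * length(voxelData(g)), 2e4,
               tolerance = 0.01)
})

test_that("rendering is bit-identical under a fixed seed", {
  pos <- matrix(c(1300, 1800, 1800), 1)
  g1 <- renderSpots(pos, acq = confocalAcquisition(), noise = TRUE, seed = 42)
  g2 <- renderSpots(pos, acq = confocalAcquisition(), noise = TRUE, seed = 42)
  expect_identical(voxelData(g1), voxelData(g2))
})

test_that("background-only render is Poisson around the configured level", {
  acq <- stedAcquisition(background = 5, readNoiseSd = 0)
  g <- renderChannel(data.frame(zNm = numeric(0), yNm = numeric(0),
                                xNm = numeric(0), brightness = numeric(0)),
                     acq, spotGeom(), noise = TRUE, seed = 9)
  x <- voxelData(g)
  se <- sqrt(5 / length(x))
  expect_lt(abs(mean(x) - 5), 3 * se)
  expect_true(all(x == floor(x)))   # photon counts
})

test_that("noise-free signal is linear in brightness below saturation", {
  pos <- matrix(c(1300, 1800, 1800), 1)
  g1 <- renderSpots(pos, brightness = 1e4)
  g2 <- renderSpots(pos, brightness = 2e4)
  s1 <- sum(voxelData(g1)) - 5 * length(voxelData(g1))
  s2 <- sum(voxelData(g2)) - 5 * length(voxelData(g2))
  expect_equal(s2 / s1, 2, tolerance = 1e-6)
})

test_that("very bright emitters clip at the detector maximum", {
  acq <- stedAcquisition(detectorMax = 1000)
  g <- renderSpots(matrix(c(1300, 1800, 1800), 1), brightness = 1e9,
                   acq = acq, noise = TRUE, seed = 1)
  expect_identical(max(voxelData(g)), 1000)
})

test_that("emitters outside the field of view are refused", {
  expect_error(renderSpots(matrix(c(1300, 1800, 99999), 1)),
               "field of view")
})

test_that("an in-focus line profile through a point source recovers the PSF FWHM", {
  g <- renderSpots(matrix(c(1300, 1800, 1800), 1))
  # sample at pixel centres to avoid interpolation broadening
  prof <- extractProfile(g, c(1300, 1800, 600), c(1300, 1800, 3000),
                         stepNm = 30)
  f <- fitGaussianProfile(prof)
  expect_lt(abs(f$fwhmNm - 76) / 76, 0.10)
})
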