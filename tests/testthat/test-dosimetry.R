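# Stokes transport coefficients and the sedimentation-diffusion solver.

test_that("settling velocity follows Stokes' law", {
  m <- mediumSpec(viscosityPaS = 7.0e-4)
  expect_equal(settlingVelocity(particleSpec(85, densityGcm3 = 1.0), m), 0)
  v1 <- settlingVelocity(particleSpec(40), m)
  v2 <- settlingVelocity(particleSpec(80), m)
  expect_equal(v2 / v1, 4, tolerance = 1e-12)
  # hand-evaluated: 9.80665 * 800 * (85e-9)^2 / (18 * 7.0e-4) m/s
  expect_equal(settlingVelocity(particleSpec(85), m), 4.4987e-9,
               tolerance = 1e-4)
})

test_that("diffusivity follows Stokes-Einstein", {
  m <- mediumSpec(viscosityPaS = 7.0e-4)
  d1 <- diffusivity(particleSpec(25), m)
  d2 <- diffusivity(particleSpec(50), m)
  expect_equal(d1 / d2, 2, tolerance = 1e-12)
  # hand-evaluated: 1.380649e-23 * 310.15 / (3 * pi * 7e-4 * 25e-9)
  expect_equal(d1, 2.59624e-11, tolerance = 1e-5)
  cold <- mediumSpec(temperatureK = 0.001, viscosityPaS = 7.0e-4)
  expect_lt(diffusivity(particleSpec(25), cold), 1e-16)
})

test_that("effective agglomerate spheres scale with cluster size and packing", {
  p <- particleSpec(85)
  m <- mediumSpec()
  same <- effectiveCluster(p, n = 1, medium = m, packing = 1)
  expect_equal(same@diameterNm, 85)
  expect_equal(same@densityGcm3, 1.8)

  e3 <- effectiveCluster(p, n = 3, medium = m, packing = 0.637)
  expect_equal(e3@diameterNm, 85 * (3 / 0.637)^(1 / 3), tolerance = 1e-12)
  expect_equal(e3@diameterNm, 142.48, tolerance = 1e-4)
  expect_gt(e3@densityGcm3, m@densityGcm3)
  expect_lt(e3@densityGcm3, p@densityGcm3)
})

test_that("no transport means no deposition", {
  m <- mediumSpec(temperatureK = 1e-9, viscosityPaS = 7.4e-4)
  dep <- simulateDeposition(particleSpec(25, densityGcm3 = 1.0), m,
                            durationH = 5)
  expect_lt(depositedFraction(dep), 1e-6)
})

test_that("pure diffusion matches the absorbing-wall closed form within 2%", {
  m <- mediumSpec(heightMm = 5, volumeMl = NA_real_, baseAreaCm2 = NA_real_)
  p <- particleSpec(25, densityGcm3 = 1.0)     # neutral buoyancy: V = 0
  tS <- 600
  dep <- simulateDeposition(p, m, durationH = tS / 3600)
  D <- diffusivity(p, m)
  closed <- 2 * sqrt(D * tS / pi) / 5e-3
  expect_equal(depositedFraction(dep), closed, tolerance = 0.02)
})

test_that("the solver conserves mass and deposits monotonically", {
  dep <- simulateDeposition(particleSpec(85), mediumSpec(), durationH = 5)
  expect_lt(dep@diagnostics$massBalanceError, 1e-6)
  s <- depositionSeries(dep)
  expect_true(all(diff(s$fraction) >= 0))
  expect_true(all(s$fraction >= 0 & s$fraction <= 1))

  # monotone in D (smaller particle diffuses faster; sedimentation off)
  m <- mediumSpec()
  fD1 <- depositedFraction(simulateDeposition(particleSpec(25, 1.0), m, 5))
  fD2 <- depositedFraction(simulateDeposition(particleSpec(85, 1.0), m, 5))
  expect_gt(fD1, fD2)
  # monotone in V (same size, denser particle settles faster)
  fV1 <- depositedFraction(simulateDeposition(particleSpec(85, 2.6), m, 5))
  fV2 <- depositedFraction(simulateDeposition(particleSpec(85, 1.8), m, 5))
  expect_gt(fV1, fV2)
})

test_that("the solution is grid-converged at the default resolution", {
  m <- mediumSpec()
  p <- particleSpec(25)
  f1 <- depositedFraction(simulateDeposition(p, m, 5))
  f2 <- depositedFraction(simulateDeposition(p, m, 5, nNodes = 2000,
                                             nSteps = 8000))
  expect_lt(abs(f1 - f2), 0.001)   # < 0.1 percentage point
})

test_that("everything deposits in the long-time limit", {
  m <- mediumSpec(heightMm = 0.05, volumeMl = NA_real_,
                  baseAreaCm2 = NA_real_)
  dep <- simulateDeposition(particleSpec(25), m, durationH = 1)
  expect_gt(depositedFraction(dep), 0.999)
})

test_that("deposition depends only weakly on small cluster sizes", {
  m <- mediumSpec()
  for (d in c(25, 85)) {
    fr <- vapply(c(1, 3, 4), function(n)
      depositedFraction(simulateDeposition(particleSpec(d, clusterSize = n),
                                           m, 5)), numeric(1))
    expect_lt(diff(range(fr)), 0.10)   # within a few percentage points
  }
})

test_that("deposited-per-area is the fraction times the column content", {
  expect_equal(depositedPerArea(0, 9.2e10, 0.5), 0)
  expect_equal(depositedPerArea(0.265, 9.2e10, 0.5), 1.219e10,
               tolerance = 1e-3)
  expect_equal(depositedPerArea(1, 2, 3), 6)
  expect_error(depositedPerArea(1.2, 1, 1), "fraction")
})

test_that("medium geometry must be self-consistent", {
  expect_error(mediumSpec(volumeMl = 1, baseAreaCm2 = 3.8, heightMm = 5),
               "inconsistent")
  m <- mediumSpec()
  expect_equal(m@heightMm, 10 / 3.8, tolerance = 1e-12)
  expect_error(particleSpec(25, clusterSize = 2.5), "integer")
})
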