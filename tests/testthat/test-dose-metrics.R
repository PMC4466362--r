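# Dose arithmetic: number/mass, coverage, occupancy, concentrations, BET.

test_that("number and mass concentrations interconvert with the lot diameter", {
  # 9.2e10 particles/mL of the 24 nm (EM diameter) lot is 1.2 ug/mL
  expect_equal(massFromNumber(9.2e10, 24), 1.2, tolerance = 0.01)
  # 50 ug/mL of the same lot is 3.8e12 particles/mL
  expect_equal(numberFromMass(50, 24), 3.8e12, tolerance = 0.015)
  # exact round trip
  x <- 9.2e10
  expect_equal(numberFromMass(massFromNumber(x, 24), 24), x,
               tolerance = 1e-12)
  # linearity
  expect_equal(massFromNumber(2 * x, 24), 2 * massFromNumber(x, 24))
})

test_that("deposited areal densities translate into surface coverage", {
  expect_equal(surfaceCoverage(1.22e10, 25), 0.06, tolerance = 0.002)
  expect_equal(surfaceCoverage(9.40e9, 85), 0.53, tolerance = 0.01)
  expect_equal(surfaceCoverage(0, 25), 0)
  expect_equal(surfaceCoverage(2 * 1e10, 25), 2 * surfaceCoverage(1e10, 25))
})

test_that("intracellular volume occupancy matches the printed example", {
  occ <- volumeOccupancy(7000, 25, cellVolumeUm3 = 1600)
  expect_equal(occ$occupiedUm3, 0.057, tolerance = 0.01)
  expect_equal(occ$volumeFraction, 3.5e-5, tolerance = 0.03)
  z <- volumeOccupancy(0, 25)
  expect_identical(z$occupiedUm3, 0)
  expect_identical(z$volumeFraction, 0)
})

test_that("intracellular concentrations span the printed range", {
  expect_equal(intracellularConcentration(404, 1600), 2.5e11,
               tolerance = 0.02)
  expect_equal(intracellularConcentration(7772, 1600), 4.8e12,
               tolerance = 0.02)
  expect_identical(intracellularConcentration(0), 0)
})

test_that("uptake efficiency is internalized over delivered-to-footprint", {
  expect_equal(uptakeEfficiency(0, 122, 1000), 0)
  expect_equal(uptakeEfficiency(122 * 1000, 122, 1000), 100)
  # hand evaluation: 100 * 117 / (122 * 1000) = 0.0959 %
  expect_equal(uptakeEfficiency(117, 122, 1000), 0.0959, tolerance = 1e-3)
})

test_that("the BET regression reproduces the calibration line", {
  expect_identical(as.numeric(betSurfaceArea(25)), 106)
  expect_equal(as.numeric(betSurfaceArea(0, rounded = FALSE)), 143.2)
  expect_equal(as.numeric(betSurfaceArea(72, rounded = FALSE)), 34.84,
               tolerance = 1e-6)
  expect_true(attr(betSurfaceArea(25), "withinCalibration"))
  expect_false(attr(betSurfaceArea(85), "withinCalibration"))
  expect_warning(out <- betSurfaceArea(120), "calibration")
  expect_true(is.na(out[1]))
})

test_that("the dose report chains administered to intracellular coherently", {
  p <- particleSpec(24)
  dep <- new("DepositionResult", fraction = 0.265,
             perAreaCm2 = depositedPerArea(0.265, 9.2e10, 0.5),
             timesH = c(0, 5), fractionSeries = c(0, 0.265),
             diagnostics = list(massBalanceError = 0, nNodes = 0, nSteps = 0))
  rep <- doseReport(p, mediumSpec(), 9.2e10, 5, internalizedPerCell = 7000,
                    cellAreaUm2 = 1000, cellVolumeUm3 = 1600,
                    deposition = dep)
  expect_equal(rep$administeredMassUgPerMl, 1.2, tolerance = 0.01)
  expect_equal(rep$deliveredPerAreaCm2, 1.219e10, tolerance = 1e-3)
  expect_equal(rep$surfaceCoverage,
               surfaceCoverage(rep$deliveredPerAreaCm2, 24))
  expect_equal(rep$intracellularPerMl, 7000 / 1600 * 1e12)
  expect_false(rep$coverageSupersaturated)
  expect_equal(rep$uptakeEfficiencyPct,
               100 * 7000 / (1.219e10 / 1e8 * 1000), tolerance = 1e-3)

  # supersaturated coverage is reported, not clipped
  dep2 <- new("DepositionResult", fraction = 0.22,
              perAreaCm2 = depositedPerArea(0.22, 9.2e12, 0.5),
              timesH = c(0, 5), fractionSeries = c(0, 0.22),
              diagnostics = list(massBalanceError = 0, nNodes = 0, nSteps = 0))
  rep2 <- doseReport(p, mediumSpec(), 9.2e12, 5, deposition = dep2)
  expect_gt(rep2$surfaceCoverage, 1)
  expect_true(rep2$coverageSupersaturated)
})
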