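# Dose arithmetic: administered / delivered / intracellular conversions.

#' Mass and number concentration conversions
#'
#' Per-particle mass is `rho * pi/6 * d^3`; mass concentration is the
#' number concentration times the per-particle mass (reported in
#' micrograms per mL), and `numberFromMass()` is the exact inverse.
#'
#' @param numberPerMl Number concentration (mL^-1).
#' @param massUgPerMl Mass concentration (ug mL^-1).
#' @param diameterNm Particle diameter (nm). For lot-specific conversions
#'   use the electron-microscopy diameter of the lot (24 nm reproduces the
#'   1.2 ug/mL of the 25 nm lot).
#' @param densityGcm3 Particle density (g cm^-3).
#' @return Mass concentration in ug mL^-1 / number concentration in mL^-1.
#' @examples
#' massFromNumber(9.2e10, 24)        # ~1.2 ug/mL
#' numberFromMass(50, 24)            # ~3.8e12 /mL
#' @export
massFromNumber <- function(numberPerMl, diameterNm, densityGcm3 = 1.8) {
  if (any(numberPerMl < 0) || diameterNm <= 0 || densityGcm3 <= 0)
    stop("inputs must be positive")
  mUg <- densityGcm3 * pi / 6 * (diameterNm * 1e-7)^3 * 1e6  # g->ug, cm^3
  numberPerMl * mUg
}

#' @rdname massFromNumber
#' @export
numberFromMass <- function(massUgPerMl, diameterNm, densityGcm3 = 1.8) {
  if (any(massUgPerMl < 0) || diameterNm <= 0 || densityGcm3 <= 0)
    stop("inputs must be positive")
  massUgPerMl / massFromNumber(1, diameterNm, densityGcm3)
}

#' Monolayer surface coverage by deposited particles
#'
#' Projected-area fraction of a surface covered by a monolayer of deposited
#' spheres: `coverage = perAreaCm2 * pi d^2 / 4`. Values above 1 mean the
#' surface would be more than completely covered and are returned as is
#' (flag downstream).
#'
#' @param perAreaCm2 Deposited particle number per cm^2.
#' @param diameterNm Particle diameter (nm).
#' @return Coverage fraction.
#' @examples
#' surfaceCoverage(1.22e10, 25)   # ~0.06
#' surfaceCoverage(9.40e9, 85)    # ~0.53
#' @export
surfaceCoverage <- function(perAreaCm2, diameterNm) {
  if (any(perAreaCm2 < 0) || diameterNm <= 0) stop("inputs must be >= 0")
  perAreaCm2 * pi * (diameterNm * 1e-7)^2 / 4
}

#' Intracellular volume occupied by particles
#'
#' `occupied = n * pi/6 * d^3`; the fraction relates it to the cell volume.
#'
#' @param n Number of internalized particles.
#' @param diameterNm Particle diameter (nm).
#' @param cellVolumeUm3 Cell volume (um^3).
#' @return List with `occupiedUm3` and `volumeFraction`.
#' @examples
#' volumeOccupancy(7000, 25)   # 0.057 um^3, 3.5e-5 of a 1600 um^3 cell
#' @export
volumeOccupancy <- function(n, diameterNm, cellVolumeUm3 = 1600) {
  if (any(n < 0) || diameterNm <= 0 || cellVolumeUm3 <= 0)
    stop("inputs must be positive")
  occ <- n * pi / 6 * (diameterNm * 1e-3)^3    # um^3
  list(occupiedUm3 = occ, volumeFraction = occ / cellVolumeUm3)
}

#' Intracellular number concentration
#'
#' Internalized particles per cell volume, in mL^-1 (1 mL = 1e12 um^3).
#'
#' @param n Number of internalized particles.
#' @param cellVolumeUm3 Cell volume (um^3).
#' @return Concentration in mL^-1.
#' @examples
#' intracellularConcentration(404)    # ~2.5e11
#' intracellularConcentration(7772)   # ~4.9e12
#' @export
intracellularConcentration <- function(n, cellVolumeUm3 = 1600) {
  if (any(n < 0) || cellVolumeUm3 <= 0) stop("inputs must be positive")
  n / cellVolumeUm3 * 1e12
}

#' Uptake efficiency
#'
#' Internalized particles as a percentage of the particles delivered to the
#' cell's footprint: `100 n / (deliveredPerAreaUm2 * cellAreaUm2)`.
#'
#' @param n Number of internalized particles.
#' @param deliveredPerAreaUm2 Delivered (deposited) number per um^2.
#' @param cellAreaUm2 Projected cell area (um^2).
#' @return Percentage.
#' @examples
#' uptakeEfficiency(117, 122, 1000)   # ~0.096 %
#' @export
uptakeEfficiency <- function(n, deliveredPerAreaUm2, cellAreaUm2) {
  if (any(n < 0)) stop("count must be >= 0")
  if (any(deliveredPerAreaUm2 <= 0) || any(cellAreaUm2 <= 0))
    stop("delivered density and area must be > 0")
  100 * n / (deliveredPerAreaUm2 * cellAreaUm2)
}

#' BET specific surface area from the calibration regression
#'
#' Linear regression of specific surface area (m^2 g^-1) on particle
#' diameter, `y = 143.2 - 1.505 x`, calibrated on bare silica particles of
#' 23-72 nm. Outside that range the regression is extrapolation and the
#' result is flagged; at large diameters it turns non-physical (<= 0) and
#' `NA` is returned with a warning.
#'
#' @param diameterNm Particle diameter (nm).
#' @param rounded Round to integer for reporting (as tabulated).
#' @return Surface area in m^2 g^-1, with attribute `withinCalibration`.
#' @examples
#' betSurfaceArea(25)   # 106
#' @export
betSurfaceArea <- function(diameterNm, rounded = TRUE) {
  if (any(diameterNm < 0)) stop("diameter must be >= 0")
  y <- 143.2 - 1.505 * diameterNm
  within <- diameterNm >= 23 & diameterNm <= 72
  if (any(y <= 0)) {
    warning("regression result <= 0: outside the valid calibration range")
    y[y <= 0] <- NA_real_
  }
  if (rounded) y <- round(y)
  attr(y, "withinCalibration") <- within
  y
}

#' Assemble the full dose report
#'
#' Chains the dose arithmetic from the administered concentration through
#' the transport simulation to the intracellular measures, with no hidden
#' state: administered (number and mass), delivered (deposited fraction and
#' per-area from [simulateDeposition()]), internalized count, intracellular
#' concentration, surface coverage, occupied volume, and uptake efficiency.
#' Coverage or volume fractions above 1 are flagged "supersaturated" rather
#' than clipped.
#'
#' @param particle A [ParticleSpec-class]. Use the lot's EM diameter for
#'   faithful mass conversion.
#' @param medium A [MediumSpec-class].
#' @param numberConcPerMl Administered number concentration (mL^-1).
#' @param durationH Exposure duration (h).
#' @param internalizedPerCell Internalized particle count per cell.
#' @param cellAreaUm2 Projected cell area (um^2).
#' @param cellVolumeUm3 Cell volume (um^3).
#' @param deposition Optional precomputed [DepositionResult-class]; when
#'   NULL the deposition is simulated.
#' @return List of class `"doseReport"`.
#' @export
doseReport <- function(particle, medium = mediumSpec(),
                       numberConcPerMl = 9.2e10, durationH = 5,
                       internalizedPerCell = 0, cellAreaUm2 = 1000,
                       cellVolumeUm3 = 1600, deposition = NULL) {
  if (is.null(deposition))
    deposition <- simulateDeposition(particle, medium, durationH,
                                     numberConcPerMl)
  perAreaCm2 <- depositedPerAreaCm2(deposition)
  perAreaUm2 <- perAreaCm2 / 1e8
  cov <- surfaceCoverage(perAreaCm2, particle@diameterNm)
  occ <- volumeOccupancy(internalizedPerCell, particle@diameterNm,
                         cellVolumeUm3)
  rep <- list(
    particle = particle, medium = medium,
    administeredNumberPerMl = numberConcPerMl,
    administeredMassUgPerMl = massFromNumber(numberConcPerMl,
                                             particle@diameterNm,
                                             particle@densityGcm3),
    deliveredFraction = depositedFraction(deposition),
    deliveredPerAreaCm2 = perAreaCm2,
    internalizedPerCell = internalizedPerCell,
    intracellularPerMl = intracellularConcentration(internalizedPerCell,
                                                    cellVolumeUm3),
    surfaceCoverage = cov,
    coverageSupersaturated = cov > 1,
    occupiedVolumeUm3 = occ$occupiedUm3,
    volumeFraction = occ$volumeFraction,
    volumeSupersaturated = occ$volumeFraction > 1,
    uptakeEfficiencyPct = uptakeEfficiency(internalizedPerCell,
                                           max(perAreaUm2, .Machine$double.xmin),
                                           cellAreaUm2),
    deposition = deposition)
  class(rep) <- "doseReport"
  rep
}

#' @export
print.doseReport <- function(x, ...) {
  cat("Dose report\n")
  cat(sprintf("  administered: %.3g mL^-1 (%.3g ug/mL, d = %g nm)\n",
              x$administeredNumberPerMl, x$administeredMassUgPerMl,
              x$particle@diameterNm))
  cat(sprintf("  delivered:    %.1f%% deposited, %.3g cm^-2\n",
              100 * x$deliveredFraction, x$deliveredPerAreaCm2))
  cat(sprintf("  internalized: %g per cell (%.3g mL^-1 intracellular)\n",
              x$internalizedPerCell, x$intracellularPerMl))
  cat(sprintf("  coverage %.3g%s; occupied %.3g um^3 (%.3g of cell volume)\n",
              x$surfaceCoverage,
              if (x$coverageSupersaturated) " [supersaturated]" else "",
              x$occupiedVolumeUm3, x$volumeFraction))
  cat(sprintf("  uptake efficiency %.3g%%\n", x$uptakeEfficiencyPct))
  invisible(x)
}
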