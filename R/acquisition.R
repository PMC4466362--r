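#' Acquisition configurations
#'
#' Constructors for [AcquisitionConfig-class]. `stedAcquisition()` describes
#' the super-resolved nanoparticle channel (30 nm pixels, 76 nm lateral PSF
#' FWHM, photon-counting APD detection); `confocalAcquisition()` the
#' diffraction-limited cellular channels (60 nm pixels, 277 nm lateral PSF
#' FWHM). Both use a 130 nm z step. The axial PSF extent of the system is
#' not sharpened by the lateral depletion, so both modes default to a 600 nm
#' axial FWHM; it is freely configurable.
#'
#' @param pixelSizeNm Lateral pixel size (nm).
#' @param stepNm Axial step (nm).
#' @param psfFwhmLateralNm Lateral PSF FWHM (nm).
#' @param psfFwhmAxialNm Axial PSF FWHM (nm).
#' @param detectorMax Detector saturation level (counts).
#' @param background Expected background (counts).
#' @param readNoiseSd Gaussian read-noise SD (counts); 0 for photon counting.
#' @return An [AcquisitionConfig-class] object.
#' @examples
#' stedAcquisition()
#' confocalAcquisition(background = 10)
#' @export
stedAcquisition <- function(pixelSizeNm = 30, stepNm = 130,
                            psfFwhmLateralNm = 76, psfFwhmAxialNm = 600,
                            detectorMax = 65535, background = 5,
                            readNoiseSd = 0) {
  new("AcquisitionConfig", mode = "STED", pixelSizeNm = pixelSizeNm,
      stepNm = stepNm, psfFwhmLateralNm = psfFwhmLateralNm,
      psfFwhmAxialNm = psfFwhmAxialNm, detectorMax = detectorMax,
      background = background, readNoiseSd = readNoiseSd)
}

#' @rdname stedAcquisition
#' @export
confocalAcquisition <- function(pixelSizeNm = 60, stepNm = 130,
                                psfFwhmLateralNm = 277, psfFwhmAxialNm = 600,
                                detectorMax = 65535, background = 5,
                                readNoiseSd = 2) {
  new("AcquisitionConfig", mode = "confocal", pixelSizeNm = pixelSizeNm,
      stepNm = stepNm, psfFwhmLateralNm = psfFwhmLateralNm,
      psfFwhmAxialNm = psfFwhmAxialNm, detectorMax = detectorMax,
      background = background, readNoiseSd = readNoiseSd)
}

# PSF sigmas (z, y, x) in nm for an acquisition
.acqSigmaNm <- function(acq) {
  c(fwhmToSigma(acq@psfFwhmAxialNm),
    fwhmToSigma(acq@psfFwhmLateralNm),
    fwhmToSigma(acq@psfFwhmLateralNm))
}

# voxel spacing (z, y, x) in nm
.acqSpacingNm <- function(acq) {
  c(acq@stepNm, acq@pixelSizeNm, acq@pixelSizeNm)
}

#' Particle and medium constructors
#'
#' `particleSpec()` describes amorphous silica particles (density
#' 1.8 g cm^-3 by default). `mediumSpec()` describes the exposure column:
#' the defaults are 1 mL of aqueous culture medium at 37 degrees C standing
#' in a 12-well plate (growth area 3.8 cm^2, hence a 2.63 mm column), with
#' the standard aqueous-medium viscosity 7.4e-4 Pa s.
#'
#' @param diameterNm Primary particle diameter (nm).
#' @param densityGcm3 Particle (or medium) density in g cm^-3.
#' @param clusterSize Primary particles per agglomerate.
#' @param temperatureK Medium temperature (K); default 37 degrees C.
#' @param viscosityPaS Dynamic viscosity (Pa s).
#' @param volumeMl Medium volume (mL).
#' @param baseAreaCm2 Well growth area (cm^2).
#' @param heightMm Column height (mm); derived from volume and area if NULL.
#' @return A [ParticleSpec-class] / [MediumSpec-class].
#' @examples
#' particleSpec(25)
#' particleSpec(85, clusterSize = 3)
#' mediumSpec()
#' @export
particleSpec <- function(diameterNm, densityGcm3 = 1.8, clusterSize = 1) {
  new("ParticleSpec", diameterNm = diameterNm, densityGcm3 = densityGcm3,
      clusterSize = clusterSize)
}

#' @rdname particleSpec
#' @export
mediumSpec <- function(temperatureK = 310.15, viscosityPaS = 7.4e-4,
                       densityGcm3 = 1.00, volumeMl = 1,
                       baseAreaCm2 = 3.8, heightMm = NULL) {
  if (is.null(heightMm)) {
    if (!is.finite(volumeMl) || !is.finite(baseAreaCm2))
      stop("either heightMm or both volumeMl and baseAreaCm2 must be given")
    heightMm <- 10 * volumeMl / baseAreaCm2
  }
  new("MediumSpec", temperatureK = temperatureK, viscosityPaS = viscosityPaS,
      densityGcm3 = densityGcm3, volumeMl = volumeMl,
      baseAreaCm2 = baseAreaCm2, heightMm = heightMm)
}
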