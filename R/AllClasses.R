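# S4 classes for the imaging and dosimetry data containers.
# Array axis convention: dim = c(nz, ny, nx); physical vectors are ordered
# (z, y, x) in nm. A voxel's physical position is the position of its centre;
# `originNm` is the centre of voxel [1, 1, 1].

#' Acquisition configuration
#'
#' Describes one imaging channel: sampling, effective point-spread function,
#' and detector behaviour. The defaults of [stedAcquisition()] and
#' [confocalAcquisition()] correspond to 30 nm pixels with a 76 nm lateral
#' PSF FWHM (STED) and 60 nm pixels with a 277 nm lateral PSF FWHM
#' (confocal), both with a 130 nm z step.
#'
#' @slot mode "STED" or "confocal".
#' @slot pixelSizeNm Lateral pixel size (nm).
#' @slot stepNm Axial step between slices (nm).
#' @slot psfFwhmLateralNm Lateral PSF full width at half maximum (nm).
#' @slot psfFwhmAxialNm Axial PSF FWHM (nm).
#' @slot detectorMax Saturation level of the detector (counts).
#' @slot background Expected background level (counts).
#' @slot readNoiseSd Gaussian read-noise standard deviation (counts).
#' @export
setClass("AcquisitionConfig",
  slots = c(
    mode = "character",
    pixelSizeNm = "numeric",
    stepNm = "numeric",
    psfFwhmLateralNm = "numeric",
    psfFwhmAxialNm = "numeric",
    detectorMax = "numeric",
    background = "numeric",
    readNoiseSd = "numeric"
  )
)

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("STED", "confocal"))
    msg <- c(msg, "mode must be 'STED' or 'confocal'")
  if (object@pixelSizeNm <= 0 || object@stepNm <= 0)
    msg <- c(msg, "pixel sizes must be > 0")
  if (object@psfFwhmLateralNm <= 0 || object@psfFwhmAxialNm <= 0)
    msg <- c(msg, "PSF FWHMs must be > 0")
  if (object@background < 0)
    msg <- c(msg, "background must be >= 0")
  if (object@detectorMax <= object@background)
    msg <- c(msg, "saturation level must exceed the background")
  if (object@readNoiseSd < 0)
    msg <- c(msg, "read-noise SD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Voxel grid
#'
#' A 3D scalar intensity array with physical voxel spacing, an origin, and a
#' channel role tag ("np", "membrane", "lamina", ...). Arrays are indexed
#' `[z, y, x]`.
#'
#' @slot data 3D numeric array of non-negative intensities.
#' @slot spacingNm Voxel spacing, `c(z, y, x)` in nm.
#' @slot originNm Physical position of the centre of voxel `[1, 1, 1]`,
#'   `c(z, y, x)` in nm.
#' @slot channel Channel role tag.
#' @export
setClass("VoxelGrid",
  slots = c(
    data = "array",
    spacingNm = "numeric",
    originNm = "numeric",
    channel = "character"
  )
)

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacingNm) != 3L || any(object@spacingNm <= 0))
    msg <- c(msg, "spacingNm must be three positive values (z, y, x)")
  if (length(object@originNm) != 3L)
    msg <- c(msg, "originNm must have three values (z, y, x)")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "intensities must be finite")
  else if (any(object@data < 0))
    msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Cell phantom
#'
#' Geometric stand-in for an adherent epithelial cell: the upper half of an
#' ellipsoid resting on the substrate plane z = 0, with an ellipsoidal
#' nucleus inside and a thin membrane shell on the whole plasma surface
#' (curved cap and basal face).
#'
#' @slot cellSemiAxesUm Cell semi-axes `c(x, y, z)` in micrometres.
#' @slot nucleusSemiAxesUm Nucleus semi-axes `c(x, y, z)` in micrometres.
#' @slot nucleusCenterUm Nucleus centre `c(x, y, z)` in micrometres.
#' @slot shellThicknessNm Membrane shell thickness (nm).
#' @export
setClass("CellPhantom",
  slots = c(
    cellSemiAxesUm = "numeric",
    nucleusSemiAxesUm = "numeric",
    nucleusCenterUm = "numeric",
    shellThicknessNm = "numeric"
  )
)

setValidity("CellPhantom", function(object) {
  msg <- character()
  if (any(object@cellSemiAxesUm <= 0) || any(object@nucleusSemiAxesUm <= 0))
    msg <- c(msg, "all semi-axes must be positive")
  if (object@shellThicknessNm <= 0)
    msg <- c(msg, "shell thickness must be > 0")
  if (!length(msg) && !.nucleusContained(object))
    msg <- c(msg, "nucleus is not strictly contained in the cell interior")
  if (length(msg)) msg else TRUE
})

#' Cell mask
#'
#' Boolean 3D region of interest produced by [segmentCell()], with the
#' projected area and enclosed volume computed from the mask voxels, and the
#' provenance of the segmentation (threshold, operations applied).
#'
#' @slot mask 3D logical array, same geometry as the source grid.
#' @slot spacingNm Voxel spacing `c(z, y, x)` in nm.
#' @slot originNm Centre of voxel `[1, 1, 1]`, `c(z, y, x)` in nm.
#' @slot threshold Intensity threshold used for the isosurface.
#' @slot provenance List of applied operations and parameters.
#' @export
setClass("CellMask",
  slots = c(
    mask = "array",
    spacingNm = "numeric",
    originNm = "numeric",
    threshold = "numeric",
    provenance = "list"
  )
)

setValidity("CellMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    msg <- c(msg, "mask must be a 3D logical array")
  if (length(object@spacingNm) != 3L || any(object@spacingNm <= 0))
    msg <- c(msg, "spacingNm must be three positive values")
  if (length(msg)) msg else TRUE
})

#' Particle specification
#'
#' Physical description of a (primary) particle: diameter, mass density and
#' an optional number of primary particles per agglomerate.
#'
#' @slot diameterNm Particle diameter (nm).
#' @slot densityGcm3 Particle mass density (g cm^-3).
#' @slot clusterSize Number of primary particles per agglomerate (>= 1).
#' @export
setClass("ParticleSpec",
  slots = c(
    diameterNm = "numeric",
    densityGcm3 = "numeric",
    clusterSize = "numeric"
  )
)

setValidity("ParticleSpec", function(object) {
  msg <- character()
  if (object@diameterNm <= 0) msg <- c(msg, "diameter must be > 0")
  if (object@densityGcm3 <= 0) msg <- c(msg, "density must be > 0")
  if (object@clusterSize < 1 || object@clusterSize %% 1 != 0)
    msg <- c(msg, "cluster size must be an integer >= 1")
  if (length(msg)) msg else TRUE
})

#' Exposure medium and column geometry
#'
#' The fluid column standing above the cell monolayer during exposure.
#' Height is derived from volume and base area when not given explicitly;
#' if all three are set they must be consistent within 5%.
#'
#' @slot temperatureK Temperature (K).
#' @slot viscosityPaS Dynamic viscosity (Pa s).
#' @slot densityGcm3 Medium density (g cm^-3).
#' @slot volumeMl Medium volume (mL).
#' @slot baseAreaCm2 Growth/base area of the well (cm^2).
#' @slot heightMm Column height (mm).
#' @export
setClass("MediumSpec",
  slots = c(
    temperatureK = "numeric",
    viscosityPaS = "numeric",
    densityGcm3 = "numeric",
    volumeMl = "numeric",
    baseAreaCm2 = "numeric",
    heightMm = "numeric"
  )
)

setValidity("MediumSpec", function(object) {
  msg <- character()
  if (object@temperatureK <= 0) msg <- c(msg, "temperature must be > 0")
  if (object@viscosityPaS <= 0) msg <- c(msg, "viscosity must be > 0")
  if (object@densityGcm3 <= 0) msg <- c(msg, "medium density must be > 0")
  if (object@heightMm <= 0) msg <- c(msg, "column height must be > 0")
  if (is.finite(object@volumeMl) && is.finite(object@baseAreaCm2)) {
    h <- 10 * object@volumeMl / object@baseAreaCm2  # mm
    if (abs(h - object@heightMm) / object@heightMm > 0.05)
      msg <- c(msg, "height, volume and base area are inconsistent (> 5%)")
  }
  if (length(msg)) msg else TRUE
})

#' Deposition result
#'
#' Output of [simulateDeposition()]: the deposited number fraction, the
#' deposited number per unit area, the deposition time series, and solver
#' diagnostics (discrete mass-balance error, grid size, cell Peclet number).
#'
#' @slot fraction Deposited number fraction at the end of the simulation.
#' @slot perAreaCm2 Deposited particle number per cm^2.
#' @slot timesH Time points of the series (hours).
#' @slot fractionSeries Deposited fraction at `timesH`.
#' @slot diagnostics List of solver diagnostics.
#' @export
setClass("DepositionResult",
  slots = c(
    fraction = "numeric",
    perAreaCm2 = "numeric",
    timesH = "numeric",
    fractionSeries = "numeric",
    diagnostics = "list"
  )
)

setValidity("DepositionResult", function(object) {
  msg <- character()
  if (object@fraction < -1e-12 || object@fraction > 1 + 1e-12)
    msg <- c(msg, "fraction must lie in [0, 1]")
  if (is.unsorted(object@fractionSeries, strictly = FALSE))
    msg <- c(msg, "deposited fraction must be non-decreasing in time")
  if (length(msg)) msg else TRUE
})

#' Point-spread function kernel
#'
#' Discrete separable PSF: a 3D non-negative array with unit sum, stored
#' together with its three 1D factors for fast separable convolution.
#'
#' @slot kernel 3D array summing to 1.
#' @slot kz,ky,kx 1D kernel factors (each sums to 1).
#' @slot spacingNm Voxel spacing `c(z, y, x)` in nm.
#' @slot sigmaNm Continuous-generator sigma `c(z, y, x)` in nm (NA for
#'   hand-built kernels).
#' @export
setClass("PSFKernel",
  slots = c(
    kernel = "array",
    kz = "numeric", ky = "numeric", kx = "numeric",
    spacingNm = "numeric",
    sigmaNm = "numeric"
  )
)

setValidity("PSFKernel", function(object) {
  msg <- character()
  if (any(object@kernel < 0)) msg <- c(msg, "kernel must be non-negative")
  if (abs(sum(object@kernel) - 1) > 1e-9)
    msg <- c(msg, "kernel must sum to 1 within 1e-9")
  if (any(lengths(list(object@kz, object@ky, object@kx)) %% 2 == 0))
    msg <- c(msg, "kernel factors must have odd length (centred peak)")
  if (length(msg)) msg else TRUE
})
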