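# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for npquant containers
#' @description Small accessor generics: raw voxel data, voxel spacing,
#'   grid origin, channel role, mask geometry and provenance.
#' @param x An npquant object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("spacingNm", function(x) standardGeneric("spacingNm"))
#' @rdname accessors
#' @export
setGeneric("originNm", function(x) standardGeneric("originNm"))
#' @rdname accessors
#' @export
setGeneric("channelRole", function(x) standardGeneric("channelRole"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setMethod("voxelData", "VoxelGrid", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("spacingNm", "VoxelGrid", function(x) x@spacingNm)
#' @rdname accessors
#' @export
setMethod("originNm", "VoxelGrid", function(x) x@originNm)
#' @rdname accessors
#' @export
setMethod("channelRole", "VoxelGrid", function(x) x@channel)
#' @rdname accessors
#' @export
setMethod("voxelData", "CellMask", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("spacingNm", "CellMask", function(x) x@spacingNm)
#' @rdname accessors
#' @export
setMethod("originNm", "CellMask", function(x) x@originNm)
#' @rdname accessors
#' @export
setMethod("provenance", "CellMask", function(x) x@provenance)

#' Projected area and enclosed volume of a cell mask
#'
#' Projected area is the area of the xy projection of the mask (used for the
#' per-cell-area object density); volume is the number of mask voxels times
#' the voxel volume.
#'
#' @param x A [CellMask-class].
#' @return Area in square micrometres / volume in cubic micrometres.
#' @export
setGeneric("maskAreaUm2", function(x) standardGeneric("maskAreaUm2"))

#' @rdname maskAreaUm2
#' @export
setGeneric("maskVolumeUm3", function(x) standardGeneric("maskVolumeUm3"))

#' @rdname maskAreaUm2
#' @export
setMethod("maskAreaUm2", "CellMask", function(x) {
  proj <- apply(x@mask, c(2, 3), any)
  sum(proj) * x@spacingNm[2] * x@spacingNm[3] / 1e6
})

#' @rdname maskAreaUm2
#' @export
setMethod("maskVolumeUm3", "CellMask", function(x) {
  sum(x@mask) * prod(x@spacingNm) / 1e9
})

#' Deposition result accessors
#'
#' @param x A [DepositionResult-class].
#' @return Deposited number fraction, deposited number per cm^2, or a
#'   data.frame time series of the deposited fraction.
#' @export
setGeneric("depositedFraction", function(x) standardGeneric("depositedFraction"))
#' @rdname depositedFraction
#' @export
setGeneric("depositedPerAreaCm2", function(x) standardGeneric("depositedPerAreaCm2"))
#' @rdname depositedFraction
#' @export
setGeneric("depositionSeries", function(x) standardGeneric("depositionSeries"))

#' @rdname depositedFraction
#' @export
setMethod("depositedFraction", "DepositionResult", function(x) x@fraction)
#' @rdname depositedFraction
#' @export
setMethod("depositedPerAreaCm2", "DepositionResult", function(x) x@perAreaCm2)
#' @rdname depositedFraction
#' @export
setMethod("depositionSeries", "DepositionResult", function(x) {
  data.frame(timeH = x@timesH, fraction = x@fractionSeries)
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "AcquisitionConfig", function(object) {
  cat(sprintf(
    "AcquisitionConfig [%s]: %g nm pixels, %g nm z-step, PSF FWHM %g/%g nm (lat/ax)\n",
    object@mode, object@pixelSizeNm, object@stepNm,
    object@psfFwhmLateralNm, object@psfFwhmAxialNm))
  cat(sprintf("  detector max %g, background %g, read noise SD %g\n",
              object@detectorMax, object@background, object@readNoiseSd))
})

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelGrid '%s': %d x %d x %d voxels (z,y,x), spacing %g/%g/%g nm\n",
              object@channel, d[1], d[2], d[3],
              object@spacingNm[1], object@spacingNm[2], object@spacingNm[3]))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "CellPhantom", function(object) {
  cat(sprintf("CellPhantom: cell semi-axes (%g, %g, %g) um, nucleus (%g, %g, %g) um\n",
              object@cellSemiAxesUm[1], object@cellSemiAxesUm[2],
              object@cellSemiAxesUm[3], object@nucleusSemiAxesUm[1],
              object@nucleusSemiAxesUm[2], object@nucleusSemiAxesUm[3]))
  cat(sprintf("  volume %.0f um^3, projected area %.0f um^2, shell %g nm\n",
              phantomVolumeUm3(object), phantomAreaUm2(object),
              object@shellThicknessNm))
})

setMethod("show", "CellMask", function(object) {
  cat(sprintf("CellMask: %s voxels, projected area %.1f um^2, volume %.1f um^3\n",
              format(sum(object@mask), big.mark = ","),
              maskAreaUm2(object), maskVolumeUm3(object)))
  cat(sprintf("  threshold %.4g; operations: %s\n", object@threshold,
              paste(names(object@provenance), collapse = ", ")))
})

setMethod("show", "ParticleSpec", function(object) {
  cat(sprintf("ParticleSpec: d = %g nm, density %g g cm^-3, cluster size %d\n",
              object@diameterNm, object@densityGcm3, as.integer(object@clusterSize)))
})

setMethod("show", "MediumSpec", function(object) {
  cat(sprintf(
    "MediumSpec: %.2f K, %.3g Pa s, %.3g g cm^-3; %g mL over %g cm^2 (h = %.3g mm)\n",
    object@temperatureK, object@viscosityPaS, object@densityGcm3,
    object@volumeMl, object@baseAreaCm2, object@heightMm))
})

setMethod("show", "DepositionResult", function(object) {
  cat(sprintf("DepositionResult: deposited fraction %.4f (%.3g cm^-2) after %.3g h\n",
              object@fraction, object@perAreaCm2, max(object@timesH)))
  cat(sprintf("  mass balance error %.2e, %d nodes, %d steps\n",
              object@diagnostics$massBalanceError,
              object@diagnostics$nNodes, object@diagnostics$nSteps))
})

setMethod("show", "PSFKernel", function(object) {
  d <- dim(object@kernel)
  cat(sprintf("PSFKernel: %d x %d x %d (z,y,x), spacing %g/%g/%g nm\n",
              d[1], d[2], d[3], object@spacingNm[1], object@spacingNm[2],
              object@spacingNm[3]))
})
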