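# Stack, object-table and descriptor I/O.
# Stacks are multi-page TIFFs (one page per z slice) with a YAML sidecar
# carrying the physical metadata; TIFF alone cannot hold the voxel sizes.

.sidecarPath <- function(path) sub("\\.tiff?$", ".yml", path)

#' Write / read a voxel grid as TIFF + YAML sidecar
#'
#' `writeStack()` stores the stack as a 16-bit multi-page TIFF (one page per
#' z slice) plus a `.yml` sidecar with voxel spacing, origin, channel role
#' and the intensity scale. Integer counts up to the scale (default 65535)
#' round-trip losslessly. `readStack()` refuses to read a TIFF without its
#' sidecar: a bare TIFF has no voxel-size metadata, and all downstream
#' geometry depends on it.
#'
#' @param grid A [VoxelGrid-class].
#' @param path TIFF file path.
#' @param scale Intensity value mapped to the top of the 16-bit range.
#' @return `writeStack()` the path, invisibly; `readStack()` a
#'   [VoxelGrid-class].
#' @export
writeStack <- function(grid, path, scale = 65535) {
  x <- grid@data
  if (max(x) > scale)
    warning("intensities exceed the scale; stored stack will clip")
  d <- dim(x)
  pages <- lapply(seq_len(d[1]), function(z)
    matrix(pmin(x[z, , ], scale) / scale, d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(spacingNm = as.numeric(grid@spacingNm),
               originNm = as.numeric(grid@originNm),
               channel = grid@channel,
               scale = scale,
               nz = d[1], ny = d[2], nx = d[3])
  yaml::write_yaml(meta, .sidecarPath(path))
  invisible(path)
}

#' @rdname writeStack
#' @export
readStack <- function(path) {
  sc <- .sidecarPath(path)
  if (!file.exists(sc))
    stop("no acquisition descriptor found (expected ", sc, "): voxel sizes ",
         "are required; write stacks with writeStack() or provide the sidecar")
  meta <- yaml::read_yaml(sc)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(length(pages), dim(pages[[1]]))
  if (!is.null(meta$nz) && (meta$nz != d[1] || meta$ny != d[2] || meta$nx != d[3]))
    stop("stack shape does not match its descriptor")
  x <- array(0, d)
  for (z in seq_len(d[1])) x[z, , ] <- round(pages[[z]] * meta$scale)
  new("VoxelGrid", data = x, spacingNm = as.numeric(meta$spacingNm),
      originNm = as.numeric(meta$originNm), channel = meta$channel)
}

#' Write / read an object or ground-truth table as CSV
#'
#' Plain CSV with full double precision (15 significant digits; round-trips
#' to better than 1e-12 relative).
#'
#' @param objects A data frame.
#' @param path CSV file path.
#' @return `writeObjects()` the path, invisibly; `readObjects()` the data
#'   frame.
#' @export
writeObjects <- function(objects, path) {
  df <- as.data.frame(objects)
  attr(df, "voxelIndices") <- NULL
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeObjects
#' @export
readObjects <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Serialise an acquisition configuration to YAML
#'
#' @param acq An [AcquisitionConfig-class].
#' @param path YAML file path.
#' @return `writeAcquisition()` the path invisibly; `readAcquisition()` the
#'   [AcquisitionConfig-class].
#' @export
writeAcquisition <- function(acq, path) {
  yaml::write_yaml(list(
    mode = acq@mode, pixelSizeNm = acq@pixelSizeNm, stepNm = acq@stepNm,
    psfFwhmLateralNm = acq@psfFwhmLateralNm,
    psfFwhmAxialNm = acq@psfFwhmAxialNm,
    detectorMax = acq@detectorMax, background = acq@background,
    readNoiseSd = acq@readNoiseSd), path)
  invisible(path)
}

#' @rdname writeAcquisition
#' @export
readAcquisition <- function(path) {
  m <- yaml::read_yaml(path)
  new("AcquisitionConfig", mode = m$mode, pixelSizeNm = m$pixelSizeNm,
      stepNm = m$stepNm, psfFwhmLateralNm = m$psfFwhmLateralNm,
      psfFwhmAxialNm = m$psfFwhmAxialNm, detectorMax = m$detectorMax,
      background = m$background, readNoiseSd = m$readNoiseSd)
}
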