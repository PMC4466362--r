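# Nanoparticle object detection, measurement and inside-cell counting.

#' Detect nanoparticle objects in the NP channel
#'
#' Implements the object-segmentation chain: (1) Otsu threshold `T` on the
#' channel; (2) Gaussian smoothing with `sigmaUm` (the pre-filter of the
#' watershed); (3) watershed on the smoothed landscape restricted to the
#' thresholded foreground, so touching agglomerates split at the smoothed
#' intensity minima between peaks; (4) discard of dim objects whose peak
#' intensity lies below `T + discardFraction * (max - T)`, with `max` the
#' channel maximum; (5) measurement of the surviving objects.
#'
#' A blank channel (no voxels above threshold, or a constant image) yields
#' an empty table, not an error. Objects touching the axial stack borders
#' are kept but flagged (`zEdge`).
#'
#' @param grid Nanoparticle-channel [VoxelGrid-class].
#' @param sigmaUm Gaussian pre-filter sigma for the watershed, in
#'   micrometres. The default (2.0) is deliberately large relative to
#'   sub-resolution particles: it splits micrometre-scale agglomerates, not
#'   neighbouring single particles. It is an honest knob; see
#'   [detectParticles()]'s sensitivity note in the vignette.
#' @param discardFraction Fraction of the threshold-to-maximum range below
#'   which objects are discarded (default 0.05).
#' @param minVoxels Minimum object size in voxels.
#' @param minContrastSigma Detection guard: the mean of the thresholded
#'   foreground must exceed the background mean by this many background
#'   standard deviations, otherwise the channel is treated as blank (pure
#'   shot noise has no 5-sigma class separation, a real particle signal
#'   does).
#' @return Data frame (one row per object) with columns `label`,
#'   `zNm`, `yNm`, `xNm` (intensity-weighted centroid), `voxels`, `peak`,
#'   `mean`, `widthNm`, `zEdge`, `inside` (NA until classified). The voxel
#'   linear indices of every object are attached as the `voxelIndices`
#'   attribute; the Otsu threshold as `threshold`.
#' @export
detectParticles <- function(grid, sigmaUm = 2.0, discardFraction = 0.05,
                            minVoxels = 1, minContrastSigma = 5) {
  if (sigmaUm <= 0) stop("sigma must be > 0")
  if (discardFraction < 0 || discardFraction >= 1)
    stop("discard fraction must lie in [0, 1)")
  x <- grid@data
  d <- dim(x)
  emptyTab <- data.frame(label = integer(0), zNm = numeric(0),
                         yNm = numeric(0), xNm = numeric(0),
                         voxels = integer(0), peak = numeric(0),
                         mean = numeric(0), widthNm = numeric(0),
                         zEdge = logical(0), inside = logical(0))
  thr <- tryCatch(otsuThreshold(grid), error = function(e) NULL)
  if (is.null(thr)) return(emptyTab)
  fg <- x > thr
  dim(fg) <- d
  if (!any(fg)) return(emptyTab)
  bgSd <- stats::sd(x[!fg])
  if (is.finite(bgSd) &&
      mean(x[fg]) - mean(x[!fg]) < minContrastSigma * bgSd)
    return(emptyTab)

  sigVox <- sigmaUm * 1000 / grid@spacingNm
  smoothK <- lapply(sigVox, function(s) .gauss1d(s, 1, 2.5))
  sm <- .conv_sep3(x, smoothK[[1]], smoothK[[2]], smoothK[[3]])

  # seeds: plateau-collapsed local maxima of the smoothed landscape in fg
  mx <- .local_maxima(sm, fg)
  seeds <- .label3d(mx)
  # components without a seed (possible on the flank of a larger neighbour's
  # smooth hill) are seeded at their own brightest voxel
  comp <- .label3d(fg)
  nComp <- max(comp)
  hasSeed <- unique(comp[seeds > 0])
  orphan <- setdiff(seq_len(nComp), hasSeed)
  if (length(orphan)) {
    nextSeed <- max(seeds)
    fgIdx <- which(fg)
    compId <- comp[fgIdx]
    for (oc in orphan) {
      ii <- fgIdx[compId == oc]
      nextSeed <- nextSeed + 1L
      seeds[ii[which.max(sm[ii])]] <- nextSeed
    }
  }
  lab <- .watershed_seeded(sm, fg, seeds)

  idx <- which(lab > 0)
  labs <- lab[idx]
  byObj <- split(idx, labs)
  byObj <- byObj[lengths(byObj) >= minVoxels]
  if (!length(byObj)) return(emptyTab)

  imax <- max(x)
  cutoff <- thr + discardFraction * (imax - thr)
  peaks <- vapply(byObj, function(ii) max(x[ii]), numeric(1))
  keep <- peaks >= cutoff
  # range-relative rule: the globally brightest object always survives
  keep[which.max(peaks)] <- TRUE
  byObj <- byObj[keep]
  peaks <- peaks[keep]

  sp <- grid@spacingNm; org <- grid@originNm
  rows <- lapply(seq_along(byObj), function(j) {
    ii <- byObj[[j]]
    ai <- arrayInd(ii, d)
    w <- x[ii]
    posZ <- org[1] + (ai[, 1] - 1) * sp[1]
    posY <- org[2] + (ai[, 2] - 1) * sp[2]
    posX <- org[3] + (ai[, 3] - 1) * sp[3]
    cz <- sum(w * posZ) / sum(w)
    data.frame(label = j,
               zNm = cz,
               yNm = sum(w * posY) / sum(w),
               xNm = sum(w * posX) / sum(w),
               voxels = length(ii),
               peak = max(w),
               mean = mean(w),
               widthNm = .lateralWidth(ai, cz, sp, org),
               zEdge = any(ai[, 1] == 1L) || any(ai[, 1] == d[1]),
               inside = NA)
  })
  out <- do.call(rbind, rows)
  out$label <- seq_len(nrow(out))
  attr(out, "voxelIndices") <- unname(byObj)
  attr(out, "threshold") <- thr
  attr(out, "sigmaUm") <- sigmaUm
  out
}

# lateral width: maximum in-plane extent of the object's voxels in the focal
# slice of its centroid. Width of a single voxel equals one pixel.
.lateralWidth <- function(ai, centroidZNm, sp, org) {
  zIdx <- round((centroidZNm - org[1]) / sp[1]) + 1
  zs <- unique(ai[, 1])
  zUse <- zs[which.min(abs(zs - zIdx))]
  pl <- ai[ai[, 1] == zUse, , drop = FALSE]
  py <- (pl[, 2] - 1) * sp[2]
  px <- (pl[, 3] - 1) * sp[3]
  if (nrow(pl) > 2) {
    h <- chull(px, py)
    px <- px[h]; py <- py[h]
  }
  dd <- 0
  if (length(px) > 1) {
    dmat <- outer(px, px, "-")^2 + outer(py, py, "-")^2
    dd <- sqrt(max(dmat))
  }
  dd + mean(sp[2:3])
}

#' Measure the lateral width of one detected object
#'
#' Maximum extent of the object's segmented voxels in the focal (xy) plane
#' of its centroid, in nm. For sub-resolution particles this approximates
#' the imaged PSF footprint; agglomerates give widths beyond the
#' single-particle band.
#'
#' @param object One row of the [detectParticles()] table.
#' @param objects The full table (carries the voxel indices).
#' @param grid The [VoxelGrid-class] the objects were detected in.
#' @return Width in nm.
#' @export
measureLateralWidth <- function(object, objects, grid) {
  ii <- attr(objects, "voxelIndices")[[object$label]]
  ai <- arrayInd(ii, dim(grid@data))
  .lateralWidth(ai, object$zNm, grid@spacingNm, grid@originNm)
}

#' Classify objects as internalized
#'
#' An object is internalized iff every one of its voxels lies inside the
#' cell mask (strict containment: particles attached to the outside of the
#' membrane are to be excluded, at the price of under- rather than
#' over-counting).
#'
#' @param objects Table from [detectParticles()].
#' @param mask A [CellMask-class] on the same lattice as the detection grid
#'   (use [resampleMask()] first if the channels were sampled differently).
#' @param grid The detection [VoxelGrid-class].
#' @return The table with the `inside` column filled.
#' @export
classifyInside <- function(objects, mask, grid) {
  if (!all(dim(mask@mask) == dim(grid@data)) ||
      any(abs(mask@spacingNm - grid@spacingNm) > 1e-6) ||
      any(abs(mask@originNm - grid@originNm) > 1e-3))
    stop("mask and objects do not share geometry; resample the mask first")
  vox <- attr(objects, "voxelIndices")
  if (nrow(objects))
    objects$inside <- vapply(vox, function(ii) all(mask@mask[ii]), logical(1))
  objects
}

#' Per-cell summary of internalized objects
#'
#' Counts the inside-flagged objects per cell and per projected cell area,
#' plus the total object number and the mean object intensity.
#'
#' @param objects Classified table from [classifyInside()].
#' @param mask The [CellMask-class] defining the cell.
#' @return One-row data frame: `objectsPerCell`, `objectsPerAreaUm2`,
#'   `cellAreaUm2`, `cellVolumeUm3`, `totalObjects`, `meanIntensity`.
#' @export
summarizeObjects <- function(objects, mask) {
  areaUm2 <- maskAreaUm2(mask)
  insideN <- sum(objects$inside %in% TRUE)
  data.frame(
    objectsPerCell = insideN,
    objectsPerAreaUm2 = insideN / areaUm2,
    cellAreaUm2 = areaUm2,
    cellVolumeUm3 = maskVolumeUm3(mask),
    totalObjects = nrow(objects),
    meanIntensity = if (insideN)
      mean(objects$mean[objects$inside %in% TRUE]) else 0)
}
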