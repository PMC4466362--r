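# Whole-cell mask extraction from the membrane channel.

#' Otsu intensity threshold
#'
#' Global histogram threshold maximising the between-class variance, using
#' 256 equal-width bins over the data range of the full 3D stack. Returns
#' the intensity at the upper edge of the background class; voxels with
#' values strictly above the threshold are foreground.
#'
#' @param grid A [VoxelGrid-class] or a numeric array.
#' @param nbins Number of histogram bins.
#' @return The threshold intensity.
#' @examples
#' x <- array(c(rep(10, 500), rep(200, 500)), c(10, 10, 10))
#' otsuThreshold(x)   # between 10 and 200
#' @export
otsuThreshold <- function(grid, nbins = 256) {
  x <- if (is(grid, "VoxelGrid")) grid@data else grid
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("constant image: no separable intensity classes")
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), nbins)
  counts <- tabulate(bin, nbins)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  w0 <- cumsum(p)[-nbins]
  mu0 <- cumsum(p * mids)[-nbins]
  muT <- sum(p * mids)
  valid <- w0 > 0 & w0 < 1
  sb2 <- rep(-Inf, nbins - 1)
  sb2[valid] <- (muT * w0[valid] - mu0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  k <- which.max(sb2)
  breaks[k + 1]
}

# offsets of a digital ball of the given radius (in voxel units)
.ballOffsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= radius^2, ]
  as.matrix(g)
}

.closing <- function(mask, offsets) {
  .morph3d(.morph3d(mask, offsets, TRUE), offsets, FALSE)
}

.opening <- function(mask, offsets) {
  .morph3d(.morph3d(mask, offsets, FALSE), offsets, TRUE)
}

# even-odd point-in-polygon; polygon is a data.frame/matrix with columns x, y
.pointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Segment the whole-cell region of interest
#'
#' Builds the 3D cell mask from the membrane channel: Otsu binarisation;
#' morphological closing then opening with a digital ball of
#' `openCloseVoxels` voxel extent (radius `openCloseVoxels / 2`; the
#' 2-voxel default closes 2-voxel holes in the isosurface while a thin
#' 3-voxel shell survives the opening); 3D hole filling; per-slice 2D hole
#' filling in all three axis orientations so cavities cut off by the stack
#' border are filled too; then the largest connected component, or the
#' components whose footprint intersects a manually drawn polygon.
#'
#' An optional boundary refinement places the mask boundary on the membrane
#' mid-plane instead of the outer isosurface: for a thin shell blurred by a
#' Gaussian PSF, the Otsu isosurface lies `sigma * sqrt(2 log(I_shell / T))`
#' outside the mid-plane along each axis (`I_shell` the shell peak
#' intensity, `T` the threshold), so the filled region is eroded by that
#' predicted offset (anisotropic: lateral and axial PSF widths differ).
#' The step is off by default and enabled by the pipeline, which knows the
#' channel's PSF; without it the mask is bounded by the outer isosurface
#' and over-estimates the cell volume by roughly half a PSF width of
#' boundary shift.
#'
#' @param grid Membrane-channel [VoxelGrid-class] (deconvolved or raw).
#' @param polygon Optional manual mask: a matrix/data.frame of (x, y)
#'   vertices in nm selecting the cell(s) of interest when several cells are
#'   in frame.
#' @param openCloseVoxels Structuring-element extent in voxels (its radius
#'   is half this).
#' @param refinePsfFwhmNm Optional `c(lateral, axial)` PSF FWHM (nm) of the
#'   channel, enabling the boundary refinement; `NULL` disables.
#' @return A [CellMask-class]. Errors if the mask is empty after filtering.
#' @export
segmentCell <- function(grid, polygon = NULL, openCloseVoxels = 2,
                        refinePsfFwhmNm = NULL) {
  thr <- otsuThreshold(grid)
  fg <- grid@data > thr
  dim(fg) <- dim(grid@data)
  offs <- .ballOffsets(openCloseVoxels / 2)
  m <- .closing(fg, offs)
  m <- .opening(m, offs)
  m <- .fill_holes3d(m)
  for (ax in 0:2) m <- .fill_holes_slices(m, ax)
  lab <- .label3d(m)
  if (max(lab) == 0)
    stop("cell segmentation produced an empty mask (threshold = ",
         format(thr), "); check the membrane channel")
  keep <- if (is.null(polygon)) {
    which.max(tabulate(lab[lab > 0]))
  } else {
    poly <- as.matrix(polygon)
    d <- dim(m)
    proj <- apply(array(lab, d), c(2, 3), max)     # max label per (y, x)
    ys <- grid@originNm[2] + (seq_len(d[2]) - 1) * grid@spacingNm[2]
    xs <- grid@originNm[3] + (seq_len(d[3]) - 1) * grid@spacingNm[3]
    yy <- rep(ys, times = d[3]); xx <- rep(xs, each = d[2])
    sel <- .pointInPolygon(xx, yy, poly)
    labs <- setdiff(unique(proj[sel]), 0L)
    if (!length(labs))
      stop("manual polygon does not intersect any segmented component")
    labs
  }
  m <- array(lab %in% keep, dim(m))
  erNm <- NULL
  if (!is.null(refinePsfFwhmNm)) {
    shellI <- stats::quantile(grid@data[fg & m], 0.90, names = FALSE)
    if (is.finite(shellI) && shellI > thr) {
      stretch <- sqrt(2 * log(shellI / thr))
      erNm <- fwhmToSigma(refinePsfFwhmNm) * stretch   # (lateral, axial)
      r <- c(erNm[2] / grid@spacingNm[1],              # voxels (z, y, x)
             erNm[1] / grid@spacingNm[2],
             erNm[1] / grid@spacingNm[3])
      ri <- ceiling(r)
      g <- expand.grid(dz = -ri[1]:ri[1], dy = -ri[2]:ri[2],
                       dx = -ri[3]:ri[3])
      g <- g[(g$dz / max(r[1], 1e-9))^2 + (g$dy / max(r[2], 1e-9))^2 +
               (g$dx / max(r[3], 1e-9))^2 <= 1, ]
      if (nrow(g) > 1) m <- .morph3d(m, as.matrix(g), FALSE)
    }
  }
  if (!any(m)) stop("cell segmentation produced an empty mask")
  new("CellMask", mask = m, spacingNm = grid@spacingNm,
      originNm = grid@originNm, threshold = thr,
      provenance = list(otsu = thr, openCloseVoxels = openCloseVoxels,
                        fill = "3D + per-slice (z, y, x)",
                        component = if (is.null(polygon)) "largest"
                                    else "polygon",
                        boundaryErosionNm = erNm))
}

#' Resample a cell mask onto another grid
#'
#' Nearest-neighbour resampling by physical position, used to carry a mask
#' segmented on the (coarser) membrane channel onto the nanoparticle
#' channel's lattice before inside/outside classification.
#'
#' @param mask A [CellMask-class].
#' @param grid Target [VoxelGrid-class] (or geometry list with `dim`,
#'   `spacingNm`, `originNm`).
#' @return A [CellMask-class] on the target lattice.
#' @export
resampleMask <- function(mask, grid) {
  if (is(grid, "VoxelGrid"))
    grid <- list(dim = dim(grid@data), spacingNm = grid@spacingNm,
                 originNm = grid@originNm)
  d <- as.integer(grid$dim)
  ds <- dim(mask@mask)
  idxAxis <- function(ax) {
    pos <- grid$originNm[ax] + (seq_len(d[ax]) - 1) * grid$spacingNm[ax]
    i <- round((pos - mask@originNm[ax]) / mask@spacingNm[ax]) + 1
    pmin(pmax(i, 1L), ds[ax])
  }
  iz <- idxAxis(1); iy <- idxAxis(2); ix <- idxAxis(3)
  out <- mask@mask[iz, iy, ix, drop = FALSE]
  dim(out) <- d
  new("CellMask", mask = out, spacingNm = grid$spacingNm,
      originNm = grid$originNm, threshold = mask@threshold,
      provenance = c(mask@provenance, list(resampled = TRUE)))
}
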