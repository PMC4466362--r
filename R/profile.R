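# Line-profile extraction and Gaussian FWHM fitting (PSF / single-particle
# width calibration).

#' Extract an intensity profile along a line segment
#'
#' Samples the stack by trilinear interpolation along the segment from `p0`
#' to `p1` at a fixed step. Positions are reported as distances (nm) from
#' `p0` along the segment.
#'
#' @param grid A [VoxelGrid-class].
#' @param p0,p1 Segment end points, `c(z, y, x)` in nm. Both must lie inside
#'   the grid.
#' @param stepNm Sampling step (nm); defaults to half the smallest voxel
#'   spacing.
#' @return Data frame with `positionNm` (strictly increasing) and
#'   `intensity`.
#' @export
extractProfile <- function(grid, p0, p1, stepNm = NULL) {
  sp <- grid@spacingNm; org <- grid@originNm; d <- dim(grid@data)
  hi <- org + (d - 1) * sp
  chk <- function(p) all(p >= org - 1e-9) && all(p <= hi + 1e-9)
  if (!chk(p0) || !chk(p1))
    stop("profile end points must lie inside the grid")
  if (is.null(stepNm)) stepNm <- min(sp) / 2
  len <- sqrt(sum((p1 - p0)^2))
  nS <- max(5L, ceiling(len / stepNm) + 1L)
  tt <- seq(0, 1, length.out = nS)
  pts <- cbind(p0[1] + tt * (p1[1] - p0[1]),
               p0[2] + tt * (p1[2] - p0[2]),
               p0[3] + tt * (p1[3] - p0[3]))
  # fractional voxel coordinates
  fz <- (pts[, 1] - org[1]) / sp[1]
  fy <- (pts[, 2] - org[2]) / sp[2]
  fx <- (pts[, 3] - org[3]) / sp[3]
  interp <- function(f, n) {
    i0 <- pmin(pmax(floor(f), 0), n - 1)
    list(i0 = i0 + 1, i1 = pmin(i0 + 2, n), w = f - i0)
  }
  az <- interp(fz, d[1]); ay <- interp(fy, d[2]); ax <- interp(fx, d[3])
  val <- numeric(nS)
  x <- grid@data
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    iz <- if (bz) az$i1 else az$i0
    iy <- if (by) ay$i1 else ay$i0
    ix <- if (bx) ax$i1 else ax$i0
    w <- (if (bz) az$w else 1 - az$w) *
         (if (by) ay$w else 1 - ay$w) *
         (if (bx) ax$w else 1 - ax$w)
    val <- val + w * x[cbind(iz, iy, ix)]
  }
  data.frame(positionNm = tt * len, intensity = val)
}

#' Fit a Gaussian to a line profile
#'
#' Least-squares fit of `A * exp(-(x - c)^2 / (2 s^2)) + b` to an intensity
#' profile with a single dominant peak, initialised from moments. The
#' constant offset accounts for background. Reports the FWHM
#' (`2 sqrt(2 log 2) * s`) and the parameter standard deviations from the
#' fit covariance (the FWHM SD is the sigma SD scaled by the same factor).
#'
#' @param profile Data frame from [extractProfile()] (columns `positionNm`,
#'   `intensity`), or any data frame with those columns.
#' @return List of class `"gaussianFit"`: `amplitude`, `centerNm`,
#'   `sigmaNm`, `offset`, `fwhmNm`, `se` (named vector including `fwhmNm`),
#'   and the raw optimiser result (`fit`).
#' @examples
#' x <- seq(-200, 200, by = 10)
#' prof <- data.frame(positionNm = x,
#'                    intensity = 100 * exp(-x^2 / (2 * 25.9^2)) + 3)
#' fitGaussianProfile(prof)$fwhmNm   # 61 nm
#' @export
fitGaussianProfile <- function(profile) {
  x <- profile$positionNm
  y <- profile$intensity
  if (length(x) < 5) stop("profile must have at least 5 samples")
  if (is.unsorted(x, strictly = TRUE)) stop("positions must be increasing")
  off0 <- min(y)
  a0 <- max(y) - off0
  if (a0 <= 0) stop("profile has no peak to fit")
  w <- pmax(y - off0, 0)
  c0 <- sum(w * x) / sum(w)
  s0 <- sqrt(sum(w * (x - c0)^2) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(x)) / 6
  resid <- function(p) p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4] - y
  fit <- minpack.lm::nls.lm(
    par = c(A = a0, cc = c0, s = s0, b = off0),
    fn = resid,
    lower = c(0, min(x) - diff(range(x)), 1e-6, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4)
    stop("Gaussian fit did not converge: ", fit$message,
         " (residual SD: ", format(stats::sd(fit$fvec)), ")")
  cf <- coef(fit)
  # parameter SDs from the Jacobian and residual variance
  se <- tryCatch({
    dof <- max(length(x) - 4, 1)
    s2 <- sum(fit$fvec^2) / dof
    sqrt(diag(s2 * solve(fit$hessian)))
  }, error = function(e) rep(NA_real_, 4))
  names(se) <- names(cf)
  out <- list(amplitude = unname(cf["A"]), centerNm = unname(cf["cc"]),
              sigmaNm = unname(cf["s"]), offset = unname(cf["b"]),
              fwhmNm = unname(cf["s"]) * FWHM_PER_SIGMA,
              se = c(se, fwhmNm = unname(se["s"]) * FWHM_PER_SIGMA),
              fit = fit)
  class(out) <- "gaussianFit"
  out
}

#' @export
print.gaussianFit <- function(x, ...) {
  cat(sprintf("Gaussian fit: FWHM %.1f +/- %.1f nm (sigma %.1f nm, centre %.1f nm)\n",
              x$fwhmNm, x$se["fwhmNm"], x$sigmaNm, x$centerNm))
  cat(sprintf("  amplitude %.3g, offset %.3g\n", x$amplitude, x$offset))
  invisible(x)
}
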