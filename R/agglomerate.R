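# Agglomerate packing models: estimated particle content of detected
# objects from their lateral widths.

#' Default single/agglomerate width cutoff
#'
#' 150 nm for 85 nm particles (objects wider than that are agglomerates);
#' 75 nm for 25 nm particles.
#'
#' @param diameterNm Primary particle diameter (nm).
#' @return Cutoff width in nm.
#' @export
defaultWidthCutoffNm <- function(diameterNm) {
  if (diameterNm >= 50) 150 else 75
}

#' Classify an object as single particle or agglomerate
#'
#' Single iff the lateral width is strictly below the cutoff; an object at
#' the cutoff counts as agglomerate.
#'
#' @param widthNm Lateral object width(s) in nm.
#' @param diameterNm Primary particle diameter (nm).
#' @param cutoffNm Width cutoff; default from [defaultWidthCutoffNm()].
#' @return Character vector, "single" or "agglomerate".
#' @examples
#' classifySingle(88, 85)    # single
#' classifySingle(578, 85)   # agglomerate
#' @export
classifySingle <- function(widthNm, diameterNm,
                           cutoffNm = defaultWidthCutoffNm(diameterNm)) {
  if (any(widthNm <= 0) || cutoffNm <= 0) stop("widths must be > 0")
  ifelse(widthNm < cutoffNm, "single", "agglomerate")
}

#' Particle count of an object under a packing model
#'
#' From a lateral width `w` and primary diameter `d`, the estimated number
#' of particles is
#' `n1 = round(w/d)` (linear chain),
#' `n2 = round(0.91 (w/d)^2)` (planar packing, density 0.91),
#' `n3 = round(0.74 (w/d)^3)` (3D close packing, density 0.74),
#' each at least 1 (a detected object is at least one particle).
#'
#' @param widthNm Object width(s) in nm.
#' @param diameterNm Primary particle diameter (nm).
#' @param model "1d", "2d" or "3d".
#' @return Integer particle count(s).
#' @examples
#' particlesInObject(578, 85, "1d")   # 7
#' particlesInObject(578, 85, "2d")   # 42
#' particlesInObject(578, 85, "3d")   # 233
#' @export
particlesInObject <- function(widthNm, diameterNm,
                              model = c("1d", "2d", "3d")) {
  model <- match.arg(model)
  if (any(widthNm <= 0) || diameterNm <= 0) stop("dimensions must be > 0")
  r <- widthNm / diameterNm
  n <- switch(model,
              "1d" = round(r),
              "2d" = round(0.91 * r^2),
              "3d" = round(0.74 * r^3))
  as.integer(pmax(1, n))
}

#' Per-cell particle totals under the agglomerate models
#'
#' Applies the three packing models to a set of detected objects. Objects
#' classified as single (width below the cutoff) contribute 1 under every
#' model; agglomerates contribute their model count. With
#' `applyTo = "all"` the model formulas are applied to every object
#' (each still at least 1) regardless of the classification.
#'
#' @param widthsNm Lateral object widths (nm), one per object.
#' @param diameterNm Primary particle diameter (nm).
#' @param cutoffNm Single/agglomerate cutoff (nm).
#' @param applyTo Apply models to `"agglomerates"` only (singles count 1) or
#'   to `"all"` objects.
#' @return List of class `"agglomerateEstimate"`: `perObject` data frame
#'   (width, classification, n1d, n2d, n3d), `totals` named vector, counts
#'   of singles/agglomerates.
#' @examples
#' est <- totalParticles(c(85, 170, 255), 85)
#' est$totals
#' @export
totalParticles <- function(widthsNm, diameterNm,
                           cutoffNm = defaultWidthCutoffNm(diameterNm),
                           applyTo = c("agglomerates", "all")) {
  applyTo <- match.arg(applyTo)
  if (!length(widthsNm)) stop("no objects to estimate")
  cls <- classifySingle(widthsNm, diameterNm, cutoffNm)
  per <- data.frame(widthNm = widthsNm, class = cls)
  for (m in c("1d", "2d", "3d")) {
    n <- particlesInObject(widthsNm, diameterNm, m)
    if (applyTo == "agglomerates") n[cls == "single"] <- 1L
    per[[paste0("n", m)]] <- n
  }
  out <- list(perObject = per,
              totals = c(n1d = sum(per$n1d), n2d = sum(per$n2d),
                         n3d = sum(per$n3d)),
              nSingle = sum(cls == "single"),
              nAgglomerate = sum(cls == "agglomerate"),
              cutoffNm = cutoffNm, applyTo = applyTo)
  class(out) <- "agglomerateEstimate"
  out
}

#' @export
print.agglomerateEstimate <- function(x, ...) {
  cat(sprintf(
    "Agglomerate estimate: %d objects (%d single, %d agglomerate; cutoff %g nm)\n",
    nrow(x$perObject), x$nSingle, x$nAgglomerate, x$cutoffNm))
  cat(sprintf("  totals: %d (1D) / %d (2D) / %d (3D) particles\n",
              x$totals["n1d"], x$totals["n2d"], x$totals["n3d"]))
  invisible(x)
}
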