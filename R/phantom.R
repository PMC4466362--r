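# Cell phantom geometry and ground-truthed emitter placement.

# containment check: the nucleus surface, sampled over directions, must stay
# within the closed half-ellipsoid cell body (touching the membrane or the
# substrate is allowed; protruding is not).
.nucleusContained <- function(ph) {
  a <- ph@cellSemiAxesUm; n <- ph@nucleusSemiAxesUm; c0 <- ph@nucleusCenterUm
  th <- seq(0, pi, length.out = 25)
  phi <- seq(0, 2 * pi, length.out = 49)
  g <- expand.grid(th = th, phi = phi)
  u <- cbind(sin(g$th) * cos(g$phi), sin(g$th) * sin(g$phi), cos(g$th))
  p <- sweep(u %*% diag(n), 2, c0, "+")
  inCell <- (p[, 1] / a[1])^2 + (p[, 2] / a[2])^2 + (p[, 3] / a[3])^2 <=
    1 + 1e-9
  all(inCell) && all(p[, 3] >= -1e-9)
}

#' Build an adherent-cell phantom
#'
#' The phantom is the upper half of an ellipsoid resting on the substrate
#' plane z = 0 (an adherent lung epithelial cell), with an ellipsoidal
#' nucleus inside and a thin membrane shell over the whole plasma surface.
#' The default semi-axes (12, 10, 6.4) um give a cell volume of about
#' 1600 um^3, a typical average for these cells.
#'
#' @param cellSemiAxesUm Cell semi-axes `c(x, y, z)` in um.
#' @param nucleusSemiAxesUm Nucleus semi-axes `c(x, y, z)` in um.
#' @param nucleusCenterUm Nucleus centre `c(x, y, z)` in um; by default the
#'   nucleus sits centred above the substrate.
#' @param shellThicknessNm Membrane shell thickness in nm.
#' @return A [CellPhantom-class]. Construction is purely geometric and
#'   deterministic.
#' @examples
#' ph <- buildPhantom()
#' phantomVolumeUm3(ph)
#' @export
buildPhantom <- function(cellSemiAxesUm = c(12, 10, 6.4),
                         nucleusSemiAxesUm = c(5, 4, 2.5),
                         nucleusCenterUm = NULL,
                         shellThicknessNm = 40) {
  if (is.null(nucleusCenterUm))
    nucleusCenterUm <- c(0, 0, min(nucleusSemiAxesUm[3] + 0.5,
                                   cellSemiAxesUm[3] - nucleusSemiAxesUm[3]))
  new("CellPhantom", cellSemiAxesUm = cellSemiAxesUm,
      nucleusSemiAxesUm = nucleusSemiAxesUm,
      nucleusCenterUm = nucleusCenterUm,
      shellThicknessNm = shellThicknessNm)
}

#' Analytic phantom volume and footprint
#'
#' Volume of the half-ellipsoid cell body, `2/3 * pi * a * b * c`, and the
#' area of its substrate footprint, `pi * a * b`.
#'
#' @param phantom A [CellPhantom-class].
#' @return Volume in um^3 / area in um^2.
#' @export
phantomVolumeUm3 <- function(phantom) {
  a <- phantom@cellSemiAxesUm
  2 / 3 * pi * a[1] * a[2] * a[3]
}

#' @rdname phantomVolumeUm3
#' @export
phantomAreaUm2 <- function(phantom) {
  a <- phantom@cellSemiAxesUm
  pi * a[1] * a[2]
}

#' Point-in-phantom tests
#'
#' Vectorised analytic interior test. `positionsNm` is an n x 3 matrix of
#' (z, y, x) positions in nm. The same test is used to voxelise the phantom,
#' so ground-truth inside flags and voxelised masks are consistent by
#' construction: a point is interior iff it lies inside the half-ellipsoid.
#'
#' @param phantom A [CellPhantom-class].
#' @param positionsNm n x 3 matrix of (z, y, x) positions in nm.
#' @param marginNm Shrink the cell surface inward by this margin (nm).
#' @return Logical vector.
#' @export
insidePhantom <- function(phantom, positionsNm, marginNm = 0) {
  a <- phantom@cellSemiAxesUm * 1000
  s <- 1 - marginNm / min(a)          # uniform shrink is distance-conservative
  z <- positionsNm[, 1]; y <- positionsNm[, 2]; x <- positionsNm[, 3]
  (x / (a[1] * s))^2 + (y / (a[2] * s))^2 + (z / (a[3] * s))^2 <= 1 &
    z >= marginNm
}

# analytic nucleus interior test, same convention
.insideNucleus <- function(phantom, positionsNm) {
  n <- phantom@nucleusSemiAxesUm * 1000
  c0 <- phantom@nucleusCenterUm * 1000
  z <- positionsNm[, 1]; y <- positionsNm[, 2]; x <- positionsNm[, 3]
  ((x - c0[1]) / n[1])^2 + ((y - c0[2]) / n[2])^2 + ((z - c0[3]) / n[3])^2 <= 1
}

#' Stack geometry covering a phantom
#'
#' Field of view and voxel lattice for one channel: the lateral extent covers
#' the cell footprint plus a margin, the axial extent runs from below the
#' substrate to above the cell apex.
#'
#' @param phantom A [CellPhantom-class].
#' @param acq An [AcquisitionConfig-class].
#' @param marginNm Spatial margin on every side (nm).
#' @return List with `dim` (nz, ny, nx), `spacingNm`, `originNm`.
#' @export
stackGeometry <- function(phantom, acq, marginNm = 800) {
  a <- phantom@cellSemiAxesUm * 1000
  sp <- .acqSpacingNm(acq)
  ext <- c(a[3] + 2 * marginNm, 2 * a[2] + 2 * marginNm, 2 * a[1] + 2 * marginNm)
  d <- as.integer(ceiling(ext / sp))
  org <- c(-marginNm, -a[2] - marginNm, -a[1] - marginNm)
  list(dim = d, spacingNm = sp, originNm = org)
}

#' Voxelise the phantom interior
#'
#' A voxel belongs to the interior iff its centre passes the analytic
#' interior test.
#'
#' @inheritParams stackGeometry
#' @param geom A geometry list from [stackGeometry()].
#' @return 3D logical array.
#' @export
voxelizePhantom <- function(phantom, geom) {
  d <- geom$dim; sp <- geom$spacingNm; org <- geom$originNm
  z <- org[1] + (seq_len(d[1]) - 1) * sp[1]
  y <- org[2] + (seq_len(d[2]) - 1) * sp[2]
  x <- org[3] + (seq_len(d[3]) - 1) * sp[3]
  a <- phantom@cellSemiAxesUm * 1000
  qz <- (z / a[3])^2; qy <- (y / a[2])^2; qx <- (x / a[1])^2
  arr <- outer(outer(qz, qy, "+"), qx, "+") <= 1
  arr & (z >= 0)
  # recycling: z varies along dim 1
}

# uniform sample on the upper half surface of the ellipsoid with semi-axes
# a (um), exact rejection using the area element weight
.sampleShell <- function(n, aUm) {
  out <- matrix(numeric(0), 0, 3)
  a <- aUm
  wmax <- max(a[2] * a[3], a[1] * a[3], a[1] * a[2])
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 32)
    u <- matrix(rnorm(3 * m), m, 3)
    u <- u / sqrt(rowSums(u^2))
    u[, 3] <- abs(u[, 3])
    w <- sqrt((u[, 1] * a[2] * a[3])^2 + (u[, 2] * a[1] * a[3])^2 +
                (u[, 3] * a[1] * a[2])^2) / wmax
    keep <- runif(m) < w
    p <- cbind(a[1] * u[keep, 1], a[2] * u[keep, 2], a[3] * u[keep, 3])
    out <- rbind(out, p)
  }
  out[seq_len(n), , drop = FALSE]   # (x, y, z) um
}

#' Membrane and lamina label emitters
#'
#' Fluorophore positions emulating the membrane label (whole plasma surface:
#' ellipsoid cap plus basal face) and the nuclear-lamina label (nucleus
#' surface). Densities are per um^2 of surface.
#'
#' @param phantom A [CellPhantom-class].
#' @param densityPerUm2 Emitter surface density (um^-2).
#' @param brightness Expected photons per emitter.
#' @return Data frame with columns `zNm`, `yNm`, `xNm`, `brightness`.
#' @export
membraneEmitters <- function(phantom, densityPerUm2 = 150, brightness = 400) {
  a <- phantom@cellSemiAxesUm
  p <- 1.6075   # Thomsen approximation for the ellipsoid surface area
  capArea <- 4 * pi * (((a[1] * a[2])^p + (a[1] * a[3])^p +
                          (a[2] * a[3])^p) / 3)^(1 / p) / 2
  baseArea <- pi * a[1] * a[2]
  nCap <- max(1L, round(capArea * densityPerUm2))
  nBase <- max(1L, round(baseArea * densityPerUm2))
  cap <- .sampleShell(nCap, a)
  r <- sqrt(runif(nBase)); th <- runif(nBase, 0, 2 * pi)
  base <- cbind(a[1] * r * cos(th), a[2] * r * sin(th), 0)
  p3 <- rbind(cap, base) * 1000
  data.frame(zNm = p3[, 3], yNm = p3[, 2], xNm = p3[, 1],
             brightness = brightness)
}

#' @rdname membraneEmitters
#' @export
laminaEmitters <- function(phantom, densityPerUm2 = 150, brightness = 400) {
  nAx <- phantom@nucleusSemiAxesUm
  c0 <- phantom@nucleusCenterUm
  p <- 1.6075
  area <- 4 * pi * (((nAx[1] * nAx[2])^p + (nAx[1] * nAx[3])^p +
                       (nAx[2] * nAx[3])^p) / 3)^(1 / p)
  nEm <- max(1L, round(area * densityPerUm2))
  s <- .sampleShell(2 * nEm, nAx)              # upper half only
  s[, 3] <- s[, 3] * sample(c(-1, 1), nrow(s), replace = TRUE)
  s <- sweep(s[seq_len(nEm), , drop = FALSE], 2, c0, "+") * 1000
  data.frame(zNm = s[, 3], yNm = s[, 2], xNm = s[, 1], brightness = brightness)
}

#' Place nanoparticle emitters with known ground truth
#'
#' Samples `nInside` particle (cluster) positions in the cell interior, at
#' least one particle diameter away from the membrane surface, and
#' `nOutside` positions outside the cell: attached to the membrane outer
#' surface or resting on the substrate around the cell (half/half in
#' expectation, emulating sedimented particles that were not washed off).
#' Cluster members are placed in contact (centre spacing equal to the
#' particle diameter), growing a randomly oriented chain.
#'
#' @param phantom A [CellPhantom-class].
#' @param nInside,nOutside Number of emitters (clusters count each member).
#' @param clusterSizes Integer vector to draw cluster sizes from, or a single
#'   size. The default places single particles.
#' @param particle A [ParticleSpec-class]; sets the diameter and brightness
#'   scaling.
#' @param brightness Expected photons per particle. The default scales the
#'   85 nm brightness (2e4 photons) by the measured object-intensity ratio
#'   between the two sizes (~1.57) rather than the theoretical dye content,
#'   which overstates the difference.
#' @param minSeparationNm Optional anisotropic minimum spacing between
#'   clusters, `c(lateral, axial)` in nm: candidate positions closer than
#'   this exclusion ellipsoid to an accepted one are rejected.
#' @param substrateBandNm Outside emitters on the substrate are placed in a
#'   band of this width (nm) around the cell footprint (kept narrower than
#'   the rendered field-of-view margin).
#' @param seed RNG seed; a fixed seed reproduces the emitter set exactly.
#' @return Data frame (one row per emitter): `zNm`, `yNm`, `xNm`,
#'   `brightness`, `diameterNm`, `cluster`, `inside`.
#' @export
sampleParticles <- function(phantom, nInside, nOutside,
                            clusterSizes = 1,
                            particle = particleSpec(85),
                            brightness = NULL,
                            minSeparationNm = NULL,
                            substrateBandNm = 600,
                            seed = NULL) {
  if (nInside < 0 || nOutside < 0) stop("counts must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(brightness))
    brightness <- if (particle@diameterNm >= 50) 2e4 else 2e4 / 1.57
  d <- particle@diameterNm
  a <- phantom@cellSemiAxesUm * 1000
  shell <- phantom@shellThicknessNm
  empty <- data.frame(zNm = numeric(0), yNm = numeric(0), xNm = numeric(0),
                      brightness = numeric(0), diameterNm = numeric(0),
                      cluster = integer(0), inside = logical(0))
  if (nInside + nOutside == 0) return(empty)
  margin <- d + shell / 2
  if (margin >= min(a) && nInside > 0)
    stop("particle does not fit inside the phantom with the required clearance")

  sep2 <- function(p, q) {       # anisotropic squared separation (units of 1)
    dl <- sqrt((p[2] - q[, 2])^2 + (p[3] - q[, 3])^2) / minSeparationNm[1]
    da <- (p[1] - q[, 1]) / minSeparationNm[2]
    dl^2 + da^2
  }

  placeCluster <- function(anchor, size) {
    pos <- matrix(anchor, 1, 3)   # rows of (z, y, x)
    while (nrow(pos) < size) {
      for (try in seq_len(200)) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- pos[nrow(pos), ] + u * d
        ok <- all(sqrt(colSums((t(pos) - cand)^2)) >= 0.99 * d)
        if (ok) { pos <- rbind(pos, cand); break }
        if (try == 200) stop("could not grow cluster chain")
      }
    }
    pos
  }

  drawInside <- function() {
    for (try in seq_len(20000)) {
      cand <- c(runif(1, margin, a[3] - margin),
                runif(1, -a[2], a[2]), runif(1, -a[1], a[1]))
      if (insidePhantom(phantom, matrix(cand, 1, 3), marginNm = margin))
        return(cand)
    }
    stop("requested inside count infeasible for this phantom")
  }

  drawOutside <- function() {
    if (runif(1) < 0.5) {  # membrane-attached, resting on the outer surface
      s <- .sampleShell(1, phantom@cellSemiAxesUm) * 1000    # (x, y, z)
      u <- c(s[1] / a[1]^2, s[2] / a[2]^2, s[3] / a[3]^2)
      u <- u / sqrt(sum(u^2))                                # outward normal
      p <- c(s[1], s[2], s[3]) + u * (shell / 2 + d / 2)
      c(max(p[3], d / 2), p[2], p[1])
    } else {               # on the substrate, in a band around the footprint
      repeat {
        x <- runif(1, -a[1] - substrateBandNm, a[1] + substrateBandNm)
        y <- runif(1, -a[2] - substrateBandNm, a[2] + substrateBandNm)
        if ((x / (a[1] + d))^2 + (y / (a[2] + d))^2 > 1)
          return(c(d / 2, y, x))
      }
    }
  }

  drawSet <- function(nTotal, drawFn) {
    pos <- matrix(numeric(0), 0, 3)
    cl <- integer(0)
    cid <- 0L
    while (nrow(pos) < nTotal) {
      size <- if (length(clusterSizes) == 1) clusterSizes else
        sample(clusterSizes, 1)
      size <- min(size, nTotal - nrow(pos))
      for (try in seq_len(5000)) {
        anchor <- drawFn()
        if (!is.null(minSeparationNm) && nrow(pos) > 0 &&
            min(sep2(anchor, pos)) < 1) {
          if (try == 5000) stop("min-separation placement infeasible")
          next
        }
        break
      }
      cid <- cid + 1L
      pc <- placeCluster(anchor, size)
      pos <- rbind(pos, pc)
      cl <- c(cl, rep(cid, nrow(pc)))
    }
    list(pos = pos, cluster = cl)
  }

  res <- list(pos = matrix(numeric(0), 0, 3), cluster = integer(0))
  if (nInside > 0) res <- drawSet(nInside, drawInside)
  nIn <- nrow(res$pos)
  if (nOutside > 0) {
    out <- drawSet(nOutside, drawOutside)
    res$pos <- rbind(res$pos, out$pos)
    res$cluster <- c(res$cluster, out$cluster + max(0L, res$cluster, 0L))
  }
  em <- data.frame(zNm = res$pos[, 1], yNm = res$pos[, 2], xNm = res$pos[, 3],
                   brightness = brightness, diameterNm = d,
                   cluster = res$cluster,
                   inside = insidePhantom(phantom, res$pos))
  stopifnot(sum(em$inside) == nIn)   # placement must respect the geometry
  em
}

#' Ground-truth table with expected merged objects
#'
#' Augments an emitter set with the memberships an ideal detector would
#' report: emitters closer than `separationNm` (anisotropic: lateral and
#' axial criteria can differ) are expected to merge into one image object.
#' Components are computed by single-linkage over the separation graph.
#'
#' @param emitters Data frame from [sampleParticles()].
#' @param separationNm `c(lateral, axial)` merge criterion in nm.
#' @return The emitter data frame with an `expectedObject` column; the
#'   attribute `separationNm` records the criterion.
#' @export
groundTruthTable <- function(emitters, separationNm = c(152, 1200)) {
  n <- nrow(emitters)
  if (n == 0) {
    emitters$expectedObject <- integer(0)
    return(emitters)
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    dl <- sqrt((emitters$yNm[-seq_len(i)] - emitters$yNm[i])^2 +
                 (emitters$xNm[-seq_len(i)] - emitters$xNm[i])^2)
    da <- abs(emitters$zNm[-seq_len(i)] - emitters$zNm[i])
    js <- which((dl / separationNm[1])^2 + (da / separationNm[2])^2 < 1) + i
    for (j in js) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  emitters$expectedObject <- as.integer(factor(roots))
  attr(emitters, "separationNm") <- separationNm
  emitters
}
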