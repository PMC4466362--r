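# Rendering emitters into noisy detector stacks.

#' Render one channel of a synthetic stack
#'
#' The expected intensity at a voxel is the configured background plus the
#' emitter brightnesses spread by a separable 3D Gaussian PSF with the
#' acquisition's lateral/axial FWHMs, integrated over the voxel extent (a
#' fully contained emitter therefore deposits exactly its brightness).
#' Noise is applied in detector order: Poisson shot noise on the expected
#' counts, then additive Gaussian read noise, then hard clipping at the
#' detector maximum (the testable analogue of an avalanche photodiode
#' saturating on very bright agglomerates).
#'
#' @param emitters Data frame with columns `zNm`, `yNm`, `xNm`, `brightness`.
#' @param acq An [AcquisitionConfig-class].
#' @param geom Geometry list from [stackGeometry()] (fields `dim`,
#'   `spacingNm`, `originNm`). Must cover all emitters.
#' @param channel Channel role tag.
#' @param noise Apply the noise model; `FALSE` returns the expected
#'   (noise-free) intensities.
#' @param seed RNG seed; fixed seed and config give a bit-identical stack.
#' @return A [VoxelGrid-class].
#' @export
renderChannel <- function(emitters, acq, geom, channel = "np",
                          noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- as.integer(geom$dim)
  sp <- geom$spacingNm
  org <- geom$originNm
  if (nrow(emitters) > 0) {
    hi <- org + (d - 1) * sp
    inFov <- emitters$zNm >= org[1] & emitters$zNm <= hi[1] &
      emitters$yNm >= org[2] & emitters$yNm <= hi[2] &
      emitters$xNm >= org[3] & emitters$xNm <= hi[3]
    if (!all(inFov))
      stop("field of view does not cover all emitters")
  }
  expected <- array(acq@background, dim = d)
  if (nrow(emitters) > 0) {
    em <- as.matrix(emitters[, c("zNm", "yNm", "xNm", "brightness")])
    expected <- .splat_gaussians(expected, em, sp, org, .acqSigmaNm(acq), 5)
  }
  if (noise) {
    counts <- rpois(length(expected), expected)
    if (acq@readNoiseSd > 0)
      counts <- counts + rnorm(length(counts), 0, acq@readNoiseSd)
    counts <- pmin(pmax(counts, 0), acq@detectorMax)
    expected <- array(counts, dim = d)
  } else {
    expected <- array(pmin(expected, acq@detectorMax), dim = d)
  }
  new("VoxelGrid", data = expected, spacingNm = sp, originNm = org,
      channel = channel)
}

#' Simulate a full multi-channel acquisition
#'
#' Renders the three channels of the emulated experiment: the nanoparticle
#' channel at its own (typically STED) sampling, and the membrane and
#' nuclear-lamina channels at confocal sampling, over the same physical
#' field of view. Channels are rendered sequentially from one seed, so the
#' whole acquisition is reproducible.
#'
#' @param phantom A [CellPhantom-class].
#' @param particles Emitter data frame from [sampleParticles()].
#' @param acqNp Acquisition for the nanoparticle channel.
#' @param acqCell Acquisition for the cellular (membrane/lamina) channels.
#' @param membraneDensityPerUm2,laminaDensityPerUm2 Label surface densities.
#' @param marginNm Field-of-view margin (nm).
#' @param noise Apply the detector noise model.
#' @param seed RNG seed.
#' @return List with elements `np`, `membrane`, `lamina` ([VoxelGrid-class]),
#'   `groundTruth` (from [groundTruthTable()]), `phantom`, and the two
#'   geometries (`geomNp`, `geomCell`).
#' @export
simulateStack <- function(phantom, particles,
                          acqNp = stedAcquisition(),
                          acqCell = confocalAcquisition(),
                          membraneDensityPerUm2 = 150,
                          laminaDensityPerUm2 = 150,
                          marginNm = 800, noise = TRUE, seed = 1) {
  set.seed(seed)
  geomNp <- stackGeometry(phantom, acqNp, marginNm)
  geomCell <- stackGeometry(phantom, acqCell, marginNm)
  mem <- membraneEmitters(phantom, membraneDensityPerUm2)
  lam <- laminaEmitters(phantom, laminaDensityPerUm2)
  np <- renderChannel(particles, acqNp, geomNp, channel = "np", noise = noise)
  membrane <- renderChannel(mem, acqCell, geomCell, channel = "membrane",
                            noise = noise)
  lamina <- renderChannel(lam, acqCell, geomCell, channel = "lamina",
                          noise = noise)
  sepLat <- 2 * acqNp@psfFwhmLateralNm
  sepAx <- 2 * acqNp@psfFwhmAxialNm
  list(np = np, membrane = membrane, lamina = lamina,
       groundTruth = groundTruthTable(particles, c(sepLat, sepAx)),
       phantom = phantom, geomNp = geomNp, geomCell = geomCell,
       acqNp = acqNp, acqCell = acqCell)
}
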