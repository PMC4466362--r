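# Otsu thresholding and whole-cell mask extraction.

test_that("Otsu separates a bimodal image and rejects a constant one", {
  x <- array(c(rep(10, 500), rep(200, 500)), c(10, 10, 10))
  thr <- otsuThreshold(x)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  expect_error(otsuThreshold(array(7, c(5, 5, 5))), "constant")
})

test_that("Otsu equals the brute-force between-class-variance argmax", {
  # 8-level toy histogram
  set.seed(1)
  lv <- c(0, 3, 10, 14, 60, 66, 71, 90)
  cnt <- c(400, 350, 120, 90, 40, 70, 25, 5)
  x8 <- array(rep(lv, cnt), c(10, 11, 10))
  expect_equal(otsuThreshold(x8), otsuBruteForce(x8))
  # random mixtures
  for (s in 1:3) {
    set.seed(s)
    x <- array(c(rnorm(800, 20, 4), rnorm(200, 80, 12)), c(10, 10, 10))
    thr <- otsuThreshold(x)
    expect_equal(thr, otsuBruteForce(x))
    # identical partition as well
    expect_identical(x > thr, x > otsuBruteForce(x))
  }
})

test_that("segmenting a voxelised solid ball returns the ball unchanged", {
  d <- c(50, 50, 50)
  ai <- arrayInd(seq_len(prod(d)), d)
  r2 <- (ai[, 1] - 25)^2 + (ai[, 2] - 25)^2 + (ai[, 3] - 25)^2
  ball <- array(r2 <= 400, d)
  g <- vg(array(as.numeric(ball) * 100, d), spacingNm = c(100, 100, 100),
          channel = "membrane")
  m <- segmentCell(g)
  expect_identical(voxelData(m), ball)
})

test_that("a punctured hollow shell segments to the filled solid", {
  d <- c(50, 50, 50)
  ai <- arrayInd(seq_len(prod(d)), d)
  r2 <- (ai[, 1] - 25)^2 + (ai[, 2] - 25)^2 + (ai[, 3] - 25)^2
  shell <- array(r2 <= 400 & r2 > 289, d)      # thickness ~3 voxels
  shell[24:25, 24:25, 42:46] <- FALSE          # 2-voxel puncture through it
  g <- vg(array(as.numeric(shell) * 100, d), spacingNm = c(100, 100, 100),
          channel = "membrane")
  m <- segmentCell(g)
  filled <- array(r2 <= 400, d)
  # identical up to single surface-tip voxels left by the discrete puncture
  expect_lte(sum(xor(voxelData(m), filled)), 3)
  expect_true(voxelData(m)[25, 25, 25])   # cavity filled
  # monotonicity: the mask contains the thresholded membrane voxels
  expect_true(all(voxelData(m)[shell]))
})

test_that("a manual polygon selects only the enclosed component", {
  d <- c(20, 40, 80)
  ai <- arrayInd(seq_len(prod(d)), d)
  ballAt <- function(cx) (ai[, 1] - 10)^2 + (ai[, 2] - 20)^2 +
    (ai[, 3] - cx)^2 <= 64
  arr <- array(0, d)
  arr[ballAt(20)] <- 100    # component A around x voxel 20
  arr[ballAt(60)] <- 100    # component B around x voxel 60
  g <- vg(arr, spacingNm = c(100, 100, 100), channel = "membrane")
  polyA <- cbind(x = c(500, 3500, 3500, 500), y = c(500, 500, 3500, 3500))
  m <- segmentCell(g, polygon = polyA)
  expect_identical(voxelData(m), array(ballAt(20), d))
  expect_false(any(voxelData(m)[, , 50:70]))
  # equal-sized components: without the polygon the other one may win; a
  # polygon around nothing errs
  polyNone <- cbind(x = c(7600, 7900, 7900), y = c(100, 100, 400))
  expect_error(segmentCell(g, polygon = polyNone), "polygon")
})

test_that("segmentation of an empty channel errors with a diagnostic", {
  arr <- array(0, c(10, 10, 10)); arr[5, 5, 5] <- 10
  g <- vg(arr, channel = "membrane")
  # single voxel is destroyed by the opening -> empty mask
  expect_error(segmentCell(g), "empty mask")
})

test_that("mask volume on a rendered phantom is within 10% of ground truth", {
  ph <- testPhantom()
  set.seed(21)
  acq <- confocalAcquisition()
  geom <- stackGeometry(ph, acq)
  mem <- membraneEmitters(ph)              # SNR >> 10 at the default brightness
  g <- renderChannel(mem, acq, geom, channel = "membrane", noise = TRUE)
  m <- segmentCell(g, refinePsfFwhmNm = c(277, 600))
  expect_lt(abs(maskVolumeUm3(m) / phantomVolumeUm3(ph) - 1), 0.10)
  expect_lt(abs(maskAreaUm2(m) / phantomAreaUm2(ph) - 1), 0.10)
  # provenance records the pipeline
  expect_equal(provenance(m)$openCloseVoxels, 2)
  expect_true(!is.null(provenance(m)$boundaryErosionNm))
})

test_that("mask resampling carries geometry onto a finer lattice", {
  d <- c(10, 20, 20)
  arr <- array(FALSE, d); arr[3:7, 5:15, 5:15] <- TRUE
  mask <- new("CellMask", mask = arr, spacingNm = c(130, 60, 60),
              originNm = c(0, 0, 0), threshold = 1, provenance = list())
  target <- list(dim = c(10, 40, 40), spacingNm = c(130, 30, 30),
                 originNm = c(0, 0, 0))
  rs <- resampleMask(mask, target)
  expect_identical(dim(voxelData(rs)), as.integer(target$dim))
  # volume preserved by nearest-neighbour resampling up to half-voxel
  # quantisation at the boundary
  expect_equal(sum(voxelData(rs)) * prod(target$spacingNm),
               sum(arr) * prod(mask@spacingNm), tolerance = 0.12)
})
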