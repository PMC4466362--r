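# Nanoparticle object detection, filtering, measurement and counting.

test_that("a blank channel yields an empty object table", {
  g <- vg(array(5, c(10, 30, 30)))
  expect_identical(nrow(detectParticles(g)), 0L)
  # shot noise alone must not fabricate objects
  set.seed(31)
  gn <- vg(array(rpois(9000, 5), c(10, 30, 30)))
  expect_identical(nrow(detectParticles(gn)), 0L)
})

test_that("well-separated spots are resolved, overlapping spots merge", {
  geom <- spotGeom()
  far <- rbind(c(1300, 1200, 1200), c(1300, 1200, 1200 + 4 * 76),
               c(1300, 2400, 1200))
  g <- renderSpots(far, geom = geom)
  expect_identical(nrow(detectParticles(g)), 3L)

  near <- rbind(c(1300, 1800, 1800 - 19), c(1300, 1800, 1800 + 19))  # 0.5 FWHM
  g2 <- renderSpots(near, geom = geom)
  expect_identical(nrow(detectParticles(g2)), 1L)
})

test_that("the range-relative discard rule removes dim objects, keeps the
           brightest, and thresholds on the peak", {
  # narrow background around 100, a dim blob at 400 with enough mass to
  # anchor the Otsu threshold below it, and a bright blob peaking at the
  # image maximum
  ripple <- rep(c(-1, -0.5, 0, 0.5, 1), length.out = 9 * 40 * 40)
  arr <- array(100 + ripple, c(9, 40, 40))
  arr[3:7, 6:13, 6:13] <- 400            # dim blob (320 voxels)
  arr[4:6, 28:30, 28:30] <- 1000         # bright blob, peak = image max
  g <- vg(arr)

  lenient <- detectParticles(g, discardFraction = 0.05)
  thr <- attr(lenient, "threshold")
  expect_gt(thr, 101)                    # background excluded
  expect_lt(thr, 400)                    # dim blob is a real object
  expect_lt(thr + 0.05 * (1000 - thr), 400)   # above the 5% line -> kept
  expect_identical(nrow(lenient), 2L)
  expect_true(all(lenient$peak >= thr + 0.05 * (1000 - thr)))

  strict <- detectParticles(g, discardFraction = 0.5)
  expect_gt(thr + 0.5 * (1000 - thr), 400)    # below the 50% line -> dropped
  expect_identical(nrow(strict), 1L)
  expect_equal(strict$peak, 1000)

  # the globally brightest object survives any discard fraction
  harsh <- detectParticles(g, discardFraction = 0.99)
  expect_identical(nrow(harsh), 1L)
  expect_equal(harsh$peak, 1000)
})

test_that("lateral width measures one pixel for a single-voxel object", {
  arr <- array(0, c(9, 30, 30))
  arr[5, 15, 15] <- 100
  obj <- detectParticles(vg(arr), minVoxels = 1)
  expect_identical(nrow(obj), 1L)
  expect_equal(obj$widthNm, 30)
  expect_gte(obj$peak, obj$mean)
})

test_that("rendered widths separate single particles from linear clusters", {
  geom <- spotGeom()
  single <- renderSpots(matrix(c(1300, 1800, 1800), 1), geom = geom)
  w1 <- detectParticles(single)$widthNm
  expect_gte(w1, 76 * 0.9)
  expect_lt(w1, 150)

  chain <- rbind(c(1300, 1800, 1800 - 85), c(1300, 1800, 1800),
                 c(1300, 1800, 1800 + 85))
  g3 <- renderSpots(chain, geom = geom)
  obj3 <- detectParticles(g3)
  expect_identical(nrow(obj3), 1L)       # contact cluster merges
  expect_gt(obj3$widthNm, 150)
  expect_equal(measureLateralWidth(obj3[1, ], obj3, g3), obj3$widthNm)
})

test_that("inside classification is strict voxel containment", {
  arr <- array(0, c(9, 30, 30))
  arr[4:6, 10:12, 10:12] <- 500   # blob A
  arr[4:6, 20:22, 20:22] <- 500   # blob B
  g <- vg(arr)
  obj <- detectParticles(g)
  expect_identical(nrow(obj), 2L)

  mk <- array(FALSE, dim(arr))
  mk[3:7, 8:14, 8:14] <- TRUE                    # covers A fully
  mk[3:7, 19:21, 19:21] <- TRUE                  # clips one voxel layer of B
  mask <- new("CellMask", mask = mk, spacingNm = g@spacingNm,
              originNm = g@originNm, threshold = 0, provenance = list())
  out <- classifyInside(obj, mask, g)
  insideA <- out$inside[which.min(out$xNm)]
  insideB <- out$inside[which.max(out$xNm)]
  expect_true(insideA)
  expect_false(insideB)

  badMask <- new("CellMask", mask = mk, spacingNm = c(130, 60, 60),
                 originNm = g@originNm, threshold = 0, provenance = list())
  expect_error(classifyInside(obj, badMask, g), "geometry")
})

test_that("counting is invariant to positive intensity rescaling", {
  geom <- spotGeom()
  pos <- rbind(c(1300, 1200, 1200), c(1300, 1200, 2400), c(1300, 2400, 1800))
  g <- renderSpots(pos, geom = geom, noise = TRUE, seed = 8)
  scaled <- vg(voxelData(g) * 3.7, g@spacingNm, g@originNm)
  expect_identical(nrow(detectParticles(g)), nrow(detectParticles(scaled)))
})

test_that("recall degrades as emitter spacing shrinks below the PSF width", {
  geom <- list(dim = c(16, 150, 150), spacingNm = c(130, 30, 30),
               originNm = c(0, 0, 0))
  countPairs <- function(sepNm) {
    ys <- seq(600, 3600, length.out = 4)
    pos <- do.call(rbind, lapply(ys, function(y)
      rbind(c(910, y, 1800 - sepNm / 2), c(910, y, 1800 + sepNm / 2))))
    nrow(detectParticles(renderSpots(pos, geom = geom)))
  }
  counts <- vapply(c(4, 2, 1, 0.4) * 76, countPairs, numeric(1))
  expect_identical(counts[1], 8)         # full recall at 4x FWHM
  expect_true(all(diff(counts) <= 0))    # monotone degradation
  expect_identical(counts[4], 4)         # fully merged pairs
})

test_that("per-cell summary divides counts by the projected mask area", {
  mk <- array(TRUE, c(2, 10, 10))
  mask <- new("CellMask", mask = mk, spacingNm = c(1000, 1000, 1000),
              originNm = c(0, 0, 0), threshold = 0, provenance = list())
  expect_equal(maskAreaUm2(mask), 100)
  obj <- data.frame(label = 1:3, zNm = 0, yNm = 0, xNm = 0, voxels = 1,
                    peak = 10, mean = c(4, 6, 8), widthNm = 30,
                    zEdge = FALSE, inside = c(TRUE, TRUE, FALSE))
  s <- summarizeObjects(obj, mask)
  expect_identical(s$objectsPerCell, 2L)
  expect_equal(s$objectsPerAreaUm2, 0.02)
  expect_equal(s$objectsPerAreaUm2 * s$cellAreaUm2, s$objectsPerCell)
  expect_equal(s$meanIntensity, 5)
  s0 <- summarizeObjects(obj[0, ], mask)
  expect_identical(s0$objectsPerCell, 0L)
  expect_equal(s0$meanIntensity, 0)
})
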