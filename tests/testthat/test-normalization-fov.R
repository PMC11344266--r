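test_that("normalization scale is the shared 99.9th percentile", {
  st <- dwiStudy(array(7, dim = c(4, 4, 4, 2)),
                 gradientTable(c(0, 1300), cbind(0, c(1, 0, 0))))
  expect_equal(computeNormalization(st)$scale, 7)   # constant study
  # 0..999 each exactly once, against the sort-based oracle
  x <- array(sample(0:999), dim = c(10, 10, 10, 1))
  st2 <- dwiStudy(x, gradientTable(0, matrix(0, 3, 1)))
  expect_equal(computeNormalization(st2)$scale, oraclePercentile(c(x), 0.999))
  # two volumes with very different ranges share one scale
  y <- array(0, dim = c(6, 6, 6, 2))
  y[, , , 1] <- stats::runif(216, 0, 1)
  y[, , , 2] <- stats::runif(216, 0, 100)
  st3 <- dwiStudy(y, gradientTable(c(0, 1300), cbind(0, c(1, 0, 0))))
  p <- computeNormalization(st3)
  expect_equal(p$scale, oraclePercentile(c(y), 0.999))
  expect_gt(p$scale, 50)     # driven by the bright volume, not per-volume
})

test_that("normalization is invariant to volume ordering and degenerate on zeros", {
  set.seed(9)
  y <- array(stats::runif(4 * 4 * 4 * 3), dim = c(4, 4, 4, 3))
  gt <- gradientTable(c(0, 1300, 1300),
                      cbind(0, c(1, 0, 0), c(0, 1, 0)))
  a <- computeNormalization(dwiStudy(y, gt))
  b <- computeNormalization(dwiStudy(y[, , , c(3, 1, 2)], gt))
  expect_identical(a$scale, b$scale)
  expect_error(computeNormalization(array(0, c(3, 3, 3))), "degenerate")
})

test_that("applyNormalization clips to [0, 1] and inverts on the interior", {
  p <- list(scale = 5, floor = 0)
  expect_equal(applyNormalization(5, p), 1)
  expect_equal(applyNormalization(-3, p), 0)
  expect_equal(applyNormalization(10, p), 1)
  x <- array(stats::runif(64, 0, 5), dim = c(4, 4, 4))
  n <- applyNormalization(x, p)
  expect_true(all(n >= 0 & n <= 1))
  expect_equal(invertNormalization(n, p), x, tolerance = 1e-12)
})

test_that("brain masking recovers an ellipsoid and rejects constants", {
  shape <- c(24, 24, 24)
  truth <- ellipsoidMask(shape, c(8, 7, 9))
  bm <- computeBrainMask(truth, medianRadius = 1)
  # perfect contrast: mask equals support within a 2-voxel boundary band
  core <- ellipsoidMask(shape, c(6, 5, 7))
  grown <- ellipsoidMask(shape, c(10, 9, 11))
  expect_true(all(bm@mask[core == 1] == 1))
  expect_true(all(bm@mask[grown == 0] == 0))
  # mild noise: volume within 10% of truth
  set.seed(2)
  noisy <- truth + array(stats::rnorm(prod(shape), 0, 0.08), dim = shape)
  bm2 <- computeBrainMask(noisy)
  expect_lt(abs(sum(bm2@mask) - sum(truth)) / sum(truth), 0.10)
  expect_error(computeBrainMask(array(1, shape)), "constant")
})

test_that("simulated cutoffs zero exactly the brain-adjacent slices", {
  shape <- c(16, 16, 50)
  brain <- brainMask(ellipsoidMask(shape, c(6, 6, 16)))
  ext <- dwifov:::maskExtent(brain@mask, 3)
  st <- dwiStudy(array(1, dim = c(shape, 1)),
                 gradientTable(0, matrix(0, 3, 1)))
  sc <- simulateCutoff(st, brain, 5, "top")
  cutZ <- (ext[2] - 4):ext[2]          # 5 slices abutting the brain top
  zeroed <- which(apply(sc$fov@mask, 3, max) == 0)
  expect_equal(zeroed, cutZ)
  expect_true(all(sc$study@data[, , cutZ, ] == 0))
  expect_true(all(sc$study@data[, , -cutZ, ] == 1))
  # cut 0: identity
  sc0 <- simulateCutoff(st, brain, 0, "top")
  expect_identical(sc0$study@data, st@data)
  expect_true(all(sc0$fov@mask == 1))
  # idempotence
  sc2 <- simulateCutoff(sc$study, brain, 5, "top")
  expect_identical(sc2$study@data, sc$study@data)
  expect_error(simulateCutoff(st, brain, 45, "top"), "exceeds")
})

test_that("random cutoffs always match round(cut/voxel) at the brain edge", {
  shape <- c(12, 12, 48)
  brain <- brainMask(ellipsoidMask(shape, c(5, 5, 15)))
  ext <- dwifov:::maskExtent(brain@mask, 3)
  st <- dwiStudy(array(stats::runif(prod(shape) * 2), dim = c(shape, 2)),
                 gradientTable(c(0, 1300), cbind(0, c(0, 0, 1))))
  set.seed(33)
  for (trial in 1:100) {
    cut <- stats::runif(1, 0, 14)
    side <- sample(c("top", "bottom"), 1)
    sc <- simulateCutoff(st, brain, cut, side)
    k <- sign(cut) * floor(abs(cut) + 0.5)   # half away from zero
    zeroed <- which(apply(sc$fov@mask, 3, max) == 0)
    expect_equal(length(zeroed), k)
    if (k > 0) {
      if (side == "top") expect_equal(max(zeroed), ext[2])
      else expect_equal(min(zeroed), ext[1])
      expect_equal(zeroed, seq(min(zeroed), max(zeroed)))
    }
  }
})

test_that("recombination preserves acquired voxels exactly", {
  set.seed(5)
  shape <- c(8, 8, 8)
  acq <- array(stats::runif(512), dim = shape)
  imp <- array(stats::runif(512), dim = shape)
  ones <- fovMask(array(1, shape), "none", 0)
  m <- array(1, shape); m[, , 6:8] <- 0
  fm <- fovMask(m, "top", 3)
  expect_identical(recombine(acq, imp, ones), acq)
  allMiss <- fovMask(array(0, shape), "top", 8)
  expect_identical(recombine(acq, imp, allMiss), imp)
  out <- recombine(acq, imp, fm)
  # element-by-element reference loop
  for (i in seq_along(out))
    expect_identical(out[i], if (m[i] == 1) acq[i] else imp[i])
  expect_error(recombine(acq, imp[1:4, , ], fm), "shape")
})

test_that("FOV masks are derived from zero-slice runs at the brain edge", {
  shape <- c(12, 12, 40)
  brain <- brainMask(ellipsoidMask(shape, c(5, 5, 14)))
  ext <- dwifov:::maskExtent(brain@mask, 3)
  data <- array(stats::runif(prod(shape)), dim = c(shape, 1))
  data[, , (ext[2] - 3):ext[2], ] <- 0
  st <- dwiStudy(data, gradientTable(0, matrix(0, 3, 1)))
  fov <- deriveFOVMask(st, brain)
  expect_equal(fov@cutSide, "top")
  expect_equal(which(apply(fov@mask, 3, min) == 0), (ext[2] - 3):ext[2])
})
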