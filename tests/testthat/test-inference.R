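test_that("view prediction is pure plumbing around the generator", {
  set.seed(41)
  shape <- c(12, 12, 12)
  vol <- array(stats::runif(prod(shape)), shape)
  t1 <- array(stats::runif(prod(shape)), shape)
  # identity oracle generator on a full-FOV volume: output equals input
  for (view in c("sagittal", "coronal")) {
    out <- predictVolumeView(identityGenerator(1), vol, t1, view, 1)
    expect_identical(out, vol)
  }
  # constant generator: constant volume, every slice assembled
  outC <- predictVolumeView(function(s) matrix(0.3, 12, 12), vol, t1,
                            "coronal", 1)
  expect_equal(outC, array(0.3, shape))
  # trained-generator view routing is enforced
  gen <- newGenerator(6, filters = 4, sliceShape = c(12, 12))
  gen$view <- "sagittal"
  expect_error(predictVolumeView(gen, vol, t1, "coronal", 1), "view")
})

test_that("view merging is the voxel-wise mean", {
  set.seed(42)
  a <- array(stats::runif(4 * 4 * 4), c(4, 4, 4))
  expect_identical(mergeViews(a, a), a)
  expect_equal(mergeViews(a * 0, 2 * a), a)
  b <- array(stats::runif(4 * 4 * 4), c(4, 4, 4))
  m <- mergeViews(a, b)
  for (i in seq_along(m)) expect_equal(m[i], (a[i] + b[i]) / 2,
                                       tolerance = 1e-7)
  expect_error(mergeViews(a, array(0, c(3, 3, 3))), "shape")
})

# bundle of plain-function generators for plumbing tests
functionBundle <- function(value = 0.5, gridShape = c(20, 20, 20),
                           counter = NULL) {
  mk <- function(key) {
    function(stack) {
      if (!is.null(counter)) counter[[key]] <- counter[[key]] + 1L
      matrix(value, dim(stack)[1], dim(stack)[2])
    }
  }
  gens <- setNames(lapply(dwifov:::bundleKeys, mk), dwifov:::bundleKeys)
  modelBundle(gens, meta = list(n = 1, gridShape = gridShape,
                                voxelSize = c(1, 1, 1), lambda = 100))
}

phantomForInference <- function(seed = 71, nDir = 2) {
  generatePhantom(phantomSpec(shape = c(20, 20, 20), nDir = nDir,
                              sigma = 0.01, seed = seed))
}

test_that("imputing a complete-FOV study changes nothing", {
  ph <- phantomForInference()
  out <- imputeStudy(functionBundle(), ph$dwi, ph$t1, brain = ph$brain)
  expect_identical(out@data, ph$dwi@data)
  expect_identical(out@gradients, ph$dwi@gradients)
})

test_that("imputation fills exactly the missing brain region and preserves the rest", {
  ph <- phantomForInference()
  sc <- simulateCutoff(ph$dwi, ph$brain, 4, "top")
  bundle <- functionBundle(value = 0.5)
  out <- imputeStudy(bundle, sc$study, ph$t1, fov = sc$fov,
                     brain = ph$brain)
  m <- sc$fov@mask
  for (v in seq_len(nVolumes(out))) {
    diffV <- out@data[, , , v] != sc$study@data[, , , v]
    # acquired voxels bit-identical
    expect_true(all(!diffV[m == 1]))
    # changed voxels are exactly the missing-region brain voxels
    expect_identical(unname(diffV), unname((m == 0) & (ph$brain@mask == 1)))
  }
  expect_identical(out@gradients, sc$study@gradients)
  # deterministic
  out2 <- imputeStudy(bundle, sc$study, ph$t1, fov = sc$fov,
                      brain = ph$brain)
  expect_identical(out@data, out2@data)
})

test_that("volumes are routed to their shell group's generators only", {
  counter <- new.env()
  for (k in dwifov:::bundleKeys) counter[[k]] <- 0L
  ph <- phantomForInference()
  # b0-only study
  b0 <- dwiStudy(ph$dwi@data[, , , 1, drop = FALSE],
                 gradientTable(0, matrix(0, 3, 1)))
  sc <- simulateCutoff(b0, ph$brain, 4, "top")
  out <- imputeStudy(functionBundle(counter = counter), sc$study, ph$t1,
                     fov = sc$fov, brain = ph$brain)
  expect_gt(counter$b0.sagittal, 0)
  expect_gt(counter$b0.coronal, 0)
  expect_equal(counter$bweighted.sagittal, 0)
  expect_equal(counter$bweighted.coronal, 0)
})

test_that("the FOV mask is derived from the data when not supplied", {
  ph <- phantomForInference(seed = 73)
  sc <- simulateCutoff(ph$dwi, ph$brain, 3, "top")
  out <- imputeStudy(functionBundle(), sc$study, ph$t1, brain = ph$brain)
  m <- sc$fov@mask
  changed <- out@data[, , , 1] != sc$study@data[, , , 1]
  expect_true(all(!changed[m == 1]))
  expect_true(any(changed[m == 0]))
})
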