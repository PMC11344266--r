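# a hand-built dwifovCase with constant intensity inside the brain
constantCase <- function(shape = c(16, 16, 16), value = 0.7) {
  bmArr <- ellipsoidMask(shape, shape * 0.35)
  dwi <- array(0, dim = c(shape, 1))
  dwi[, , , 1] <- bmArr * value
  structure(list(dwi = dwi, t1 = bmArr * 0.5, brain = brainMask(bmArr),
                 groups = list(b0 = 1L, bweighted = integer(0)),
                 bvals = 0, bvecs = matrix(0, 3, 1),
                 voxelSize = c(1, 1, 1),
                 normDWI = list(scale = 1, floor = 0),
                 normT1 = list(scale = 1, floor = 0)),
            class = "dwifovCase")
}

test_that("checkpoint selection is the argmin of validation error", {
  # injected sequence of fake checkpoint scores
  scores <- c(0.9, 0.4, 0.7, 0.4, 0.8)
  expect_equal(selectBestCheckpoint(scores), 2)   # earliest tie wins
  expect_equal(selectBestCheckpoint(c(3, 2, 1)), 3)
  expect_equal(selectBestCheckpoint(1.5), 1)
  expect_error(selectBestCheckpoint(c(1, NA)), "finite")
  expect_error(selectBestCheckpoint(numeric(0)), "finite")
})

test_that("validation score is the masked imputed-region error", {
  cs <- constantCase()
  # generator that reproduces the constant brain intensity: score 0
  perfect <- function(stack) matrix(0.7, 16, 16)
  expect_equal(validationScore(perfect, list(cs), cutMM = 3,
                               shellGroup = "b0", view = "sagittal", n = 1),
               0, tolerance = 1e-12)
  # zero-output generator: score equals masked mean of squared truth
  zero <- function(stack) matrix(0, 16, 16)
  expect_equal(validationScore(zero, list(cs), cutMM = 3,
                               shellGroup = "b0", view = "sagittal", n = 1),
               0.49, tolerance = 1e-12)
  # invariant to validation-study ordering
  cs2 <- constantCase(value = 0.4)
  a <- validationScore(zero, list(cs, cs2), cutMM = 3,
                       shellGroup = "b0", view = "sagittal", n = 1)
  b <- validationScore(zero, list(cs2, cs), cutMM = 3,
                       shellGroup = "b0", view = "sagittal", n = 1)
  expect_identical(a, b)
  expect_equal(a, mean(c(0.49, 0.16)), tolerance = 1e-12)
  expect_error(validationScore(zero, list(cs), cutMM = 0,
                               shellGroup = "b0", view = "sagittal", n = 1),
               "empty missing region")
})

test_that("training reduces the generator L1 loss on small phantoms", {
  sp <- phantomSpec(shape = c(32, 32, 32), nDir = 2, seed = 31)
  mk <- function(seed) {
    s2 <- sp; s2$seed <- seed
    ph <- generatePhantom(s2)
    prepareCase(ph$dwi, ph$t1)
  }
  train <- lapply(1:3, function(i) mk(400 + i))
  val <- list(mk(410))
  cfg <- trainConfig(n = 1, steps = 120, batchSize = 4, filters = 4,
                     lr = 1e-3, cutoffRangeMM = c(0, 8), valEvery = 60,
                     seed = 77)
  res <- trainGenerator(train, val, "b0", "sagittal", cfg)
  tr <- res$state$traces$gL1
  # moving-average convergence trend, not a value
  expect_lt(mean(tr[101:120]), mean(tr[1:20]))
  expect_true(all(is.finite(as.matrix(res$state$traces))))
  # best checkpoint corresponds to the recorded minimum validation score
  v <- res$state$validation
  expect_equal(res$state$bestScore, min(v$score))
  expect_equal(res$state$bestStep, v$step[which.min(v$score)])
  # the returned generator reproduces the best validation score
  expect_equal(validationScore(res$generator, val, res$state$valCutMM,
                               shellGroup = "b0", view = "sagittal", n = 1),
               res$state$bestScore, tolerance = 1e-12)
})

test_that("training is reproducible and supports degenerate augmentation", {
  sp <- phantomSpec(shape = c(24, 24, 24), nDir = 1, seed = 55)
  ph <- generatePhantom(sp)
  cs <- prepareCase(ph$dwi, ph$t1)
  cfg <- trainConfig(n = 1, steps = 20, batchSize = 2, filters = 4,
                     cutoffRangeMM = c(0, 0), valEvery = 10, seed = 5,
                     valCutMM = 4)
  # cutoff range [0,0]: pure self-reconstruction training still completes
  res1 <- trainGenerator(list(cs), list(cs), "b0", "sagittal", cfg)
  res2 <- trainGenerator(list(cs), list(cs), "b0", "sagittal", cfg)
  expect_identical(res1$state$traces, res2$state$traces)
  expect_identical(res1$state$validation, res2$state$validation)
})

test_that("bundles save and load with an intact manifest", {
  td <- withr::local_tempdir()
  set.seed(61)
  gens <- setNames(lapply(1:4, function(i)
    newGenerator(6, filters = 4, sliceShape = c(8, 8))),
    c("b0.sagittal", "b0.coronal", "bweighted.sagittal",
      "bweighted.coronal"))
  b <- modelBundle(gens, meta = list(n = 1, lambda = 100, seed = 3,
                                     gridShape = c(8, 8, 8),
                                     voxelSize = c(1, 1, 1)))
  saveModelBundle(b, file.path(td, "m"))
  b2 <- loadModelBundle(file.path(td, "m"))
  expect_equal(b2@meta$n, 1)
  expect_equal(sort(names(b2@generators)), sort(names(b@generators)))
  s <- array(stats::runif(8 * 8 * 6), c(8, 8, 6))
  expect_identical(forwardGenerate(b2@generators$b0.sagittal, s),
                   forwardGenerate(b@generators$b0.sagittal, s))
  # incomplete bundles are rejected
  expect_error(modelBundle(gens[1:3]), "named exactly")
  file.remove(file.path(td, "m", "b0.coronal.rds"))
  expect_error(loadModelBundle(file.path(td, "m")), "missing generator")
})

test_that("YAML configs round-trip and reject unknown keys", {
  td <- withr::local_tempdir()
  writeLines(c("n: 2", "steps: 50", "lambda: 10"), file.path(td, "c.yml"))
  cfg <- trainConfigFromYAML(file.path(td, "c.yml"))
  expect_equal(cfg$n, 2)
  expect_equal(cfg$steps, 50)
  expect_equal(cfg$lambda, 10)
  writeLines("bogus: 1", file.path(td, "bad.yml"))
  expect_error(trainConfigFromYAML(file.path(td, "bad.yml")), "unknown")
})
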