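test_that("masked MSE/PSNR match loop oracles and analytic values", {
  set.seed(21)
  for (trial in 1:5) {
    shape <- c(6, 7, 5)
    ref <- array(stats::runif(prod(shape)), shape)
    tst <- array(stats::runif(prod(shape)), shape)
    msk <- array(stats::rbinom(prod(shape), 1, 0.6), shape)
    if (sum(msk) == 0) msk[1] <- 1
    expect_equal(maskedMSE(ref, tst, msk), oracleMaskedMSE(ref, tst, msk),
                 tolerance = 1e-10)
    # permuting voxel order inside the mask leaves MSE unchanged
    perm <- sample(which(msk == 1))
    ref2 <- ref; tst2 <- tst
    ref2[which(msk == 1)] <- ref[perm]
    tst2[which(msk == 1)] <- tst[perm]
    expect_equal(maskedMSE(ref2, tst2, msk), maskedMSE(ref, tst, msk),
                 tolerance = 1e-12)
  }
  ones <- array(1, c(4, 4, 4))
  expect_equal(maskedPSNR(ones, ones - 0.1, ones), 20)
  expect_equal(maskedPSNR(ones, ones - sqrt(0.001), ones), 30)
  expect_equal(maskedPSNR(ones, ones, ones), Inf)
  expect_error(maskedMSE(ones, ones, ones * 0), "empty")
})

test_that("3-D SSIM agrees with a naive sliding-window oracle", {
  set.seed(22)
  shape <- c(9, 8, 10)
  ref <- array(stats::runif(prod(shape)), shape)
  tst <- ref + array(stats::rnorm(prod(shape), 0, 0.1), shape)
  expect_equal(ssim3D(ref, tst, window = 3),
               oracleSSIM(ref, tst, 3), tolerance = 1e-6)
  msk <- array(stats::rbinom(prod(shape), 1, 0.5), shape)
  msk[5, 4, 5] <- 1
  expect_equal(ssim3D(ref, tst, mask = msk, window = 3),
               oracleSSIM(ref, tst, 3, mask = msk), tolerance = 1e-6)
  # window-7 path against the oracle on a larger fixture
  shape7 <- c(12, 12, 12)
  r7 <- array(stats::runif(prod(shape7)), shape7)
  t7 <- r7 + array(stats::rnorm(prod(shape7), 0, 0.2), shape7)
  expect_equal(ssim3D(r7, t7), oracleSSIM(r7, t7, 7), tolerance = 1e-6)
  expect_equal(ssim3D(ref, ref), 1)
  # anti-correlated structured pair has negative SSIM
  x <- array(rep(c(-1, 1), length.out = prod(shape7)) * 0.4 + 0.5, shape7)
  y <- 1 - x
  expect_lt(ssim3D(x, y), 0)
  expect_error(ssim3D(ref, tst, window = 4), "odd")
  expect_error(ssim3D(array(0, c(4, 4, 4)), array(0, c(4, 4, 4))), "window")
})

test_that("distance stratification assigns slice distances and orders error growth", {
  shape <- c(10, 10, 30)
  brain <- brainMask(ellipsoidMask(shape, c(4, 4, 12)))
  ext <- dwifov:::maskExtent(brain@mask, 3)
  m <- array(1, shape)
  zs <- (ext[2] - 4):ext[2]
  m[, , zs] <- 0
  fov <- fovMask(m, "top", 5)
  set.seed(23)
  ref <- array(stats::runif(prod(shape), 0.4, 0.9), shape)
  # identical volumes: +Inf PSNR, SSIM 1 everywhere
  tab0 <- distanceStratifiedMetrics(ref, ref, fov, brain, window = 3)
  expect_equal(tab0$distanceMM, 1:5)
  expect_equal(tab0$nSlices, rep(1L, 5))
  expect_true(all(tab0$psnr == Inf))
  expect_true(all(abs(tab0$ssim - 1) < 1e-12))
  # error growing linearly with distance: PSNR strictly decreasing
  tst <- ref
  for (i in seq_along(zs))
    tst[, , zs[i]] <- ref[, , zs[i]] + 0.03 * i
  tab <- distanceStratifiedMetrics(ref, tst, fov, brain, window = 3)
  expect_true(all(diff(tab$psnr) < 0))
  expect_error(distanceStratifiedMetrics(ref, ref,
                                         fovMask(array(1, shape), "none", 0),
                                         brain), "missing")
})

test_that("ADC maps are analytic on constant ratios and match the tensor phantom", {
  # S/S0 = exp(-1.3) at b = 1300 -> ADC = 1e-3 mm^2/s
  shape <- c(5, 5, 5)
  d <- array(0, dim = c(shape, 2))
  d[, , , 1] <- 1
  d[, , , 2] <- exp(-1.3)
  st <- dwiStudy(d, gradientTable(c(0, 1300), cbind(0, c(1, 0, 0))))
  a <- adcMap(st, 1)
  expect_equal(a, array(1e-3, shape), tolerance = 1e-12)
  # S = S0 -> ADC 0
  d[, , , 2] <- 1
  expect_equal(adcMap(dwiStudy(d, st@gradients), 1), array(0, shape),
               tolerance = 1e-15)
  # noiseless tensor phantom: ADC equals g' D g to 1e-8
  ph <- noiselessPhantom()
  sel <- ph$brain@mask == 1
  for (dir in 1:3) {
    gv <- bVectors(ph$dwi)[, 1 + dir]
    a <- adcMap(ph$dwi, dir)
    q <- oracleTensorADC(ph$tensors, gv)
    expect_lt(max(abs(a[sel] - q[sel])), 1e-8)
  }
  expect_error(adcMap(dwiStudy(d[, , , 2, drop = FALSE],
                               gradientTable(1300, c(1, 0, 0))), 1), "b0")
})

test_that("direction-bias test matches a rank-based oracle and handles degeneracy", {
  expect_equal(directionBiasTest(list(c(1, 2, 3), c(1, 2, 3))),
               list(H = 0, p = 1, df = 1L))
  r <- directionBiasTest(list(c(1, 2, 3), c(100, 101, 102)))
  expect_lt(r$p, 0.05)
  set.seed(24)
  for (trial in 1:10) {
    groups <- lapply(1:4, function(i) stats::rnorm(sample(3:8, 1)))
    got <- directionBiasTest(groups)
    expect_equal(got$H, oracleKruskalH(groups), tolerance = 1e-9)
  }
  expect_error(directionBiasTest(list(1:3)), "at least 2")
})

test_that("method comparison reports compose the three metrics", {
  set.seed(25)
  shape <- c(12, 12, 16)
  brain <- brainMask(ellipsoidMask(shape, c(5, 5, 6)))
  ext <- dwifov:::maskExtent(brain@mask, 3)
  m <- array(1, shape); m[, , (ext[2] - 2):ext[2]] <- 0
  fov <- fovMask(m, "top", 3)
  gt <- gradientTable(c(0, 1300), cbind(0, c(0, 0, 1)))
  mkStudy <- function(noise) {
    d <- array(stats::runif(prod(shape) * 2, 0.3, 1), dim = c(shape, 2))
    dwiStudy(d + noise * array(stats::rnorm(prod(shape) * 2, 0, 0.1),
                               dim = c(shape, 2)), gt)
  }
  ref <- mkStudy(0)
  refs <- list(a = ref)
  addNoise <- function(sd) dwiStudy(ref@data +
    array(stats::rnorm(prod(shape) * 2, 0, sd), dim = c(shape, 2)), gt)
  outs <- list(
    copyReference = list(a = ref),
    noisy = list(a = addNoise(0.1)),
    noisier = list(a = addNoise(0.3)))
  rep <- compareMethods(refs, outs, list(a = fov), list(a = brain),
                        window = 3)
  copyRow <- rep[rep$method == "copyReference" & rep$shellGroup == "b0", ]
  expect_equal(copyRow$psnrMean, Inf)
  expect_equal(copyRow$ssimMean, 1)
  # noisier method has strictly lower PSNR than the less noisy one
  pn <- function(m) mean(rep[rep$method == m, "psnrMean"])
  expect_lt(pn("noisier"), pn("noisy"))
  # single method, single study row equals the metric ops directly
  params <- computeNormalization(ref)
  region <- (fov@mask == 0) & (brain@mask == 1)
  v <- applyNormalization(ref@data[, , , 1], params)
  t <- applyNormalization(outs$noisy$a@data[, , , 1], params)
  row <- rep[rep$method == "noisy" & rep$shellGroup == "b0", ]
  expect_equal(row$mseMean, maskedMSE(v, t, region), tolerance = 1e-12)
  expect_error(compareMethods(refs, list(x = list(b = ref)),
                              list(a = fov), list(a = brain)), "keys")
})
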