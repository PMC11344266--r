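test_that("adversarial objective matches analytic values and a mean-of-logs oracle", {
  expect_equal(adversarialLoss(0.5, 0.5), 2 * log(0.5), tolerance = 1e-12)
  eps <- 1e-3
  expect_equal(adversarialLoss(1 - eps, eps), 2 * log(1 - eps),
               tolerance = 1e-12)
  set.seed(13)
  for (trial in 1:10) {
    dR <- array(stats::runif(60, 0.01, 0.99), c(5, 4, 3))
    dF <- array(stats::runif(60, 0.01, 0.99), c(5, 4, 3))
    # element-wise mean-of-logs oracle
    oracle <- sum(log(c(dR))) / 60 + sum(log(1 - c(dF))) / 60
    expect_equal(adversarialLoss(dR, dF), oracle, tolerance = 1e-6)
  }
  expect_error(adversarialLoss(0.5, NaN), "non-finite")
  expect_error(adversarialLoss(1.2, 0.5), "0, 1")
})

test_that("L1 loss is the mean absolute difference", {
  x <- matrix(stats::runif(64), 8)
  expect_equal(l1Loss(x, x), 0)
  expect_equal(l1Loss(matrix(1, 8, 8), matrix(0, 8, 8)), 1)
  set.seed(14)
  for (trial in 1:10) {
    a <- matrix(stats::rnorm(48), 6)
    b <- matrix(stats::rnorm(48), 6)
    tot <- 0
    for (i in seq_along(a)) tot <- tot + abs(a[i] - b[i])
    expect_equal(l1Loss(a, b), tot / 48, tolerance = 1e-7)
  }
  expect_error(l1Loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("combined objective arithmetic and negative-lambda guard", {
  expect_equal(totalGeneratorObjective(-0.5, 0.3, 0), -0.5)
  expect_equal(totalGeneratorObjective(-0.7, 0.02, 100), 1.3)
  expect_error(totalGeneratorObjective(0, 0, -1), "non-negative")
})

test_that("combined objective gradient matches finite differences on a toy generator", {
  # 1-parameter toy generator: a single 1x1 linear convolution, theta * x.
  # Residuals are kept away from the |.| kink so the finite difference is
  # valid.
  set.seed(15)
  H <- 6; W <- 6; N <- 2
  x <- array(stats::runif(H * W * N, 0.2, 0.8), c(H, W, 1, N))
  target <- array(1, c(H, W, 1, N))        # generated < target everywhere
  disc <- newDiscriminator(2, filters = 4)
  toy <- function(theta) {
    lay <- dwifov:::newConvLayer(1, 1, k = 1, pad = 0, act = "linear")
    lay$W[1, 1] <- theta
    lay$b <- 0
    structure(list(layers = list(lay), inChannels = 1, filters = 1),
              class = "dwifovGenerator")
  }
  lambda <- 100
  objective <- function(theta) {
    gen <- toy(theta)
    fwd <- dwifov:::generatorForwardBatch(gen, x, keepCache = TRUE)
    # identical loss path as training, evaluated at this theta
    dwifov:::genLossGrads(gen, disc, x, target, lambda, gf = fwd)$value
  }
  theta0 <- 0.3
  gl <- dwifov:::genLossGrads(toy(theta0), disc, x, target, lambda)
  analytic <- gl$grads[[1]]$dW[1, 1]
  eps <- 1e-5
  fd <- (objective(theta0 + eps) - objective(theta0 - eps)) / (2 * eps)
  expect_equal(analytic, fd, tolerance = 1e-5)
})

test_that("stable logit-space losses equal the probability-space formulas", {
  set.seed(16)
  z <- array(stats::rnorm(40, 0, 3), c(5, 4, 1, 2))
  dProb <- 1 / (1 + exp(-z))
  # discriminator-side value as computed in training
  cond <- array(stats::runif(5 * 4 * 2 * 2), c(5, 4, 2, 2))
  real <- array(stats::runif(5 * 4 * 1 * 2), c(5, 4, 1, 2))
  disc <- newDiscriminator(3, filters = 4)
  fake <- real * 0.5
  dl <- dwifov:::discLossGrads(disc, cond, real, fake)
  fR <- dwifov:::discForwardBatch(disc, dwifov:::abind4(cond, real))$out
  fF <- dwifov:::discForwardBatch(disc, dwifov:::abind4(cond, fake))$out
  expect_equal(dl$value,
               adversarialLoss(1 / (1 + exp(-fR)), 1 / (1 + exp(-fF))),
               tolerance = 1e-6)
})

test_that("generators are deterministic with bounded output range", {
  set.seed(17)
  gen <- newGenerator(6, filters = 4, sliceShape = c(12, 12))
  stack <- array(stats::runif(12 * 12 * 6), c(12, 12, 6))
  out1 <- forwardGenerate(gen, stack)
  out2 <- forwardGenerate(gen, stack)
  expect_identical(out1, out2)
  expect_equal(dim(out1), c(12, 12))
  for (trial in 1:20) {
    s <- array(stats::runif(12 * 12 * 6, 0, 1), c(12, 12, 6))
    o <- forwardGenerate(gen, s)
    expect_true(all(o >= 0 & o <= 1))   # codomain of the output activation
  }
  expect_error(forwardGenerate(gen, array(0, c(12, 12, 4))), "channels")
})

test_that("zero-weight output head maps any input to the activation of zero", {
  gen <- newGenerator(2, filters = 4, sliceShape = c(8, 8))
  last <- length(gen$layers)
  gen$layers[[last]]$W[] <- 0
  gen$layers[[last]]$b[] <- 0
  out <- forwardGenerate(gen, array(stats::runif(8 * 8 * 2), c(8, 8, 2)))
  expect_equal(out, matrix((tanh(0) + 1) / 2, 8, 8))
})
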