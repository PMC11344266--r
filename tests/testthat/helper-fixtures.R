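# Small fixtures built in code at test time.

# ellipsoid mask centred in a cubic grid
ellipsoidMask <- function(shape, semi) {
  ctr <- (shape + 1) / 2
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  rho <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2
  array(as.numeric(rho <= 1), dim = shape)
}

# quick random study: V volumes of given shape with 1 b0 + (V-1) weighted
randomStudy <- function(shape = c(12, 12, 12), V = 3, seed = 1) {
  set.seed(seed)
  bvals <- c(0, rep(1300, V - 1))
  bv <- matrix(stats::rnorm(3 * V), 3)
  bv[, 1] <- 0
  for (v in 2:V) bv[, v] <- bv[, v] / sqrt(sum(bv[, v]^2))
  dwiStudy(array(stats::runif(prod(shape) * V), dim = c(shape, V)),
           gradientTable(bvals, bv))
}

# the tiny noiseless phantom used by several closure tests
noiselessPhantom <- function(shape = c(24, 24, 24), nDir = 3, seed = 11) {
  generatePhantom(phantomSpec(shape = shape, nDir = nDir, sigma = 0,
                              sigmaT1 = 0, seed = seed))
}

# "oracle generator": returns the central DWI input channel
identityGenerator <- function(n) {
  force(n)
  function(stack) stack[, , n + 1]
}
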