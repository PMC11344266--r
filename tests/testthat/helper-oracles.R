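# Independent, naively coded oracles. These deliberately use direct loops /
# closed forms and share no code with the implementation paths they check.

# type-7 percentile by explicit sorting and linear interpolation
oraclePercentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# brute-force trilinear interpolation at one 0-based coordinate
oracleTrilinear <- function(vol, x, y, z) {
  d <- dim(vol)
  val <- 0
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- x0 + dx; iy <- y0 + dy; iz <- z0 + dz
    w <- (if (dx) x - x0 else 1 - (x - x0)) *
      (if (dy) y - y0 else 1 - (y - y0)) *
      (if (dz) z - z0 else 1 - (z - z0))
    v <- if (ix >= 0 && ix < d[1] && iy >= 0 && iy < d[2] &&
             iz >= 0 && iz < d[3]) vol[ix + 1, iy + 1, iz + 1] else 0
    val <- val + w * v
  }
  val
}

# voxel-loop masked MSE
oracleMaskedMSE <- function(ref, test, mask) {
  tot <- 0; n <- 0
  for (i in seq_along(ref)) {
    if (mask[i] > 0) { tot <- tot + (ref[i] - test[i])^2; n <- n + 1 }
  }
  tot / n
}

# naive sliding-window SSIM with uniform cubic window (population variance)
oracleSSIM <- function(ref, test, window, dataRange = 1, mask = NULL) {
  r <- (window - 1) / 2
  d <- dim(ref)
  C1 <- (0.01 * dataRange)^2; C2 <- (0.03 * dataRange)^2
  vals <- c()
  for (i in (r + 1):(d[1] - r)) for (j in (r + 1):(d[2] - r))
    for (k in (r + 1):(d[3] - r)) {
      if (!is.null(mask) && mask[i, j, k] == 0) next
      a <- ref[(i - r):(i + r), (j - r):(j + r), (k - r):(k + r)]
      b <- test[(i - r):(i + r), (j - r):(j + r), (k - r):(k + r)]
      ma <- mean(a); mb <- mean(b)
      va <- mean(a^2) - ma^2; vb <- mean(b^2) - mb^2
      cab <- mean(a * b) - ma * mb
      vals <- c(vals, ((2 * ma * mb + C1) * (2 * cab + C2)) /
                  ((ma^2 + mb^2 + C1) * (va + vb + C2)))
    }
  mean(vals)
}

# rank-based Kruskal-Wallis H with tie correction, from first principles
oracleKruskalH <- function(groups) {
  vals <- unlist(groups)
  n <- length(vals)
  rk <- rank(vals)
  i0 <- 0
  H <- 0
  for (g in groups) {
    ri <- rk[(i0 + 1):(i0 + length(g))]
    H <- H + sum(ri)^2 / length(g)
    i0 <- i0 + length(g)
  }
  H <- 12 / (n * (n + 1)) * H - 3 * (n + 1)
  ties <- table(vals)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# quadratic form g' D g from the 6-component tensor field layout
oracleTensorADC <- function(tensors, gvec) {
  gvec[1]^2 * tensors[, , , 1] + gvec[2]^2 * tensors[, , , 2] +
    gvec[3]^2 * tensors[, , , 3] +
    2 * (gvec[1] * gvec[2] * tensors[, , , 4] +
           gvec[1] * gvec[3] * tensors[, , , 5] +
           gvec[2] * gvec[3] * tensors[, , , 6])
}
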