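# Convolutional network engine for the slice generators and patch
# discriminator: im2col/col2im patch kernels in C++ (src/conv.cpp), matrix
# products through BLAS, exact analytic backprop, Adam updates. At
# desk-scale slice sizes (<= 128^2) this trains the four tiny generators in
# minutes on one CPU without external deep-learning runtimes.
#
# Tensor layout: activations are [H, W, C, N] arrays; weights of a k x k
# convolution are (k*k*Cin) x Cout matrices whose rows follow the im2col
# column order (di fastest, then dj, then channel).

convForward <- function(x, layer) {
  d <- dim(x)
  col <- cpp_im2col(x, d[1], d[2], d[3], d[4],
                    layer$k, layer$stride, layer$pad)
  Ho <- (d[1] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
  Wo <- (d[2] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
  outM <- col %*% layer$W
  for (cc in seq_len(layer$cout))        # cheap bias add, cout is small
    outM[, cc] <- outM[, cc] + layer$b[cc]
  y <- array(outM, dim = c(Ho, Wo, d[4], layer$cout))
  y <- aperm(y, c(1, 2, 4, 3))
  list(z = y, cache = list(col = col, inDim = d, Ho = Ho, Wo = Wo))
}

convBackward <- function(dZ, layer, cache, computeDX = TRUE) {
  d <- cache$inDim
  N <- d[4]
  dOutM <- matrix(aperm(dZ, c(1, 2, 4, 3)), cache$Ho * cache$Wo * N,
                  layer$cout)
  dW <- crossprod(cache$col, dOutM)
  db <- colSums(dOutM)
  dX <- NULL
  if (computeDX) {
    dCol <- tcrossprod(dOutM, layer$W)
    dX <- cpp_col2im(dCol, d[1], d[2], d[3], d[4],
                     layer$k, layer$stride, layer$pad)
  }
  list(dX = dX, dW = dW, db = db)
}

actForward <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         lrelu = pmax(z, 0) + 0.2 * pmin(z, 0),
         tanh = tanh(z),
         linear = z)
}

actBackward <- function(dA, z, a, act) {
  switch(act,
         relu = dA * (z > 0),
         lrelu = dA * (0.2 + 0.8 * (z > 0)),
         tanh = dA * (1 - a^2),
         linear = dA)
}

up2Forward <- function(x) {
  d <- dim(x)
  ri <- rep(seq_len(d[1]), each = 2)
  rj <- rep(seq_len(d[2]), each = 2)
  x[ri, rj, , , drop = FALSE]
}

up2Backward <- function(dY) {
  d <- dim(dY)
  odd1 <- seq(1, d[1], by = 2); odd2 <- seq(1, d[2], by = 2)
  dY[odd1, odd2, , , drop = FALSE] +
    dY[odd1 + 1, odd2, , , drop = FALSE] +
    dY[odd1, odd2 + 1, , , drop = FALSE] +
    dY[odd1 + 1, odd2 + 1, , , drop = FALSE]
}

newConvLayer <- function(cin, cout, k = 3, stride = 1, pad = 1,
                         act = "relu", initScale = 1) {
  fan <- k * k * cin
  list(type = "conv", k = k, stride = stride, pad = pad, cin = cin,
       cout = cout, act = act,
       W = matrix(stats::rnorm(fan * cout, 0,
                               initScale * sqrt(2 / fan)), fan, cout),
       b = numeric(cout))
}

newResLayer <- function(c) {
  conv1 <- newConvLayer(c, c, act = "relu")
  conv2 <- newConvLayer(c, c, act = "linear")
  list(type = "res", c = c, conv1 = conv1, conv2 = conv2)
}

layerForward <- function(layer, x) {
  switch(layer$type,
    conv = {
      cf <- convForward(x, layer)
      a <- actForward(cf$z, layer$act)
      list(out = a, cache = list(conv = cf$cache, z = cf$z, a = a))
    },
    skipchain = {
      nf <- netForward(layer$layers, x, keepCache = TRUE)
      list(out = nf$out + x, cache = nf$caches)
    },
    res = {
      c1 <- convForward(x, layer$conv1)
      a1 <- actForward(c1$z, "relu")
      c2 <- convForward(a1, layer$conv2)
      list(out = c2$z + x,
           cache = list(c1 = c1$cache, z1 = c1$z, c2 = c2$cache))
    },
    up2 = list(out = up2Forward(x), cache = NULL)
  )
}

layerBackward <- function(layer, dOut, cache, needDX = TRUE) {
  switch(layer$type,
    conv = {
      dZ <- actBackward(dOut, cache$z, cache$a, layer$act)
      cb <- convBackward(dZ, layer, cache$conv, computeDX = needDX)
      list(dX = cb$dX, grads = list(dW = cb$dW, db = cb$db))
    },
    skipchain = {
      nb <- netBackward(layer$layers, cache, dOut, needInputGrad = TRUE)
      list(dX = nb$dX + dOut, grads = nb$grads)
    },
    res = {
      cb2 <- convBackward(dOut, layer$conv2, cache$c2)
      dA1 <- actBackward(cb2$dX, cache$z1, NULL, "relu")
      cb1 <- convBackward(dA1, layer$conv1, cache$c1, computeDX = needDX)
      list(dX = if (needDX) cb1$dX + dOut else NULL,
           grads = list(dW1 = cb1$dW, db1 = cb1$db,
                        dW2 = cb2$dW, db2 = cb2$db))
    },
    up2 = list(dX = up2Backward(dOut), grads = NULL)
  )
}

netForward <- function(layers, x, keepCache = FALSE) {
  caches <- if (keepCache) vector("list", length(layers)) else NULL
  for (l in seq_along(layers)) {
    lf <- layerForward(layers[[l]], x)
    x <- lf$out
    if (keepCache) caches[[l]] <- lf$cache
  }
  list(out = x, caches = caches)
}

netBackward <- function(layers, caches, dOut, needInputGrad = TRUE) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    lb <- layerBackward(layers[[l]], dOut, caches[[l]],
                        needDX = l > 1 || needInputGrad)
    dOut <- lb$dX
    grads[l] <- list(lb$grads)   # keep NULL slots (parameter-free layers)
  }
  list(dX = dOut, grads = grads)
}

# ---- Adam -------------------------------------------------------------

adamInit <- function(layers) {
  lapply(layers, function(l) {
    switch(l$type,
      conv = list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0),
      skipchain = adamInit(l$layers),
      res = list(mW1 = l$conv1$W * 0, vW1 = l$conv1$W * 0,
                 mb1 = l$conv1$b * 0, vb1 = l$conv1$b * 0,
                 mW2 = l$conv2$W * 0, vW2 = l$conv2$W * 0,
                 mb2 = l$conv2$b * 0, vb2 = l$conv2$b * 0),
      NULL)
  })
}

adamStepParam <- function(p, g, m, v, lr, b1, b2, t, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

adamUpdate <- function(layers, grads, state, lr, b1, b2, t) {
  for (l in seq_along(layers)) {
    g <- grads[[l]]
    if (is.null(g)) next
    lay <- layers[[l]]
    s <- state[[l]]
    if (lay$type == "skipchain") {
      u <- adamUpdate(lay$layers, g, s, lr, b1, b2, t)
      lay$layers <- u$layers
      s <- u$state
    } else if (lay$type == "conv") {
      u <- adamStepParam(lay$W, g$dW, s$mW, s$vW, lr, b1, b2, t)
      lay$W <- u$p; s$mW <- u$m; s$vW <- u$v
      u <- adamStepParam(lay$b, g$db, s$mb, s$vb, lr, b1, b2, t)
      lay$b <- u$p; s$mb <- u$m; s$vb <- u$v
    } else if (lay$type == "res") {
      u <- adamStepParam(lay$conv1$W, g$dW1, s$mW1, s$vW1, lr, b1, b2, t)
      lay$conv1$W <- u$p; s$mW1 <- u$m; s$vW1 <- u$v
      u <- adamStepParam(lay$conv1$b, g$db1, s$mb1, s$vb1, lr, b1, b2, t)
      lay$conv1$b <- u$p; s$mb1 <- u$m; s$vb1 <- u$v
      u <- adamStepParam(lay$conv2$W, g$dW2, s$mW2, s$vW2, lr, b1, b2, t)
      lay$conv2$W <- u$p; s$mW2 <- u$m; s$vW2 <- u$v
      u <- adamStepParam(lay$conv2$b, g$db2, s$mb2, s$vb2, lr, b1, b2, t)
      lay$conv2$b <- u$p; s$mb2 <- u$m; s$vb2 <- u$v
    }
    layers[[l]] <- lay
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

# ---- model builders ---------------------------------------------------

#' Create an untrained slice generator
#'
#' A residual encoder-decoder: stride-1 convolution, a stride-2
#' downsampling stage with residual blocks at the bottleneck and
#' nearest-neighbour upsampling, wrapped in a long skip connection so
#' full-resolution features bypass the bottleneck, then a tanh output
#' head. The tanh output lives in [-1, 1]; the generator maps
#' normalized [0, 1] intensities to that range on entry and back on exit.
#' The residual depth follows the slice size: 9 residual blocks at >= 128^2
#' slices (the full-scale configuration), 1 below that (desk scale).
#'
#' @param inChannels input channel count, 2*(2n+1).
#' @param filters base filter count.
#' @param sliceShape length-2 spatial shape the generator will see; both
#'   extents must be even (one stride-2 stage).
#' @param nResBlocks residual block count; default picked from sliceShape.
#' @return an object of class \code{dwifovGenerator}.
#' @export
newGenerator <- function(inChannels, filters = 16, sliceShape = c(48, 48),
                         nResBlocks = NULL) {
  if (any(sliceShape %% 2 != 0))
    stop("slice extents must be even for the down/upsampling stage")
  if (is.null(nResBlocks))
    nResBlocks <- if (min(sliceShape) >= 128) 9L else 1L
  F1 <- filters
  inner <- c(
    list(newConvLayer(F1, 2 * F1, stride = 2, act = "relu")),
    lapply(seq_len(nResBlocks), function(i) newResLayer(2 * F1)),
    list(list(type = "up2")),
    list(newConvLayer(2 * F1, F1, act = "linear"))
  )
  layers <- list(
    newConvLayer(inChannels, F1, act = "relu"),
    # long skip over the down/up path: full-resolution features bypass the
    # bottleneck, so fine detail near the acquired boundary survives
    list(type = "skipchain", layers = inner),
    newConvLayer(F1, F1, act = "relu"),
    newConvLayer(F1, 1, act = "tanh", initScale = 0.2)
  )
  structure(list(layers = layers, inChannels = inChannels,
                 filters = filters, nResBlocks = nResBlocks,
                 sliceShape = sliceShape),
            class = "dwifovGenerator")
}

#' Create an untrained patch discriminator
#'
#' A small strided convolutional classifier over the conditioning stack
#' concatenated with a candidate slice; its output is a spatial map of
#' real/fake logits, one per receptive-field patch.
#'
#' @param inChannels conditioning channels + 1 (candidate slice).
#' @param filters base filter count.
#' @return an object of class \code{dwifovDiscriminator}.
#' @export
newDiscriminator <- function(inChannels, filters = 16) {
  layers <- list(
    newConvLayer(inChannels, filters, stride = 2, act = "lrelu"),
    newConvLayer(filters, 2 * filters, stride = 2, act = "lrelu"),
    newConvLayer(2 * filters, 1, act = "linear")
  )
  structure(list(layers = layers, inChannels = inChannels,
                 filters = filters),
            class = "dwifovDiscriminator")
}

# Generator forward on a batch: x01 [H,W,C,N] in [0,1] -> [H,W,1,N] in [0,1].
generatorForwardBatch <- function(gen, x01, keepCache = FALSE) {
  nf <- netForward(gen$layers, 2 * x01 - 1, keepCache = keepCache)
  list(out01 = (nf$out + 1) / 2, tanhOut = nf$out, caches = nf$caches)
}

# Discriminator forward: inputs already in [-1, 1]; returns logits map.
discForwardBatch <- function(disc, xm1, keepCache = FALSE) {
  netForward(disc$layers, xm1, keepCache = keepCache)
}

sigmoid <- function(z) 1 / (1 + exp(-z))
softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))
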