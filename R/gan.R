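#' Adversarial (minimax) objective value
#'
#' The conditional adversarial value E[log D(y)] + E[log(1 - D(G(x)))], with
#' both expectations taken as the per-pixel mean over the discriminator's
#' patch score maps. The discriminator ascends this quantity and the
#' generator descends its second term; the training loop implements both in
#' a numerically stable logit form whose value agrees with this
#' probability-space formula.
#'
#' @param dReal,dFake discriminator probability maps in (0, 1) for real and
#'   generated slices (any shape).
#' @return scalar objective value.
#' @examples
#' adversarialLoss(0.5, 0.5)   # 2 * log(0.5)
#' @export
adversarialLoss <- function(dReal, dFake) {
  if (!all(is.finite(dReal)) || !all(is.finite(dFake)))
    stop("non-finite discriminator scores")
  if (any(dReal <= 0) || any(dReal >= 1) || any(dFake <= 0) || any(dFake >= 1))
    stop("discriminator scores must lie in (0, 1)")
  mean(log(dReal)) + mean(log(1 - dFake))
}

#' L1 reconstruction loss
#'
#' Mean absolute voxel difference between the ground-truth slice and the
#' generated slice.
#'
#' @param target,generated arrays of one shape.
#' @return scalar mean absolute difference.
#' @export
l1Loss <- function(target, generated) {
  if (!all(dim(target) == dim(generated)) ||
      length(target) != length(generated))
    stop("target and generated slices must share one shape")
  mean(abs(target - generated))
}

#' Combined generator objective
#'
#' The generator minimizes its adversarial term plus lambda times the L1
#' reconstruction term.
#'
#' @param advTerm adversarial term (the part of the minimax value the
#'   generator can influence).
#' @param l1Term L1 reconstruction term.
#' @param lambda non-negative L1 weight (default 100 throughout the package).
#' @return scalar \code{advTerm + lambda * l1Term}.
#' @export
totalGeneratorObjective <- function(advTerm, l1Term, lambda) {
  if (lambda < 0) stop("lambda must be non-negative")
  advTerm + lambda * l1Term
}

#' Run a generator on one input stack
#'
#' Deterministic forward pass: no sampled latent enters the generator, so two
#' calls with identical weights and inputs are bit-identical. For plumbing
#' tests and baselines, \code{generator} may also be a plain R function
#' mapping the H x W x C stack to an H x W matrix.
#'
#' @param generator a \code{dwifovGenerator} (see [newGenerator()]) or a
#'   function.
#' @param inputStack H x W x C array in normalized [0, 1] intensities, with
#'   C equal to the generator's input channel count.
#' @return H x W matrix in [0, 1].
#' @export
forwardGenerate <- function(generator, inputStack) {
  if (is.function(generator)) return(generator(inputStack))
  if (!inherits(generator, "dwifovGenerator"))
    stop("generator must be a dwifovGenerator or a function")
  d <- dim(inputStack)
  if (length(d) != 3)
    stop("inputStack must be H x W x C")
  if (d[3] != generator$inChannels)
    stop("input has ", d[3], " channels but the generator expects ",
         generator$inChannels)
  x <- array(inputStack, dim = c(d, 1))
  out <- generatorForwardBatch(generator, x)$out01
  matrix(out, d[1], d[2])
}

# ---- training-step gradients (internal) -------------------------------
#
# All losses are computed in logit space for stability; their values equal
# the probability-space formulas of adversarialLoss() exactly:
#   log D = -softplus(-z),  log(1 - D) = -softplus(z).

# Discriminator step loss and gradients. cond, real, fake are [-1,1] scaled;
# returns value of the minimax objective (to maximize) and parameter grads
# of the loss the discriminator minimizes (its negation).
discLossGrads <- function(disc, cond, real, fake) {
  N <- dim(cond)[4]
  # real and fake pairs run as one 2N batch through the discriminator
  x2 <- array(0, dim = c(dim(cond)[1:2], dim(cond)[3] + 1, 2 * N))
  x2[, , , seq_len(N)] <- abind4(cond, real)
  x2[, , , N + seq_len(N)] <- abind4(cond, fake)
  f2 <- discForwardBatch(disc, x2, keepCache = TRUE)
  zR <- f2$out[, , , seq_len(N), drop = FALSE]
  zF <- f2$out[, , , N + seq_len(N), drop = FALSE]
  M <- length(zR)
  value <- -mean(softplus(-zR)) - mean(softplus(zF))  # E log D + E log(1-D)
  # D minimizes -value
  dz <- f2$out * 0
  dz[, , , seq_len(N)] <- -(1 - sigmoid(zR)) / M
  dz[, , , N + seq_len(N)] <- sigmoid(zF) / M
  g2 <- netBackward(disc$layers, f2$caches, dz, needInputGrad = FALSE)
  list(value = value, grads = g2$grads)
}

# Generator step: builds fake = G(stack), evaluates adv term
# mean(log(1 - D(fake))) plus lambda * L1(target, fake) on the [0,1] scale,
# and returns gradients for the generator parameters. A cached forward pass
# `gf` may be supplied when the generator has not changed since it was run.
genLossGrads <- function(gen, disc, stack01, target01, lambda, gf = NULL) {
  d <- dim(stack01)
  if (is.null(gf))
    gf <- generatorForwardBatch(gen, stack01, keepCache = TRUE)
  fake01 <- gf$out01
  cond <- 2 * stack01 - 1
  xF <- abind4(cond, gf$tanhOut)
  fF <- discForwardBatch(disc, xF, keepCache = TRUE)
  zF <- fF$out
  M <- length(zF)
  advTerm <- -mean(softplus(zF))            # E log(1 - D(G))
  l1Term <- mean(abs(target01 - fake01))
  value <- totalGeneratorObjective(advTerm, l1Term, lambda)
  dzF <- -sigmoid(zF) / M                   # d advTerm / dz
  db <- netBackward(disc$layers, fF$caches, dzF)
  nc <- dim(cond)[3]
  dFakeTanh <- db$dX[, , nc + 1, , drop = FALSE]
  # L1 on [0,1] scale; fake01 = (tanh + 1)/2 so d fake01/d tanh = 1/2
  dL1 <- sign(fake01 - target01) / length(fake01)
  dFakeTanh <- dFakeTanh + lambda * dL1 * 0.5
  gb <- netBackward(gen$layers, gf$caches, dFakeTanh,
                    needInputGrad = FALSE)
  list(value = value, advTerm = advTerm, l1Term = l1Term, grads = gb$grads)
}

# concatenate two [H,W,C,N] arrays along the channel axis
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}
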