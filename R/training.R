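#' Training configuration
#'
#' Defaults follow the package-wide conventions: L1 weight lambda = 100,
#' Adam with momentum parameters (0.5, 0.999) and a desk-scale learning
#' rate of 1.5e-3 held constant for the first half of training then decayed
#' linearly, batch size 8 at desk scale (24 at the full 256^3 scale), cutoff
#' augmentation uniform on \code{cutoffRangeMM} with the cut side drawn
#' top/bottom with equal probability, and validation-based model selection
#' at a fixed cutoff (30 mm at full scale, scaled proportionally to the
#' grid's z extent).
#'
#' @param n neighbourhood half-width (full-scale default 7; desk scale 1).
#' @param lambda L1 weight in the generator objective.
#' @param batchSize slices per mini-batch.
#' @param steps optimization steps (one D and one G update each).
#' @param cutoffRangeMM range the training cutoff is drawn from, mm.
#' @param maxCutMM largest admissible cutoff, mm.
#' @param lr,beta1,beta2 Adam hyper-parameters (desk-scale default lr 1.5e-3).
#' @param lrSchedule "linear-half" holds lr constant for the first half of
#'   training, then decays it linearly toward zero; "constant" disables the
#'   decay.
#' @param filters base filter count of generator and discriminator.
#' @param valEvery validation cadence in steps.
#' @param valCutMM fixed validation cutoff (mm); NULL = 30 mm scaled by
#'   gridZmm / 256.
#' @param ablateStructural zero the structural channels (T1w-ablation
#'   baseline). Channel count is kept so checkpoints stay shape-compatible.
#' @param seed RNG seed for the whole run.
#' @return list of class \code{dwifovTrainConfig}.
#' @export
trainConfig <- function(n = 1, lambda = 100, batchSize = 8, steps = 500,
                        cutoffRangeMM = c(0, 50), maxCutMM = 50,
                        lr = 1.5e-3, lrSchedule = c("linear-half", "constant"),
                        beta1 = 0.5, beta2 = 0.999,
                        filters = 8, valEvery = 100, valCutMM = NULL,
                        ablateStructural = FALSE, seed = 1) {
  lrSchedule <- match.arg(lrSchedule)
  if (batchSize < 1) stop("batchSize must be >= 1")
  if (cutoffRangeMM[1] < 0 || cutoffRangeMM[2] > maxCutMM)
    stop("cutoffRangeMM must lie within [0, maxCutMM]")
  structure(list(n = n, lambda = lambda, batchSize = batchSize,
                 steps = steps, cutoffRangeMM = cutoffRangeMM,
                 maxCutMM = maxCutMM, lr = lr, lrSchedule = lrSchedule,
                 beta1 = beta1, beta2 = beta2,
                 filters = filters, valEvery = valEvery, valCutMM = valCutMM,
                 ablateStructural = ablateStructural, seed = seed),
            class = "dwifovTrainConfig")
}

#' Read a training configuration from YAML
#'
#' Keys mirror the arguments of [trainConfig()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return list of class \code{dwifovTrainConfig}.
#' @export
trainConfigFromYAML <- function(path) {
  vals <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n` key as boolean FALSE; restore it
  names(vals)[names(vals) == "FALSE"] <- "n"
  known <- names(formals(trainConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(trainConfig, vals)
}

#' Prepare one study for training or inference
#'
#' Resamples the DWI and structural image onto the normalized grid (shared
#' grid frame anchored on the DWI), computes the shared intensity
#' normalization for the DWI study and a separate one for the structural
#' image, applies both, and derives a brain mask from the mean b0 if none is
#' given.
#'
#' @param study a [DWIStudy-class].
#' @param structural a [StructuralImage-class].
#' @param grid a [NormalizedGrid-class]; NULL keeps the study's native grid
#'   (it must already be isotropic).
#' @param brain optional [BrainMask-class] on the output grid.
#' @return list of class \code{dwifovCase} with elements \code{dwi}
#'   (normalized 4-D array), \code{t1} (normalized 3-D array), \code{brain},
#'   \code{groups}, \code{bvals}, \code{bvecs}, \code{voxelSize},
#'   \code{normDWI}, \code{normT1}, \code{gridAff}.
#' @export
prepareCase <- function(study, structural, grid = NULL, brain = NULL) {
  if (!is.null(grid) &&
      (!all(dim(study@data)[1:3] == grid@shape) ||
       any(abs(study@voxelSize - grid@voxelSize) > 1e-6))) {
    ga <- gridAffine(grid, dim(study@data)[1:3], study@affine)
    V <- nVolumes(study)
    newData <- array(0, dim = c(grid@shape, V))
    for (v in seq_len(V))
      newData[, , , v] <- resampleToGrid(study@data[, , , v], study@affine,
                                         grid, ga)
    t1 <- resampleToGrid(structural@data, structural@affine, grid, ga)
    vox <- rep(grid@voxelSize, 3)
  } else {
    ga <- study@affine
    newData <- study@data
    t1 <- structural@data
    vox <- study@voxelSize
    if (!all(dim(t1) == dim(newData)[1:3]))
      stop("structural image must share the study grid when grid = NULL")
  }
  normDWI <- computeNormalization(newData)
  normT1 <- computeNormalization(t1)
  dwiN <- applyNormalization(newData, normDWI)
  t1N <- applyNormalization(t1, normT1)
  groups <- volumeGroups(study)
  if (is.null(brain)) {
    if (!length(groups$b0)) stop("cannot derive a brain mask without b0")
    meanB0 <- apply(dwiN[, , , groups$b0, drop = FALSE], 1:3, mean)
    brain <- computeBrainMask(meanB0)
  }
  structure(list(dwi = dwiN, t1 = t1N, brain = brain, groups = groups,
                 bvals = bValues(study), bvecs = bVectors(study),
                 voxelSize = vox, normDWI = normDWI, normT1 = normT1,
                 gridAff = ga),
            class = "dwifovCase")
}

# mini-batch of 2.5D stacks from a truncated volume + structural
buildBatch <- function(trunc, t1, axis, idxs, n, ablate = FALSE) {
  d <- dim(trunc)
  sliceDim <- d[-axis]
  nc <- 2L * (2L * n + 1L)
  N <- length(idxs)
  stack <- array(0, dim = c(sliceDim, nc, N))
  offs <- (-n):n
  for (b in seq_len(N)) {
    for (j in seq_along(offs)) {
      i <- idxs[b] + offs[j]
      stack[, , j, b] <- getSliceZero(trunc, axis, i)
      if (!ablate)
        stack[, , j + 2 * n + 1, b] <- getSliceZero(t1, axis, i)
    }
  }
  stack
}

buildTargets <- function(truth, axis, idxs) {
  d <- dim(truth)
  sliceDim <- d[-axis]
  tgt <- array(0, dim = c(sliceDim, 1, length(idxs)))
  for (b in seq_along(idxs))
    tgt[, , 1, b] <- getSliceZero(truth, axis, idxs[b])
  tgt
}

defaultValCut <- function(gridZmm) 30 * gridZmm / 256

#' Train one slice generator
#'
#' The training loop: at every step a study, a volume of the requested shell
#' group, a cutoff extent (uniform on the configured range) and a cut side
#' (top/bottom, equal probability) are drawn; a mini-batch of slice indices
#' inside the brain's bounding box along the view axis is sampled; the
#' discriminator and generator are updated in alternation on the adversarial
#' + lambda * L1 objective. At every validation point the imputation error on
#' the validation studies' missing regions only (fixed cutoff) is computed,
#' and the returned generator is the checkpoint minimizing that error.
#'
#' @param trainCases,valCases lists of \code{dwifovCase} (see
#'   [prepareCase()]); at least one of each.
#' @param shellGroup "b0" or "bweighted".
#' @param view "sagittal" or "coronal".
#' @param config a [trainConfig()].
#' @return list with \code{generator} (best checkpoint, with view and shell
#'   group recorded), and \code{state}: loss traces (one row per step:
#'   dLoss, gAdv, gL1), validation trace, best step and score.
#' @export
trainGenerator <- function(trainCases, valCases,
                           shellGroup = c("b0", "bweighted"),
                           view = c("sagittal", "coronal"),
                           config = trainConfig()) {
  shellGroup <- match.arg(shellGroup)
  view <- match.arg(view)
  if (!length(trainCases) || !length(valCases))
    stop("need at least one training and one validation study")
  axis <- viewAxis(view)
  set.seed(config$seed)
  d3 <- dim(trainCases[[1]]$dwi)[1:3]
  sliceShape <- d3[-axis]
  n <- config$n
  nc <- 2L * (2L * n + 1L)
  gen <- newGenerator(nc, config$filters, sliceShape)
  disc <- newDiscriminator(nc + 1L, config$filters)
  genState <- adamInit(gen$layers)
  discState <- adamInit(disc$layers)
  vz <- trainCases[[1]]$voxelSize[3]
  valCut <- if (is.null(config$valCutMM)) defaultValCut(d3[3] * vz)
            else config$valCutMM
  # per-case cached geometry
  geo <- lapply(trainCases, function(cs) {
    list(extZ = maskExtent(cs$brain@mask, 3),
         bbox = maskExtent(cs$brain@mask, axis))
  })
  traces <- matrix(NA_real_, config$steps, 3,
                   dimnames = list(NULL, c("dLoss", "gAdv", "gL1")))
  valSteps <- integer(0); valScores <- numeric(0)
  best <- NULL; bestScore <- Inf; bestStep <- NA_integer_
  tG <- 0L; tD <- 0L
  for (step in seq_len(config$steps)) {
    ci <- sample.int(length(trainCases), 1)
    cs <- trainCases[[ci]]
    vols <- cs$groups[[shellGroup]]
    if (!length(vols)) stop("shell group ", shellGroup, " empty in study ", ci)
    v <- vols[sample.int(length(vols), 1)]
    cut <- stats::runif(1, config$cutoffRangeMM[1], config$cutoffRangeMM[2])
    side <- if (stats::runif(1) < 0.5) "top" else "bottom"
    k <- as.integer(roundHalfAway(cut / vz))
    extZ <- geo[[ci]]$extZ
    k <- min(k, extZ[2] - extZ[1])      # never swallow the whole brain
    truth <- cs$dwi[, , , v]
    trunc <- truncateVolume(truth, extZ, k, side)
    bbox <- geo[[ci]]$bbox
    idxs <- sample(bbox[1]:bbox[2], config$batchSize, replace = TRUE)
    stack <- buildBatch(trunc, cs$t1, axis, idxs, n,
                        ablate = config$ablateStructural)
    target <- buildTargets(truth, axis, idxs)
    lrt <- if (config$lrSchedule == "linear-half")
      config$lr * min(1, 2 * (config$steps - step + 1) / config$steps)
    else config$lr
    cond <- 2 * stack - 1
    real <- 2 * target - 1
    # one generator forward serves both steps: G is unchanged by the D update
    gf <- generatorForwardBatch(gen, stack, keepCache = TRUE)
    dl <- discLossGrads(disc, cond, real, gf$tanhOut)
    tD <- tD + 1L
    up <- adamUpdate(disc$layers, dl$grads, discState,
                     lrt, config$beta1, config$beta2, tD)
    disc$layers <- up$layers; discState <- up$state
    gl <- genLossGrads(gen, disc, stack, target, config$lambda, gf = gf)
    tG <- tG + 1L
    up <- adamUpdate(gen$layers, gl$grads, genState,
                     lrt, config$beta1, config$beta2, tG)
    gen$layers <- up$layers; genState <- up$state
    traces[step, ] <- c(-dl$value, gl$advTerm, gl$l1Term)
    if (!all(is.finite(traces[step, ])))
      stop("non-finite loss at step ", step,
           " (d=", traces[step, 1], ", gAdv=", traces[step, 2],
           ", gL1=", traces[step, 3], ")")
    if (step %% config$valEvery == 0 || step == config$steps) {
      sc <- validationScore(gen, valCases, valCut, cutSide = "top",
                            shellGroup = shellGroup, view = view, n = n,
                            ablateStructural = config$ablateStructural)
      valSteps <- c(valSteps, step); valScores <- c(valScores, sc)
      if (sc < bestScore) {
        bestScore <- sc; bestStep <- step
        best <- gen
      }
    }
  }
  best$view <- view
  best$shellGroup <- shellGroup
  best$n <- n
  list(generator = best,
       state = list(traces = as.data.frame(traces),
                    validation = data.frame(step = valSteps,
                                            score = valScores),
                    bestStep = bestStep, bestScore = bestScore,
                    valCutMM = valCut))
}

#' Imputed-region validation error of a generator
#'
#' Applies a fixed cutoff to each validation study, predicts the view's
#' slices, and returns the mean squared error within (brain mask AND missing
#' region) on the normalized intensity scale, averaged over studies. The
#' cutoff is fixed (not random) so scores are comparable across checkpoints.
#'
#' @param generator a \code{dwifovGenerator} or a function (see
#'   [forwardGenerate()]).
#' @param valCases list of \code{dwifovCase}.
#' @param cutMM,cutSide the fixed validation cutoff.
#' @param shellGroup,view routing of the generator.
#' @param n neighbourhood half-width.
#' @param ablateStructural zero the structural channels.
#' @return scalar mean error (lower is better).
#' @export
validationScore <- function(generator, valCases, cutMM, cutSide = "top",
                            shellGroup = c("b0", "bweighted"),
                            view = c("sagittal", "coronal"), n = 1,
                            ablateStructural = FALSE) {
  shellGroup <- match.arg(shellGroup)
  view <- match.arg(view)
  errs <- vapply(valCases, function(cs) {
    vols <- cs$groups[[shellGroup]]
    if (!length(vols)) stop("shell group ", shellGroup, " empty")
    v <- vols[1]
    vz <- cs$voxelSize[3]
    k <- as.integer(roundHalfAway(cutMM / vz))
    extZ <- maskExtent(cs$brain@mask, 3)
    if (k < 1) stop("validation cutoff produces an empty missing region")
    k <- min(k, extZ[2] - extZ[1])
    truth <- cs$dwi[, , , v]
    trunc <- truncateVolume(truth, extZ, k, cutSide)
    zs <- if (cutSide == "top") (extZ[2] - k + 1):extZ[2]
          else extZ[1]:(extZ[1] + k - 1)
    pred <- predictVolumeSlices(generator, trunc, cs$t1, view, n,
                                brain = cs$brain,
                                ablateStructural = ablateStructural)
    sel <- array(FALSE, dim = dim(truth))
    sel[, , zs] <- cs$brain@mask[, , zs] == 1
    if (!any(sel)) stop("validation missing region contains no brain voxels")
    mean((pred[sel] - truth[sel])^2)
  }, numeric(1))
  mean(errs)
}

#' Select the best checkpoint from validation scores
#'
#' The model-selection contract: the chosen checkpoint is the argmin of the
#' validation imputed-region error; ties resolve to the earliest checkpoint.
#'
#' @param scores numeric vector of validation errors, one per checkpoint, in
#'   chronological order.
#' @return integer index of the selected checkpoint.
#' @export
selectBestCheckpoint <- function(scores) {
  if (!length(scores) || any(!is.finite(scores)))
    stop("scores must be finite and non-empty")
  which.min(scores)
}

#' Train the full four-generator bundle
#'
#' Trains one generator per (shell group, view) pair, each on its own shell
#' group and view only, with per-pair seeds derived from the configured
#' master seed.
#'
#' @inheritParams trainGenerator
#' @return list with \code{bundle} (a [ModelBundle-class]) and
#'   \code{states} (per-pair training states).
#' @export
trainBundle <- function(trainCases, valCases, config = trainConfig()) {
  gens <- list(); states <- list()
  i <- 0L
  for (shell in c("b0", "bweighted")) {
    for (view in c("sagittal", "coronal")) {
      i <- i + 1L
      cfg <- config
      cfg$seed <- childSeed(config$seed, i)
      key <- paste(shell, view, sep = ".")
      res <- trainGenerator(trainCases, valCases, shell, view, cfg)
      gens[[key]] <- res$generator
      states[[key]] <- res$state
    }
  }
  d3 <- dim(trainCases[[1]]$dwi)[1:3]
  meta <- list(n = config$n, lambda = config$lambda,
               gridShape = d3, voxelSize = trainCases[[1]]$voxelSize,
               filters = config$filters, steps = config$steps,
               seed = config$seed,
               ablateStructural = config$ablateStructural,
               normalization = "99.9th-percentile scale, clip to [0,1]")
  list(bundle = modelBundle(gens, meta), states = states)
}

#' Save / load a model bundle
#'
#' A bundle directory holds one weights file per (shell group, view) pair
#' plus a JSON manifest recording n, grid, normalization convention, lambda
#' and seed.
#'
#' @param bundle a [ModelBundle-class].
#' @param dir directory path.
#' @return \code{saveModelBundle}: invisibly \code{dir};
#'   \code{loadModelBundle}: a [ModelBundle-class].
#' @export
saveModelBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(bundle@generators))
    saveRDS(bundle@generators[[key]],
            file.path(dir, paste0(key, ".rds")))
  jsonlite::write_json(bundle@meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname saveModelBundle
#' @export
loadModelBundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  gens <- list()
  for (key in bundleKeys) {
    f <- file.path(dir, paste0(key, ".rds"))
    if (!file.exists(f)) stop("missing generator weights: ", f)
    gens[[key]] <- readRDS(f)
  }
  modelBundle(gens, manifest)
}
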