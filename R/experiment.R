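#' Reference desk-scale end-to-end experiment
#'
#' The package's complete study in miniature, fully seeded: simulate
#' train/val/test phantom splits, train the four slice generators and a
#' T1w-ablated baseline bundle under identical settings and seeds, impute
#' test studies truncated from the top of the brain, and evaluate against
#' the zero-fill and nearest-acquired-slice-replication baselines, the
#' distance-stratified performance pattern, and the per-direction ADC
#' direction-bias test.
#'
#' Defaults are the package's desk-scale study conditions: 12/3/5 phantoms
#' of 48^3 voxels with 1 b0 + 6 directions at b = 1300 s/mm^2 and Rician
#' noise sigma = 0.02, four generators with n = 1 and 8 base filters
#' trained for 500 steps each, and a 10 mm test cutoff from the top.
#'
#' @param seed master seed for every source of randomness.
#' @param nTrain,nVal,nTest split sizes.
#' @param testCutMM fixed cutoff applied to test studies (mm).
#' @param spec a [phantomSpec()]; per-case seeds are derived from
#'   \code{seed}.
#' @param config a [trainConfig()]; the training cutoff range defaults to
#'   0-12 mm, the 48-voxel-grid equivalent of the full-scale 0-50 mm
#'   augmentation.
#' @param verbose print progress messages.
#' @return list with elements \code{report} (per-method, per-shell-group
#'   mean/sd of MSE, PSNR, SSIM over the test studies, methods: imputed,
#'   ablated, zerofill, replicate), \code{acquiredMaxDiff} (largest change
#'   on any acquired voxel; 0 by construction), \code{distanceTable}
#'   (pooled per-slice distance vs PSNR rows), \code{distanceSpearman}
#'   (rank correlation between distance and PSNR), \code{adcTest} (H, p of
#'   the per-direction Kruskal-Wallis test), and \code{states} (training
#'   states of the full bundle).
#' @export
fovExtensionExperiment <- function(seed = 1, nTrain = 12, nVal = 3,
                                   nTest = 5, testCutMM = 10,
                                   spec = phantomSpec(),
                                   config = trainConfig(cutoffRangeMM = c(0, 12),
                                                        maxCutMM = 12),
                                   verbose = interactive()) {
  say <- function(...) if (verbose) message(...)
  mkCase <- function(k) {
    s <- spec
    s$seed <- childSeed(seed, k)
    ph <- generatePhantom(s)
    prepareCase(ph$dwi, ph$t1)
  }
  say("simulating ", nTrain + nVal + nTest, " phantom studies")
  trainCases <- lapply(seq_len(nTrain), mkCase)
  valCases <- lapply(nTrain + seq_len(nVal), mkCase)
  testIdx <- nTrain + nVal + seq_len(nTest)
  testPh <- lapply(testIdx, function(k) {
    s <- spec
    s$seed <- childSeed(seed, k)
    generatePhantom(s)
  })
  testCases <- lapply(testPh, function(ph) prepareCase(ph$dwi, ph$t1))

  cfgFull <- config
  cfgFull$seed <- childSeed(seed, 1001)
  say("training the four generators")
  full <- trainBundle(trainCases, valCases, cfgFull)
  cfgAbl <- cfgFull
  cfgAbl$ablateStructural <- TRUE
  say("training the T1w-ablated baseline bundle")
  abl <- trainBundle(trainCases, valCases, cfgAbl)

  refs <- list(); outs <- list(imputed = list(), ablated = list(),
                               zerofill = list(), replicate = list())
  fovs <- list(); brains <- list()
  distRows <- list()
  acquiredMaxDiff <- 0
  say("imputing ", nTest, " truncated test studies")
  for (i in seq_len(nTest)) {
    ph <- testPh[[i]]
    cs <- testCases[[i]]
    key <- paste0("case", i)
    sc <- simulateCutoff(ph$dwi, cs$brain, testCutMM, "top")
    out <- imputeStudy(full$bundle, sc$study, ph$t1, fov = sc$fov,
                       brain = cs$brain)
    outA <- imputeStudy(abl$bundle, sc$study, ph$t1, fov = sc$fov,
                        brain = cs$brain, ablateStructural = TRUE)
    acq <- sc$fov@mask == 1
    acquiredMaxDiff <- max(acquiredMaxDiff,
                           vapply(seq_len(nVolumes(out)), function(v)
                             max(abs(out@data[, , , v][acq] -
                                       sc$study@data[, , , v][acq])),
                             numeric(1)))
    # baselines: zero fill is the truncated study itself; replication
    # copies the nearest acquired slice into every missing slice
    missZ <- which(apply(sc$fov@mask, 3, min) == 0)
    nearZ <- min(missZ) - 1          # top cut: slice just below the block
    replData <- sc$study@data
    for (z in missZ) replData[, , z, ] <- sc$study@data[, , nearZ, ]
    refs[[key]] <- ph$dwi
    outs$imputed[[key]] <- out
    outs$ablated[[key]] <- outA
    outs$zerofill[[key]] <- sc$study
    outs$replicate[[key]] <- dwiStudy(replData, sc$study@gradients,
                                      voxelSize = sc$study@voxelSize,
                                      affine = sc$study@affine)
    fovs[[key]] <- sc$fov
    brains[[key]] <- cs$brain
    # distance-stratified rows on the normalized scale, both shell groups
    params <- computeNormalization(ph$dwi)
    for (v in c(volumeGroups(ph$dwi)$b0[1],
                volumeGroups(ph$dwi)$bweighted[1])) {
      tab <- distanceStratifiedMetrics(
        applyNormalization(ph$dwi@data[, , , v], params),
        applyNormalization(out@data[, , , v], params),
        sc$fov, cs$brain, voxelZ = ph$dwi@voxelSize[3])
      tab$case <- key
      distRows[[length(distRows) + 1]] <- tab
    }
  }
  say("computing the evaluation report")
  report <- compareMethods(refs, outs, fovs, brains)
  distanceTable <- do.call(rbind, distRows)
  ok <- is.finite(distanceTable$psnr)
  distanceSpearman <- stats::cor(distanceTable$distanceMM[ok],
                                 distanceTable$psnr[ok],
                                 method = "spearman")
  # per-direction ADC fidelity: one PSNR per (direction, study), compared
  # across directions. ADC in 1e-3 mm^2/s units, range 3 (CSF diffusivity).
  nDir <- length(volumeGroups(refs[[1]])$bweighted)
  adcPsnr <- lapply(seq_len(nDir), function(d) {
    vapply(names(refs), function(key) {
      region <- (fovs[[key]]@mask == 0) & (brains[[key]]@mask == 1)
      aRef <- adcMap(refs[[key]], d) * 1e3
      aTst <- adcMap(outs$imputed[[key]], d) * 1e3
      okv <- region & is.finite(aRef) & is.finite(aTst)
      mse <- mean((aRef[okv] - aTst[okv])^2)
      10 * log10(3^2 / mse)
    }, numeric(1))
  })
  adcTest <- directionBiasTest(adcPsnr)
  list(report = report, acquiredMaxDiff = acquiredMaxDiff,
       distanceTable = distanceTable, distanceSpearman = distanceSpearman,
       adcPsnr = adcPsnr, adcTest = adcTest,
       states = full$states, ablatedStates = abl$states,
       bundle = full$bundle)
}
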