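#' Masked mean squared error
#'
#' Mean of squared differences over mask voxels only.
#'
#' @param reference,test arrays of one shape.
#' @param mask binary array of the same shape; must select at least one
#'   voxel.
#' @return scalar MSE.
#' @export
maskedMSE <- function(reference, test, mask) {
  if (!all(dim(reference) == dim(test)) || !all(dim(reference) == dim(mask)))
    stop("reference, test and mask must share one shape")
  sel <- mask > 0
  if (!any(sel)) stop("mask is empty")
  mean((reference[sel] - test[sel])^2)
}

#' Masked peak signal-to-noise ratio
#'
#' \code{10 * log10(dataRange^2 / MSE)} in dB over the mask; identical
#' volumes give the +Inf sentinel.
#'
#' @inheritParams maskedMSE
#' @param dataRange dynamic range of the intensities (1 on the normalized
#'   scale used throughout this package).
#' @return scalar PSNR in dB (+Inf when MSE = 0).
#' @export
maskedPSNR <- function(reference, test, mask, dataRange = 1) {
  if (dataRange <= 0) stop("dataRange must be positive")
  mse <- maskedMSE(reference, test, mask)
  if (mse == 0) return(Inf)
  10 * log10(dataRange^2 / mse)
}

# cumulative sum along one axis of a 3-D array
cumAlong <- function(x, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  m <- matrix(xp, d[axis])
  m <- apply(m, 2, cumsum)
  aperm(array(m, dim = d[perm]), order(perm))
}

# windowed sums of size w along every axis via cumulative sums:
# out[i] = cs[i + w - 1] - cs[i - 1] (cs[0] = 0); output dims shrink by w - 1
boxSumValid <- function(x, w) {
  for (axis in 1:3) {
    cs <- cumAlong(x, axis)
    n <- dim(cs)[axis]
    upper <- switch(axis, cs[w:n, , , drop = FALSE],
                    cs[, w:n, , drop = FALSE], cs[, , w:n, drop = FALSE])
    lower <- upper * 0
    if (n - w >= 1) {
      lowCs <- switch(axis, cs[1:(n - w), , , drop = FALSE],
                      cs[, 1:(n - w), , drop = FALSE],
                      cs[, , 1:(n - w), drop = FALSE])
      switch(axis,
             lower[-1, , ] <- lowCs,
             lower[, -1, ] <- lowCs,
             lower[, , -1] <- lowCs)
    }
    x <- upper - lower
  }
  x
}

# SSIM map over valid window centres (uniform cubic window). Returns the map
# (dims = shape - w + 1) and the centre offset r = (w-1)/2.
ssimMapValid <- function(reference, test, window = 7, dataRange = 1) {
  w <- window
  nw <- w^3
  mu1 <- boxSumValid(reference, w) / nw
  mu2 <- boxSumValid(test, w) / nw
  s1 <- boxSumValid(reference^2, w) / nw - mu1^2
  s2 <- boxSumValid(test^2, w) / nw - mu2^2
  s12 <- boxSumValid(reference * test, w) / nw - mu1 * mu2
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s1 + s2 + C2))
  list(map = map, offset = (w - 1) %/% 2)
}

#' 3-D structural similarity index
#'
#' Standard SSIM with a uniform cubic window (side \code{window} in every
#' dimension) and stabilizing constants \code{(0.01 * dataRange)^2} and
#' \code{(0.03 * dataRange)^2}, averaged over window centres that lie inside
#' the mask (windows are always fully inside the volume).
#'
#' @inheritParams maskedPSNR
#' @param mask binary array; NULL averages over all valid centres.
#' @param window odd window side, at least 3 (default 7).
#' @return scalar in [-1, 1].
#' @export
ssim3D <- function(reference, test, mask = NULL, window = 7, dataRange = 1) {
  if (window < 3 || window %% 2 != 1) stop("window must be odd and >= 3")
  if (!all(dim(reference) == dim(test)))
    stop("reference and test must share one shape")
  if (any(dim(reference) < window))
    stop("volume smaller than the SSIM window")
  sm <- ssimMapValid(reference, test, window, dataRange)
  if (is.null(mask)) return(mean(sm$map))
  r <- sm$offset
  d <- dim(reference)
  maskC <- mask[(r + 1):(d[1] - r), (r + 1):(d[2] - r),
                (r + 1):(d[3] - r), drop = FALSE]
  sel <- maskC > 0
  if (!any(sel)) stop("no window centres inside the mask")
  mean(sm$map[sel])
}

#' Imputation performance stratified by distance to the acquired region
#'
#' Assigns each missing axial slice its distance (mm) to the nearest
#' informative acquired slice (an acquired slice intersecting the brain;
#' acquired background slices beyond the cut are not a data boundary) and
#' computes PSNR/SSIM per distance bin within the brain mask. This quantifies how performance degrades deeper into the missing
#' region.
#'
#' @param reference,test 3-D arrays (normalized intensities).
#' @param fov an [FOVMask-class] with a non-empty missing region.
#' @param brain a [BrainMask-class].
#' @param voxelZ axial voxel size in mm.
#' @param binMM bin width in mm (default one slice).
#' @param window SSIM window.
#' @param dataRange intensity range.
#' @return data.frame with one row per bin: distanceMM, nSlices, nVoxels,
#'   mse, psnr, ssim.
#' @export
distanceStratifiedMetrics <- function(reference, test, fov, brain,
                                      voxelZ = 1, binMM = voxelZ,
                                      window = 7, dataRange = 1) {
  d <- dim(reference)
  sliceAcq <- apply(fov@mask, 3, min) == 1
  missZ <- which(!sliceAcq)
  if (!length(missZ)) stop("FOV mask has no missing slices")
  # distance to the nearest *informative* acquired slice: one that
  # intersects the brain. Acquired background slices beyond the cut carry
  # no signal and do not count as a data boundary.
  hasBrain <- apply(brain@mask, 3, max) > 0
  acqZ <- which(sliceAcq & hasBrain)
  if (!length(acqZ)) acqZ <- which(sliceAcq)
  dist <- vapply(missZ, function(z) min(abs(z - acqZ)) * voxelZ, numeric(1))
  bin <- ceiling(dist / binMM) * binMM
  sm <- ssimMapValid(reference, test, window, dataRange)
  r <- sm$offset
  maskC <- brain@mask[(r + 1):(d[1] - r), (r + 1):(d[2] - r),
                      (r + 1):(d[3] - r), drop = FALSE]
  rows <- lapply(sort(unique(bin)), function(bv) {
    zs <- missZ[bin == bv]
    sel <- array(FALSE, dim = d)
    sel[, , zs] <- brain@mask[, , zs] > 0
    nv <- sum(sel)
    mse <- if (nv) mean((reference[sel] - test[sel])^2) else NA_real_
    psnr <- if (!nv || is.na(mse)) NA_real_
            else if (mse == 0) Inf else 10 * log10(dataRange^2 / mse)
    zc <- zs[zs > r & zs <= d[3] - r] - r
    ssim <- NA_real_
    if (length(zc)) {
      selC <- array(FALSE, dim = dim(sm$map))
      selC[, , zc] <- maskC[, , zc, drop = FALSE] > 0
      if (any(selC)) ssim <- mean(sm$map[selC])
    }
    data.frame(distanceMM = bv, nSlices = length(zs), nVoxels = nv,
               mse = mse, psnr = psnr, ssim = ssim)
  })
  do.call(rbind, rows)
}

#' Apparent diffusion coefficient map for one gradient direction
#'
#' \code{ADC = -ln(S / S0) / b} per voxel (mm^2/s), with S0 the mean of the
#' study's b0 volumes and S the indexed diffusion-weighted volume. Voxels
#' with non-positive S or S0 are set to NA and excluded downstream.
#'
#' @param study a [DWIStudy-class] with at least one b0 volume.
#' @param directionIndex 1-based index into the diffusion-weighted volumes.
#' @return 3-D array of ADC values (NA where undefined).
#' @export
adcMap <- function(study, directionIndex) {
  g <- volumeGroups(study)
  if (!length(g$b0)) stop("study has no b0 volume")
  if (directionIndex < 1 || directionIndex > length(g$bweighted))
    stop("directionIndex out of range [1, ", length(g$bweighted), "]")
  v <- g$bweighted[directionIndex]
  b <- bValues(study)[v]
  S0 <- apply(study@data[, , , g$b0, drop = FALSE], 1:3, mean)
  S <- study@data[, , , v]
  adc <- array(NA_real_, dim = dim(S))
  ok <- S > 0 & S0 > 0
  adc[ok] <- -log(S[ok] / S0[ok]) / b
  adc
}

#' Direction-bias test on per-direction performance
#'
#' Kruskal-Wallis rank test (with tie correction) across gradient-direction
#' groups, asking whether imputation performance depends on the diffusion
#' direction. When every observation is identical the degenerate case is
#' reported as H = 0, p = 1.
#'
#' @param perDirection list of numeric vectors, one per direction group
#'   (at least 2 groups with at least 1 observation each).
#' @return list with \code{H} (test statistic), \code{p} (chi-square
#'   p-value) and \code{df}.
#' @export
directionBiasTest <- function(perDirection) {
  if (length(perDirection) < 2 || any(lengths(perDirection) < 1))
    stop("need at least 2 direction groups with at least 1 observation each")
  vals <- unlist(perDirection, use.names = FALSE)
  if (length(unique(vals)) == 1)
    return(list(H = 0, p = 1, df = length(perDirection) - 1L))
  grp <- factor(rep(seq_along(perDirection), lengths(perDirection)))
  kt <- stats::kruskal.test(vals, grp)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

# per-shell-group metrics for one (reference, test) study pair on the
# normalized scale of the reference study
evaluateStudyPair <- function(refStudy, testStudy, fov, brain, window = 7) {
  params <- computeNormalization(refStudy)
  g <- volumeGroups(refStudy)
  region <- (fov@mask == 0) & (brain@mask == 1)
  if (!any(region)) stop("evaluation region (missing AND brain) is empty")
  rows <- lapply(c("b0", "bweighted"), function(shell) {
    vols <- g[[shell]]
    if (!length(vols)) return(NULL)
    ms <- vapply(vols, function(v) {
      ref <- applyNormalization(refStudy@data[, , , v], params)
      tst <- applyNormalization(testStudy@data[, , , v], params)
      c(mse = maskedMSE(ref, tst, region),
        psnr = maskedPSNR(ref, tst, region, dataRange = 1),
        ssim = ssim3D(ref, tst, mask = region, window = window,
                      dataRange = 1))
    }, numeric(3))
    data.frame(shellGroup = shell, mse = mean(ms["mse", ]),
               psnr = mean(ms["psnr", ]), ssim = mean(ms["ssim", ]))
  })
  do.call(rbind, rows)
}

#' Compare imputation methods across studies
#'
#' For every method and shell group, per-study masked MSE/PSNR/SSIM are
#' computed over (missing region AND brain mask) on the normalized [0, 1]
#' scale (dataRange = 1), then aggregated as mean and standard deviation
#' across studies.
#'
#' @param referenceStudies named list of ground-truth [DWIStudy-class].
#' @param methodOutputs named list (one element per method) of named lists
#'   of output studies; study names must match \code{referenceStudies}.
#' @param fovs,brains named lists of [FOVMask-class] / [BrainMask-class]
#'   per study.
#' @param window SSIM window.
#' @return data.frame with columns method, shellGroup, and mean/sd of mse,
#'   psnr, ssim.
#' @export
compareMethods <- function(referenceStudies, methodOutputs, fovs, brains,
                           window = 7) {
  keys <- names(referenceStudies)
  for (m in names(methodOutputs))
    if (!setequal(names(methodOutputs[[m]]), keys))
      stop("study keys of method '", m, "' do not match the references")
  rows <- list()
  for (m in names(methodOutputs)) {
    per <- lapply(keys, function(k)
      cbind(study = k,
            evaluateStudyPair(referenceStudies[[k]],
                              methodOutputs[[m]][[k]],
                              fovs[[k]], brains[[k]], window)))
    per <- do.call(rbind, per)
    for (shell in unique(per$shellGroup)) {
      sub <- per[per$shellGroup == shell, ]
      rows[[length(rows) + 1]] <- data.frame(
        method = m, shellGroup = shell,
        mseMean = mean(sub$mse), mseSD = stats::sd(sub$mse),
        psnrMean = mean(sub$psnr), psnrSD = stats::sd(sub$psnr),
        ssimMean = mean(sub$ssim), ssimSD = stats::sd(sub$ssim))
    }
  }
  do.call(rbind, rows)
}

#' Write an evaluation report as CSV and JSON
#'
#' @param report data.frame (e.g. from [compareMethods()] or
#'   [distanceStratifiedMetrics()]).
#' @param csvPath,jsonPath output paths (NULL skips a format).
#' @return invisibly, the written paths.
#' @export
writeEvalReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath)) utils::write.csv(report, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(c(csvPath, jsonPath))
}
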