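# Internal slice-by-slice predictor. Predicts slices along the view axis,
# optionally restricted to the brain's bounding box (slices outside it stay
# zero), batching stacks through the generator in chunks.
predictVolumeSlices <- function(generator, dwiVolume, structural, view, n,
                                brain = NULL, ablateStructural = FALSE,
                                chunk = 24) {
  axis <- viewAxis(view)
  d <- dim(dwiVolume)
  if (!all(d == dim(structural)))
    stop("DWI and structural volumes must share one shape")
  rng <- if (is.null(brain)) c(1L, d[axis]) else maskExtent(brain@mask, axis)
  out <- array(0, dim = d)
  idxAll <- rng[1]:rng[2]
  if (is.function(generator)) {
    for (i in idxAll) {
      ps <- extractPatch(dwiVolume, structural, view, i, n)
      input <- ps@input
      if (ablateStructural) input[, , (2 * n + 2):(2 * (2 * n + 1))] <- 0
      out <- setSlice(out, axis, i, forwardGenerate(generator, input))
    }
    return(out)
  }
  for (start in seq(1, length(idxAll), by = chunk)) {
    idxs <- idxAll[start:min(start + chunk - 1, length(idxAll))]
    stack <- buildBatch(dwiVolume, structural, axis, idxs, n,
                        ablate = ablateStructural)
    pred <- generatorForwardBatch(generator, stack)$out01
    for (b in seq_along(idxs))
      out <- setSlice(out, axis, idxs[b], pred[, , 1, b])
  }
  out
}

#' Predict a whole volume in one view
#'
#' Runs the generator on every slice along the view axis and stacks the
#' predictions into a full volume on the grid.
#'
#' @param generator a \code{dwifovGenerator} (trained for this view) or a
#'   plain function mapping an H x W x C stack to an H x W matrix.
#' @param dwiVolume normalized 3-D DWI volume (typically FOV-truncated).
#' @param structural normalized 3-D structural array on the same grid.
#' @param view "sagittal" or "coronal".
#' @param n neighbourhood half-width.
#' @param ablateStructural zero the structural channels before prediction.
#' @return 3-D array of predictions, same shape as \code{dwiVolume}.
#' @export
predictVolumeView <- function(generator, dwiVolume, structural, view, n,
                              ablateStructural = FALSE) {
  view <- match.arg(view, c("sagittal", "coronal"))
  if (!is.function(generator) && !is.null(generator$view) &&
      nzchar(generator$view) && generator$view != view)
    stop("generator was trained for the ", generator$view,
         " view, not ", view)
  predictVolumeSlices(generator, dwiVolume, structural, view, n,
                      brain = NULL, ablateStructural = ablateStructural)
}

#' Merge two single-view predictions
#'
#' Voxel-wise arithmetic mean of the sagittal and coronal predictions
#' (equal weights).
#'
#' @param predSagittal,predCoronal 3-D arrays of one shape.
#' @return 3-D array.
#' @export
mergeViews <- function(predSagittal, predCoronal) {
  if (!all(dim(predSagittal) == dim(predCoronal)))
    stop("view predictions must share one shape")
  (predSagittal + predCoronal) / 2
}

#' Impute the missing FOV of a DWI study
#'
#' The full pipeline: route each volume to its shell group's generators,
#' predict sagittal and coronal volumes, merge by voxel averaging, keep the
#' missing-region slices only, map back to subject geometry, and recombine
#' as \code{m * acquired + (1 - m) * imputed}. Acquired voxels and the
#' gradient table pass through bit-identically.
#'
#' @param bundle a complete [ModelBundle-class].
#' @param study the FOV-truncated [DWIStudy-class] (raw intensities).
#' @param structural the complete-FOV [StructuralImage-class], co-registered
#'   with the study.
#' @param fov optional [FOVMask-class] on the study's grid; derived from
#'   zero-slice runs adjacent to the brain's z-extremes when NULL.
#' @param brain optional [BrainMask-class]; computed from the structural
#'   image when NULL.
#' @param maskToBrain mask imputed slices to the brain before recombination
#'   (default TRUE), preventing halo artifacts outside tissue.
#' @param ablateStructural zero the structural channels (baseline mode).
#' @return a [DWIStudy-class] with the missing region filled in.
#' @export
imputeStudy <- function(bundle, study, structural, fov = NULL, brain = NULL,
                        maskToBrain = TRUE, ablateStructural = FALSE) {
  validObject(bundle)
  n <- bundle@meta$n
  if (is.null(n)) stop("bundle manifest lacks the neighbourhood width n")
  gshape <- bundle@meta$gridShape
  onGrid <- is.null(gshape) || all(dim(study@data)[1:3] == gshape)
  if (!onGrid) {
    grid <- normalizedGrid(gshape, bundle@meta$voxelSize[1])
    ga <- gridAffine(grid, dim(study@data)[1:3], study@affine)
    V <- nVolumes(study)
    dataG <- array(0, dim = c(grid@shape, V))
    for (v in seq_len(V))
      dataG[, , , v] <- resampleToGrid(study@data[, , , v], study@affine,
                                       grid, ga)
    t1G <- resampleToGrid(structural@data, structural@affine, grid, ga)
    vox <- rep(grid@voxelSize, 3)
  } else {
    dataG <- study@data
    t1G <- structural@data
    vox <- study@voxelSize
    ga <- NULL
    if (!all(dim(t1G) == dim(dataG)[1:3]))
      stop("structural image must share the study grid")
  }
  normDWI <- computeNormalization(dataG)
  normT1 <- computeNormalization(t1G)
  dwiN <- applyNormalization(dataG, normDWI)
  t1N <- applyNormalization(t1G, normT1)
  if (is.null(brain)) brain <- computeBrainMask(t1N)
  gridStudy <- dwiStudy(dataG, study@gradients, voxelSize = vox)
  if (is.null(fov)) fov <- deriveFOVMask(gridStudy, brain)
  miss <- fov@mask == 0
  if (!any(miss)) return(study)          # complete FOV: nothing to impute
  groups <- volumeGroups(study)
  bm <- brain@mask
  outData <- study@data
  subjFov <- fov
  if (!onGrid) {
    m <- resampleFromGrid(fov@mask, grid, ga, dim(study@data)[1:3],
                          study@affine, interpolation = "nearest")
    subjFov <- fovMask(m, fov@cutSide, fov@cutMM)
  }
  for (shell in c("b0", "bweighted")) {
    vols <- groups[[shell]]
    if (!length(vols)) next
    gS <- bundle@generators[[paste0(shell, ".sagittal")]]
    gC <- bundle@generators[[paste0(shell, ".coronal")]]
    if (is.null(gS) || is.null(gC))
      stop("bundle lacks generators for present shell group ", shell)
    for (v in vols) {
      trunc <- dwiN[, , , v]
      predS <- predictVolumeSlices(gS, trunc, t1N, "sagittal", n,
                                   brain = if (maskToBrain) brain else NULL,
                                   ablateStructural = ablateStructural)
      predC <- predictVolumeSlices(gC, trunc, t1N, "coronal", n,
                                   brain = if (maskToBrain) brain else NULL,
                                   ablateStructural = ablateStructural)
      merged <- mergeViews(predS, predC)
      if (maskToBrain) merged <- merged * bm
      imputed <- invertNormalization(merged, normDWI)
      if (!onGrid)
        imputed <- resampleFromGrid(imputed, grid, ga,
                                    dim(study@data)[1:3], study@affine)
      outData[, , , v] <- recombine(study@data[, , , v], imputed, subjFov)
    }
  }
  dwiStudy(outData, study@gradients, voxelSize = study@voxelSize,
           affine = study@affine)
}
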