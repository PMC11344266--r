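#' Extract one 2.5D patch sample
#'
#' Builds the (2(2n+1))-channel input stack for slice \code{sliceIndex} in
#' the chosen view: channels 1..(2n+1) are the DWI slices i-n .. i+n,
#' channels (2n+2)..2(2n+1) the structural slices at identical spatial
#' indices. Neighbour slices beyond the volume are zero-filled. The target is
#' the slice at \code{sliceIndex} of \code{targetVolume} (by default the DWI
#' volume itself, i.e. the self-supervised full-FOV regime).
#'
#' @param dwiVolume 3-D normalized DWI volume (single v) on the grid; when
#'   training with simulated cutoffs this is the truncated volume.
#' @param structural 3-D normalized structural array of the same shape.
#' @param view "sagittal" or "coronal"; the axial view is rejected.
#' @param sliceIndex 1-based slice index along the view axis.
#' @param n neighbourhood half-width (paper-scale default is 7; desk-scale
#'   tests use 1-2).
#' @param targetVolume 3-D array the ground-truth target slice is taken from;
#'   defaults to \code{dwiVolume}.
#' @param shellGroup optional label stored on the sample.
#' @return a [PatchSample-class].
#' @export
extractPatch <- function(dwiVolume, structural, view, sliceIndex, n,
                         targetVolume = dwiVolume, shellGroup = "") {
  if (n < 0) stop("n must be non-negative")
  axis <- viewAxis(view)
  d <- dim(dwiVolume)
  if (!all(d == dim(structural)))
    stop("DWI and structural volumes must share one shape")
  if (sliceIndex < 1 || sliceIndex > d[axis])
    stop("slice index ", sliceIndex, " out of bounds [1, ", d[axis], "]")
  sliceDim <- d[-axis]
  nc <- 2L * (2L * n + 1L)
  input <- array(0, dim = c(sliceDim, nc))
  offs <- (-n):n
  for (j in seq_along(offs)) {
    i <- sliceIndex + offs[j]
    input[, , j] <- getSliceZero(dwiVolume, axis, i)
    input[, , j + 2 * n + 1] <- getSliceZero(structural, axis, i)
  }
  new("PatchSample", input = input,
      target = getSliceZero(targetVolume, axis, sliceIndex),
      view = view, sliceIndex = as.integer(sliceIndex),
      shellGroup = shellGroup)
}

#' Enumerate training samples for one study
#'
#' Yields one [PatchSample-class] per (slice index, volume) pair, for all
#' slice indices intersecting the brain's bounding box along the view axis
#' and all volumes of the requested shell group. Inputs are taken from the
#' FOV-truncated data (\code{study} masked by \code{fov}); targets come from
#' the uncorrupted ground truth, so the model is trained to predict both
#' cutoff and non-cutoff regions.
#'
#' @param study ground-truth [DWIStudy-class], normalized and on the grid.
#' @param structural normalized 3-D structural array (or
#'   [StructuralImage-class]) on the same grid.
#' @param fov an [FOVMask-class]; inputs are \code{study * mask}.
#' @param view "sagittal" or "coronal".
#' @param shellGroup "b0" or "bweighted".
#' @param n neighbourhood half-width.
#' @param brain a [BrainMask-class] giving the bounding box; required.
#' @return list of [PatchSample-class] objects, ordered volume-major then
#'   slice. Empty (with a warning) when the brain box is empty.
#' @export
enumerateTrainingSamples <- function(study, structural, fov, view,
                                     shellGroup = c("b0", "bweighted"),
                                     n = 1, brain) {
  shellGroup <- match.arg(shellGroup)
  axis <- viewAxis(view)
  if (is(structural, "StructuralImage")) structural <- structural@data
  vols <- volumeGroups(study)[[shellGroup]]
  ext <- tryCatch(maskExtent(brain@mask, axis), error = function(e) NULL)
  if (is.null(ext)) {
    warning("empty brain bounding box; no training samples")
    return(list())
  }
  m <- fov@mask
  out <- vector("list", length(vols) * (ext[2] - ext[1] + 1))
  k <- 0L
  for (v in vols) {
    truth <- study@data[, , , v]
    trunc <- truth * m
    for (i in ext[1]:ext[2]) {
      k <- k + 1L
      out[[k]] <- extractPatch(trunc, structural, view, i, n,
                               targetVolume = truth,
                               shellGroup = shellGroup)
    }
  }
  out
}
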