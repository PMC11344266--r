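#' Construct a validated gradient table
#'
#' Coerces a raw FSL-style gradient table into the internal invariants:
#' b-vectors of diffusion-weighted volumes are renormalized to unit length
#' (with a warning when the input norm deviates by more than 1e-3), and
#' b-vectors of b0 volumes are forced to (0, 0, 0).
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs 3 x V matrix of gradient directions (columns), FSL layout.
#' @param b0Threshold b-value separating b0 from weighted volumes. Default 50
#'   s/mm^2, which absorbs the small non-zero b-values scanners report for
#'   unweighted volumes.
#' @return a [GradientTable-class].
#' @examples
#' gt <- gradientTable(c(0, 1300), cbind(c(0, 0, 0), c(0.6, 0.8, 0)))
#' bValues(gt)
#' @export
gradientTable <- function(bvals, bvecs, b0Threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3 && ncol(bvecs) == 3) bvecs <- t(bvecs)
  if (length(bvals) != ncol(bvecs))
    stop("gradient table mismatch: ", length(bvals), " b-values vs ",
         ncol(bvecs), " b-vectors")
  wtd <- bvals > b0Threshold
  if (any(wtd)) {
    nrm <- sqrt(colSums(bvecs[, wtd, drop = FALSE]^2))
    if (any(nrm == 0))
      stop("weighted volume with zero b-vector")
    if (any(abs(nrm - 1) > 1e-3))
      warning("renormalizing ", sum(abs(nrm - 1) > 1e-3),
              " b-vector(s) with non-unit norm")
    bvecs[, wtd] <- sweep(bvecs[, wtd, drop = FALSE], 2, nrm, "/")
  }
  if (any(!wtd)) {
    if (any(colSums(abs(bvecs[, !wtd, drop = FALSE])) > 1e-12))
      warning("zeroing b-vector(s) of b0 volume(s)")
    bvecs[, !wtd] <- 0
  }
  new("GradientTable", bvals = bvals, bvecs = bvecs,
      b0Threshold = as.numeric(b0Threshold))
}

#' Construct a DWI study
#'
#' @param data 4-D array indexed (x, y, z, volume); z is superior-inferior
#'   with the slice index increasing toward superior.
#' @param gradients a [GradientTable-class] (or bvals/bvecs via
#'   [gradientTable()]).
#' @param voxelSize numeric length-3, mm.
#' @param affine 4 x 4 voxel-to-world matrix (0-based voxel indices); defaults
#'   to a diagonal scaling by \code{voxelSize}.
#' @return a [DWIStudy-class].
#' @export
dwiStudy <- function(data, gradients, voxelSize = c(1, 1, 1),
                     affine = NULL) {
  if (is.null(affine)) affine <- diag(c(voxelSize, 1))
  new("DWIStudy", data = data, gradients = gradients,
      voxelSize = as.numeric(voxelSize), affine = affine)
}

#' Construct a structural image
#'
#' @param data 3-D array.
#' @inheritParams dwiStudy
#' @return a [StructuralImage-class].
#' @export
structuralImage <- function(data, voxelSize = c(1, 1, 1), affine = NULL) {
  if (is.null(affine)) affine <- diag(c(voxelSize, 1))
  new("StructuralImage", data = data, voxelSize = as.numeric(voxelSize),
      affine = affine)
}

#' Construct a normalized grid
#'
#' @param shape integer length-3 (voxels). Default 256^3, the full-scale
#'   analysis grid; tests and desk-scale phantoms use 48-64^3.
#' @param voxelSize isotropic voxel edge length in mm (default 1).
#' @return a [NormalizedGrid-class].
#' @export
normalizedGrid <- function(shape = c(256L, 256L, 256L), voxelSize = 1) {
  new("NormalizedGrid", shape = as.integer(shape),
      voxelSize = as.numeric(voxelSize))
}

#' Construct an FOV mask
#'
#' @param mask binary 3-D array (1 = acquired).
#' @param cutSide "top", "bottom" or "none".
#' @param cutMM cutoff extent in mm.
#' @return an [FOVMask-class].
#' @export
fovMask <- function(mask, cutSide = "none", cutMM = 0) {
  storage.mode(mask) <- "double"
  new("FOVMask", mask = mask, cutSide = cutSide, cutMM = as.numeric(cutMM))
}

#' Construct a brain mask
#'
#' @param mask binary 3-D array.
#' @return a [BrainMask-class].
#' @export
brainMask <- function(mask) {
  storage.mode(mask) <- "double"
  new("BrainMask", mask = mask)
}

#' Construct a model bundle
#'
#' @param generators named list with keys \code{b0.sagittal},
#'   \code{b0.coronal}, \code{bweighted.sagittal}, \code{bweighted.coronal}.
#' @param meta list of training metadata (n, grid, lambda, seed, ...).
#' @return a [ModelBundle-class].
#' @export
modelBundle <- function(generators, meta = list()) {
  new("ModelBundle", generators = generators, meta = meta)
}
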