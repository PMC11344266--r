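#' @import methods
NULL

#' Gradient table for a diffusion-weighted study
#'
#' One b-value (s/mm^2) and one diffusion-encoding direction (b-vector) per
#' volume. Volumes with b-value at or below \code{b0Threshold} are treated as
#' unweighted (b0) references and carry a zero b-vector; all other volumes
#' carry a unit-norm b-vector.
#'
#' @slot bvals numeric vector of b-values, one per volume.
#' @slot bvecs 3 x V numeric matrix of gradient directions (columns).
#' @slot b0Threshold b-value (s/mm^2) below which a volume counts as b0.
#'   Real-world gradient tables jitter around 0, so a small threshold is used
#'   instead of exact zero.
#'
#' @seealso [gradientTable()] for the validating constructor.
#' @export
setClass("GradientTable",
  representation(bvals = "numeric", bvecs = "matrix", b0Threshold = "numeric"),
  prototype(bvals = numeric(0), bvecs = matrix(0, 3, 0), b0Threshold = 50)
)

setValidity("GradientTable", function(object) {
  msg <- character(0)
  if (nrow(object@bvecs) != 3)
    msg <- c(msg, "bvecs must have 3 rows")
  if (length(object@bvals) != ncol(object@bvecs))
    msg <- c(msg, "bvals length must equal the number of bvec columns")
  if (length(object@b0Threshold) != 1 || object@b0Threshold < 0)
    msg <- c(msg, "b0Threshold must be a single non-negative number")
  if (any(object@bvals < 0))
    msg <- c(msg, "b-values must be non-negative")
  if (length(object@bvals) > 0) {
    nrm <- sqrt(colSums(object@bvecs^2))
    wtd <- object@bvals > object@b0Threshold
    if (any(wtd) && any(abs(nrm[wtd] - 1) > 1e-3))
      msg <- c(msg, "weighted volumes must have unit-norm b-vectors (tol 1e-3)")
    if (any(!wtd) && any(nrm[!wtd] > 1e-12))
      msg <- c(msg, "b0 volumes must have zero b-vectors")
  }
  if (length(msg)) msg else TRUE
})

#' 4-D diffusion-weighted MRI study
#'
#' A stack of 3-D volumes indexed (x, y, z, v) with z the superior-inferior
#' (axial) axis and the axial slice index increasing toward superior, plus the
#' gradient table and voxel geometry.
#'
#' @slot data 4-D numeric array (x, y, z, volume).
#' @slot gradients a [GradientTable-class] with one entry per volume.
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#' @slot affine 4 x 4 voxel-to-world matrix (0-based voxel indices).
#'
#' @seealso [dwiStudy()], [readDWI()], [writeDWI()].
#' @export
setClass("DWIStudy",
  representation(data = "array", gradients = "GradientTable",
                 voxelSize = "numeric", affine = "matrix")
)

setValidity("DWIStudy", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 4)
    msg <- c(msg, "data must be a 4-D array")
  else if (dim(object@data)[4] != length(object@gradients@bvals))
    msg <- c(msg, "number of volumes must match the gradient table")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive lengths (mm)")
  if (!all(dim(object@affine) == c(4, 4)))
    msg <- c(msg, "affine must be 4 x 4")
  else if (abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be invertible")
  if (length(msg)) msg else TRUE
})

#' 3-D structural (T1-weighted-like) image
#'
#' The complete-FOV anatomical image that conditions the imputation. Must be
#' co-registered with the DWI study it accompanies (registration is consumed,
#' not computed, by this package).
#'
#' @slot data 3-D numeric array.
#' @slot voxelSize numeric length-3 (mm).
#' @slot affine 4 x 4 voxel-to-world matrix.
#' @export
setClass("StructuralImage",
  representation(data = "array", voxelSize = "numeric", affine = "matrix")
)

setValidity("StructuralImage", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3)
    msg <- c(msg, "data must be a 3-D array")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive lengths (mm)")
  if (!all(dim(object@affine) == c(4, 4)) || abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be an invertible 4 x 4 matrix")
  if (length(msg)) msg else TRUE
})

#' Normalized isotropic analysis grid
#'
#' The fixed grid all volumes are resampled onto before patch extraction:
#' isotropic voxels, axes (sagittal = x, coronal = y, axial = z). Images are
#' padded with zeros or centre-cropped to the grid shape.
#'
#' @slot shape integer length-3, grid extent in voxels.
#' @slot voxelSize single isotropic voxel edge length in mm.
#' @export
setClass("NormalizedGrid",
  representation(shape = "integer", voxelSize = "numeric")
)

setValidity("NormalizedGrid", function(object) {
  msg <- character(0)
  if (length(object@shape) != 3 || any(object@shape < 1))
    msg <- c(msg, "shape must be 3 positive integers")
  if (length(object@voxelSize) != 1 || object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a single positive length (isotropic)")
  if (length(msg)) msg else TRUE
})

#' Field-of-view mask
#'
#' Binary 3-D mask of acquired voxels (1 = acquired, 0 = missing). The missing
#' region, if any, is a set of complete axial slices contiguous in z,
#' adjacent to one z-extreme of the brain.
#'
#' @slot mask 3-D array of 0/1.
#' @slot cutSide one of "top", "bottom", "none".
#' @slot cutMM extent of the simulated cutoff in mm (0 when cutSide = "none").
#' @export
setClass("FOVMask",
  representation(mask = "array", cutSide = "character", cutMM = "numeric")
)

setValidity("FOVMask", function(object) {
  msg <- character(0)
  if (length(dim(object@mask)) != 3)
    msg <- c(msg, "mask must be a 3-D array")
  if (!all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask must be binary")
  if (!object@cutSide %in% c("top", "bottom", "none"))
    msg <- c(msg, "cutSide must be 'top', 'bottom' or 'none'")
  if (length(object@cutMM) != 1 || object@cutMM < 0)
    msg <- c(msg, "cutMM must be a single non-negative length")
  if (length(dim(object@mask)) == 3) {
    sliceMin <- apply(object@mask, 3, min)
    sliceMax <- apply(object@mask, 3, max)
    mixed <- sliceMin != sliceMax
    if (any(mixed))
      msg <- c(msg, "missing region must consist of complete axial slices")
    miss <- which(sliceMax == 0)
    if (length(miss) && any(diff(miss) != 1))
      msg <- c(msg, "missing axial slices must be contiguous")
    if (object@cutMM == 0 && length(miss))
      msg <- c(msg, "mask must be all ones when cutMM = 0")
  }
  if (length(msg)) msg else TRUE
})

#' Binary brain mask
#'
#' Restricts metric computation to brain voxels and locates the brain's
#' z-extent for cutoff simulation.
#'
#' @slot mask 3-D binary array, non-empty.
#' @export
setClass("BrainMask", representation(mask = "array"))

setValidity("BrainMask", function(object) {
  msg <- character(0)
  if (length(dim(object@mask)) != 3)
    msg <- c(msg, "mask must be a 3-D array")
  if (!all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask must be binary")
  if (sum(object@mask) == 0)
    msg <- c(msg, "brain mask must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Bundle of the four trained generators
#'
#' One generator per (shell group, view) pair: (b0, sagittal), (b0, coronal),
#' (bweighted, sagittal), (bweighted, coronal). All four must be present
#' before inference; each is trained only on its own shell group and view.
#'
#' @slot generators named list with exactly the four keys
#'   \code{b0.sagittal}, \code{b0.coronal}, \code{bweighted.sagittal},
#'   \code{bweighted.coronal}.
#' @slot meta list of training metadata (n, grid, lambda, seed, normalization
#'   convention).
#' @export
setClass("ModelBundle", representation(generators = "list", meta = "list"))

bundleKeys <- c("b0.sagittal", "b0.coronal",
                "bweighted.sagittal", "bweighted.coronal")

setValidity("ModelBundle", function(object) {
  msg <- character(0)
  if (!setequal(names(object@generators), bundleKeys))
    msg <- c(msg, paste("generators must be named exactly:",
                        paste(bundleKeys, collapse = ", ")))
  if (any(vapply(object@generators, is.null, logical(1))))
    msg <- c(msg, "all four generators must be present")
  if (length(msg)) msg else TRUE
})

#' 2.5D patch sample
#'
#' One training/inference unit: the first (2n+1) channels of \code{input} are
#' DWI slices i-n .. i+n in the chosen view, the next (2n+1) channels the
#' structural slices at identical spatial indices; \code{target} is the
#' uncorrupted DWI slice i.
#'
#' @slot input H x W x 2(2n+1) array.
#' @slot target H x W matrix.
#' @slot view "sagittal" or "coronal" (the axial view is never used).
#' @slot sliceIndex 1-based slice index i along the view axis.
#' @slot shellGroup "b0", "bweighted" or "" when not routed yet.
#' @export
setClass("PatchSample",
  representation(input = "array", target = "matrix", view = "character",
                 sliceIndex = "integer", shellGroup = "character")
)

setValidity("PatchSample", function(object) {
  msg <- character(0)
  d <- dim(object@input)
  if (length(d) != 3)
    msg <- c(msg, "input must be H x W x C")
  else {
    if (d[3] %% 2 != 0 || ((d[3] / 2) %% 2) != 1)
      msg <- c(msg, "channel count must equal 2*(2n+1)")
    if (!all(d[1:2] == dim(object@target)))
      msg <- c(msg, "target spatial shape must match input")
  }
  if (!object@view %in% c("sagittal", "coronal"))
    msg <- c(msg, "view must be 'sagittal' or 'coronal'")
  if (length(msg)) msg else TRUE
})
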