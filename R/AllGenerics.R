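#' Accessors for dwifov data classes
#'
#' Small accessor generics in the Bioconductor style: user code should use
#' these rather than reaching into slots.
#'
#' @param x a dwifov object.
#' @return the corresponding component (see details per method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dwiData", function(x) standardGeneric("dwiData"))

#' @rdname accessors
#' @export
setGeneric("gradients", function(x) standardGeneric("gradients"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))

#' @rdname accessors
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' @rdname accessors
#' @export
setGeneric("bVectors", function(x) standardGeneric("bVectors"))

#' @rdname accessors
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname accessors
#' @export
setGeneric("generators", function(x) standardGeneric("generators"))

#' Volume indices by shell group
#'
#' Partitions the volumes of a study (or entries of a gradient table) into the
#' b0 group (b-value at or below the b0 threshold) and the diffusion-weighted
#' group.
#'
#' @param x a [DWIStudy-class] or [GradientTable-class].
#' @return named list with integer index vectors \code{$b0} and
#'   \code{$bweighted}.
#' @export
setGeneric("volumeGroups", function(x) standardGeneric("volumeGroups"))

#' @rdname accessors
setMethod("dwiData", "DWIStudy", function(x) x@data)
#' @rdname accessors
setMethod("dwiData", "StructuralImage", function(x) x@data)
#' @rdname accessors
setMethod("gradients", "DWIStudy", function(x) x@gradients)
#' @rdname accessors
setMethod("voxelSize", "DWIStudy", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "StructuralImage", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "NormalizedGrid", function(x) x@voxelSize)
#' @rdname accessors
setMethod("affineMatrix", "DWIStudy", function(x) x@affine)
#' @rdname accessors
setMethod("affineMatrix", "StructuralImage", function(x) x@affine)
#' @rdname accessors
setMethod("bValues", "GradientTable", function(x) x@bvals)
#' @rdname accessors
setMethod("bValues", "DWIStudy", function(x) x@gradients@bvals)
#' @rdname accessors
setMethod("bVectors", "GradientTable", function(x) x@bvecs)
#' @rdname accessors
setMethod("bVectors", "DWIStudy", function(x) x@gradients@bvecs)
#' @rdname accessors
setMethod("nVolumes", "GradientTable", function(x) length(x@bvals))
#' @rdname accessors
setMethod("nVolumes", "DWIStudy", function(x) dim(x@data)[4])
#' @rdname accessors
setMethod("maskArray", "FOVMask", function(x) x@mask)
#' @rdname accessors
setMethod("maskArray", "BrainMask", function(x) x@mask)
#' @rdname accessors
setMethod("gridShape", "NormalizedGrid", function(x) x@shape)
#' @rdname accessors
setMethod("generators", "ModelBundle", function(x) x@generators)

setMethod("volumeGroups", "GradientTable", function(x) {
  b0 <- which(x@bvals <= x@b0Threshold)
  list(b0 = b0, bweighted = setdiff(seq_along(x@bvals), b0))
})
setMethod("volumeGroups", "DWIStudy", function(x) volumeGroups(x@gradients))

setMethod("show", "GradientTable", function(object) {
  g <- volumeGroups(object)
  cat("GradientTable:", length(object@bvals), "volumes (",
      length(g$b0), "b0,", length(g$bweighted), "weighted )\n")
  if (length(g$bweighted))
    cat("  shell b-values:",
        paste(unique(round(object@bvals[g$bweighted])), collapse = ", "),
        "s/mm^2\n")
})

setMethod("show", "DWIStudy", function(object) {
  d <- dim(object@data)
  cat(sprintf("DWIStudy: %d x %d x %d voxels, %d volumes\n",
              d[1], d[2], d[3], d[4]))
  cat("  voxel size:", paste(signif(object@voxelSize, 4), collapse = " x "),
      "mm\n")
  show(object@gradients)
})

setMethod("show", "StructuralImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("StructuralImage: %d x %d x %d voxels, voxel %s mm\n",
              d[1], d[2], d[3],
              paste(signif(object@voxelSize, 4), collapse = " x ")))
})

setMethod("show", "NormalizedGrid", function(object) {
  cat(sprintf("NormalizedGrid: %s voxels @ %g mm isotropic\n",
              paste(object@shape, collapse = " x "), object@voxelSize))
})

setMethod("show", "FOVMask", function(object) {
  miss <- sum(apply(object@mask, 3, max) == 0)
  cat(sprintf("FOVMask: %s, cut %s / %g mm, %d missing axial slice(s)\n",
              paste(dim(object@mask), collapse = " x "),
              object@cutSide, object@cutMM, miss))
})

setMethod("show", "ModelBundle", function(object) {
  cat("ModelBundle with generators:",
      paste(names(object@generators), collapse = ", "), "\n")
  if (!is.null(object@meta$n))
    cat("  neighbourhood half-width n =", object@meta$n, "\n")
})

setMethod("show", "PatchSample", function(object) {
  d <- dim(object@input)
  cat(sprintf("PatchSample: %d x %d, %d channels, %s slice %d (%s)\n",
              d[1], d[2], d[3], object@view, object@sliceIndex,
              if (nzchar(object@shellGroup)) object@shellGroup else "unrouted"))
})
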