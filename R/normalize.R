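#' Intensity normalization parameters
#'
#' The normalization maps raw intensities to [0, 1] by dividing by the 99.9th
#' percentile of the study's intensities and clipping; the floor is 0. All
#' volumes of one DWI study share a single set of parameters, so relative
#' signal attenuation across volumes is preserved. A structural image gets
#' its own parameters.
#'
#' @param study a [DWIStudy-class], [StructuralImage-class] or bare array.
#' @param percentile upper percentile defining the scale (default 0.999).
#' @param excludeZeros if TRUE, background zeros are excluded before taking
#'   the percentile. Default FALSE: the percentile is taken over all voxels.
#' @return list with elements \code{scale} (positive) and \code{floor} (0).
#' @export
computeNormalization <- function(study, percentile = 0.999,
                                 excludeZeros = FALSE) {
  x <- if (is(study, "DWIStudy") || is(study, "StructuralImage"))
    study@data else study
  x <- as.numeric(x)
  if (!length(x)) stop("empty study")
  if (excludeZeros) {
    x <- x[x != 0]
    if (!length(x)) stop("degenerate normalization: all voxels are zero")
  }
  scale <- stats::quantile(x, percentile, names = FALSE, type = 7)
  if (!is.finite(scale) || scale <= 0)
    stop("degenerate normalization scale: ", scale)
  list(scale = scale, floor = 0)
}

#' Apply / invert intensity normalization
#'
#' \code{applyNormalization} maps to [0, 1] via \code{clip(x / scale, 0, 1)};
#' \code{invertNormalization} multiplies back by the scale (exact on the
#' non-clipped range).
#'
#' @param volume numeric array.
#' @param params list from [computeNormalization()].
#' @return array of the same shape.
#' @export
applyNormalization <- function(volume, params) {
  if (params$scale <= 0) stop("normalization scale must be positive")
  pmin(pmax(volume / params$scale, 0), 1)
}

#' @rdname applyNormalization
#' @export
invertNormalization <- function(volume, params) volume * params$scale

#' Brain mask by median filtering + Otsu thresholding
#'
#' Computes a simple brain mask from an intensity volume (typically the mean
#' b0): slice-wise median filtering to suppress speckle, a global Otsu
#' threshold, then retention of the largest 6-connected component. This
#' stands in for atlas-based masking; it is adequate for phantoms and for
#' restricting metrics to tissue.
#'
#' @param volume 3-D intensity array.
#' @param medianRadius radius of the median filter (voxels); 0 disables.
#' @return a [BrainMask-class].
#' @export
computeBrainMask <- function(volume, medianRadius = 1) {
  stopIfNot3D(volume, "volume")
  rng <- range(volume)
  if (diff(rng) <= 0)
    stop("brain masking failed: constant-valued volume")
  v <- (volume - rng[1]) / diff(rng)
  if (medianRadius > 0)
    v <- EBImage::medianFilter(v, size = medianRadius)
  # global Otsu threshold: flatten to one frame so EBImage treats the whole
  # volume as a single image
  th <- EBImage::otsu(matrix(v, nrow = dim(v)[1]), range = c(0, 1))
  m <- array(as.numeric(v > th), dim = dim(v))
  if (sum(m) == 0)
    stop("brain masking failed: empty mask after thresholding")
  brainMask(largestComponent(m))
}

# Largest 6-connected component of a binary 3-D array, by vectorized label
# propagation (each voxel takes the max label among itself and its in-mask
# face neighbours until convergence).
largestComponent <- function(m) {
  d <- dim(m)
  lab <- array(seq_len(prod(d)), dim = d) * m
  shift <- function(a, axis, by) {
    out <- array(0, dim = d)
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    n <- d[axis]
    if (by == 1) { src[[axis]] <- 1:(n - 1); dst[[axis]] <- 2:n }
    else { src[[axis]] <- 2:n; dst[[axis]] <- 1:(n - 1) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  repeat {
    nxt <- lab
    for (axis in 1:3) for (by in c(1, -1))
      nxt <- pmax(nxt, shift(lab, axis, by))
    nxt <- nxt * m
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  tab <- table(lab[lab > 0])
  keep <- as.numeric(names(tab)[which.max(tab)])
  array(as.numeric(lab == keep), dim = d)
}

#' Simulate a field-of-view cutoff
#'
#' Zero-fills the k = round(cutMM / voxel) axial slices adjacent to the
#' brain's superior ("top") or inferior ("bottom") boundary in every volume,
#' and returns the FOV mask marking them missing. Shapes are unchanged: the
#' cutoff is represented by zero-filling plus the mask, not by shrinking
#' arrays. Ties in the slice count round half away from zero.
#'
#' @param study a [DWIStudy-class] on the normalized grid.
#' @param brain a [BrainMask-class] locating the brain's z-extent.
#' @param cutMM cutoff extent in mm, in [0, maxCutMM].
#' @param cutSide "top" or "bottom".
#' @param maxCutMM largest admissible cutoff (default 50 mm).
#' @return list with \code{study} (truncated copy) and \code{fov}
#'   ([FOVMask-class]).
#' @export
simulateCutoff <- function(study, brain, cutMM, cutSide = c("top", "bottom"),
                           maxCutMM = 50) {
  cutSide <- match.arg(cutSide)
  if (cutMM < 0 || cutMM > maxCutMM)
    stop("cutMM must lie in [0, ", maxCutMM, "]")
  d <- dim(study@data)
  vz <- study@voxelSize[3]
  k <- as.integer(roundHalfAway(cutMM / vz))
  ext <- maskExtent(brain@mask, 3)
  if (k > ext[2] - ext[1] + 1)
    stop("cutoff of ", k, " slices exceeds the brain extent (",
         ext[2] - ext[1] + 1, " slices)")
  mask <- array(1, dim = d[1:3])
  if (k > 0) {
    zs <- if (cutSide == "top") (ext[2] - k + 1):ext[2]
          else ext[1]:(ext[1] + k - 1)
    mask[, , zs] <- 0
    study@data[, , zs, ] <- 0
  }
  list(study = study,
       fov = fovMask(mask, cutSide = if (k > 0) cutSide else "none",
                     cutMM = if (k > 0) cutMM else 0))
}

# Single-volume variant used inside the training loop (avoids copying the
# whole 4-D study per step).
truncateVolume <- function(vol, brainExtentZ, k, cutSide) {
  if (k > 0) {
    zs <- if (cutSide == "top") (brainExtentZ[2] - k + 1):brainExtentZ[2]
          else brainExtentZ[1]:(brainExtentZ[1] + k - 1)
    vol[, , zs] <- 0
  }
  vol
}

#' Recombine acquired and imputed data
#'
#' The final output of the pipeline is \code{m * acquired + (1 - m) *
#' imputed}: acquired voxels pass through bit-identically, imputed voxels
#' fill the missing region only.
#'
#' @param acquired,imputed 3-D arrays of one shape.
#' @param fov an [FOVMask-class] of the same shape.
#' @return 3-D array.
#' @export
recombine <- function(acquired, imputed, fov) {
  m <- fov@mask
  if (!all(dim(acquired) == dim(m)) || !all(dim(imputed) == dim(m)))
    stop("acquired, imputed and fov mask must share one shape")
  out <- imputed
  sel <- m == 1
  out[sel] <- acquired[sel]
  out
}

#' Derive an FOV mask from a truncated study
#'
#' Locates runs of all-zero axial slices adjacent to the brain's z-extremes
#' and marks them missing. Used when a study arrives without an explicit FOV
#' mask. Slices are considered empty when they contain no voxel above
#' \code{tol} within any volume.
#'
#' @param study a [DWIStudy-class].
#' @param brain a [BrainMask-class] for the expected brain extent (from the
#'   structural image, whose FOV is complete).
#' @param tol intensity below which a voxel counts as empty.
#' @return an [FOVMask-class].
#' @export
deriveFOVMask <- function(study, brain, tol = 1e-8) {
  d <- dim(study@data)
  sliceMax <- apply(study@data, 3, max)
  empty <- sliceMax <= tol
  ext <- maskExtent(brain@mask, 3)
  mask <- array(1, dim = d[1:3])
  vz <- study@voxelSize[3]
  # top run: empty slices descending from the brain's superior boundary
  topRun <- 0
  for (z in ext[2]:ext[1]) { if (empty[z]) topRun <- topRun + 1 else break }
  botRun <- 0
  for (z in ext[1]:ext[2]) { if (empty[z]) botRun <- botRun + 1 else break }
  if (topRun >= botRun && topRun > 0) {
    mask[, , (ext[2] - topRun + 1):ext[2]] <- 0
    return(fovMask(mask, "top", topRun * vz))
  }
  if (botRun > 0) {
    mask[, , ext[1]:(ext[1] + botRun - 1)] <- 0
    return(fovMask(mask, "bottom", botRun * vz))
  }
  fovMask(mask, "none", 0)
}
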