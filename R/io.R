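#' Read a 4-D diffusion-weighted study
#'
#' Reads a 4-D NIfTI volume together with its FSL-style gradient table
#' (\code{.bval}: one row of b-values; \code{.bvec}: 3 rows x V columns).
#' B-vectors of diffusion-weighted volumes are renormalized to unit length
#' (warning when the stored norm is off by more than 1e-3).
#'
#' @param imagePath path to a .nii or .nii.gz file with 4 dimensions.
#' @param bvalPath,bvecPath paths to the FSL gradient table files.
#' @param b0Threshold b-value (s/mm^2) separating b0 from weighted volumes.
#' @return a [DWIStudy-class].
#' @export
readDWI <- function(imagePath, bvalPath, bvecPath, b0Threshold = 50) {
  img <- RNifti::readNifti(imagePath)
  d <- dim(img)
  if (length(d) != 4)
    stop("expected a 4-D NIfTI image, got ", length(d), " dimensions")
  bvals <- scan(bvalPath, quiet = TRUE)
  bvecs <- as.matrix(utils::read.table(bvecPath))
  dimnames(bvecs) <- NULL
  if (nrow(bvecs) != 3)
    stop("bvec file must have 3 rows (FSL layout), got ", nrow(bvecs))
  if (length(bvals) != d[4] || ncol(bvecs) != d[4])
    stop("gradient table does not match image: image has ", d[4],
         " volumes, bval has ", length(bvals), ", bvec has ", ncol(bvecs))
  vox <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  dwiStudy(array(as.numeric(img), dim = d),
           gradientTable(bvals, bvecs, b0Threshold),
           voxelSize = vox, affine = aff)
}

#' Read a 3-D structural image
#'
#' @param imagePath path to a 3-D NIfTI file.
#' @return a [StructuralImage-class].
#' @export
readStructural <- function(imagePath) {
  img <- RNifti::readNifti(imagePath)
  d <- dim(img)
  if (length(d) != 3)
    stop("expected a 3-D NIfTI image, got ", length(d), " dimensions")
  structuralImage(array(as.numeric(img), dim = d),
                  voxelSize = RNifti::pixdim(img)[1:3],
                  affine = unclass(RNifti::xform(img))[1:4, 1:4])
}

niftiFromArray <- function(data, voxelSize, affine) {
  img <- RNifti::asNifti(data)
  nd <- length(dim(data))
  RNifti::pixdim(img) <- c(voxelSize, rep(1, max(0, nd - 3)))
  aff <- structure(affine, code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  img
}

#' Write a DWI study as NIfTI plus FSL gradient table
#'
#' Intensities are stored as 32-bit float; the gradient table is written with
#' full double precision so that a read/write round trip reproduces b-values
#' and b-vectors exactly.
#'
#' @param study a [DWIStudy-class].
#' @param imagePath output .nii or .nii.gz path.
#' @param bvalPath,bvecPath output gradient table paths.
#' @param datatype NIfTI storage type (default "float").
#' @return invisibly, the three paths.
#' @export
writeDWI <- function(study, imagePath, bvalPath, bvecPath,
                     datatype = "float") {
  img <- niftiFromArray(study@data, study@voxelSize, study@affine)
  RNifti::writeNifti(img, imagePath, datatype = datatype)
  writeGradientTable(study@gradients, bvalPath, bvecPath)
  invisible(c(imagePath, bvalPath, bvecPath))
}

#' Write a structural image as NIfTI
#'
#' @param image a [StructuralImage-class].
#' @param imagePath output path.
#' @param datatype NIfTI storage type.
#' @return invisibly, the path.
#' @export
writeStructural <- function(image, imagePath, datatype = "float") {
  img <- niftiFromArray(image@data, image@voxelSize, image@affine)
  RNifti::writeNifti(img, imagePath, datatype = datatype)
  invisible(imagePath)
}

#' Write / read gradient tables in FSL layout
#'
#' @param gt a [GradientTable-class].
#' @param bvalPath,bvecPath file paths.
#' @return \code{writeGradientTable}: invisibly the paths;
#'   \code{readGradientTable}: a [GradientTable-class].
#' @export
writeGradientTable <- function(gt, bvalPath, bvecPath) {
  writeLines(paste(sprintf("%.17g", gt@bvals), collapse = " "), bvalPath)
  writeLines(apply(gt@bvecs, 1,
                   function(r) paste(sprintf("%.17g", r), collapse = " ")),
             bvecPath)
  invisible(c(bvalPath, bvecPath))
}

#' @rdname writeGradientTable
#' @param b0Threshold see [gradientTable()].
#' @export
readGradientTable <- function(bvalPath, bvecPath, b0Threshold = 50) {
  bvals <- scan(bvalPath, quiet = TRUE)
  bvecs <- as.matrix(utils::read.table(bvecPath))
  dimnames(bvecs) <- NULL
  gradientTable(bvals, bvecs, b0Threshold)
}

#' Read / write binary masks as integer NIfTI
#'
#' @param path NIfTI path.
#' @return \code{readMaskImage}: a binary 3-D array with \code{voxelSize} and
#'   \code{affine} attributes.
#' @export
readMaskImage <- function(path) {
  img <- RNifti::readNifti(path)
  m <- array(as.numeric(img) > 0.5, dim = dim(img)) * 1
  attr(m, "voxelSize") <- RNifti::pixdim(img)[1:3]
  attr(m, "affine") <- unclass(RNifti::xform(img))[1:4, 1:4]
  m
}

#' @rdname readMaskImage
#' @param mask binary 3-D array.
#' @param voxelSize,affine geometry to stamp on the output.
#' @export
writeMaskImage <- function(mask, path, voxelSize = c(1, 1, 1),
                           affine = NULL) {
  if (is.null(affine)) affine <- diag(c(voxelSize, 1))
  img <- niftiFromArray(array(as.numeric(mask > 0.5), dim = dim(mask)),
                        voxelSize, affine)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' World-aligned affine of a normalized grid
#'
#' The normalized grid is axis-aligned in world space with isotropic spacing;
#' its translation is chosen so that the grid centre coincides with the world
#' position of the reference image centre. Padding and cropping are therefore
#' centred, and all images of one study share a single grid frame when the
#' same reference is used.
#'
#' @param grid a [NormalizedGrid-class].
#' @param refShape integer length-3 shape of the reference image.
#' @param refAffine 4 x 4 voxel-to-world matrix of the reference image.
#' @return 4 x 4 grid voxel-to-world matrix.
#' @export
gridAffine <- function(grid, refShape, refAffine) {
  ctrWorld <- (refAffine %*% c((refShape - 1) / 2, 1))[1:3]
  v <- grid@voxelSize
  t <- ctrWorld - v * (grid@shape - 1) / 2
  a <- diag(c(v, v, v, 1))
  a[1:3, 4] <- t
  a
}

#' Resample a volume onto the normalized grid
#'
#' Maps every grid voxel through the grid affine into the source image's voxel
#' space and interpolates. Voxels that fall outside the source image are
#' filled with 0, so padding to a larger grid is zero-filled and cropping is
#' centred. [resampleFromGrid()] is the inverse operation back to subject
#' geometry.
#'
#' @param volume 3-D array in subject space.
#' @param affine 4 x 4 voxel-to-world matrix of \code{volume}.
#' @param grid a [NormalizedGrid-class].
#' @param gridAff optional grid affine; defaults to [gridAffine()] computed
#'   from \code{volume} itself. Pass a shared value to keep several images of
#'   one study in a common frame.
#' @param interpolation "linear" (intensities) or "nearest" (masks/labels).
#' @return 3-D array of shape \code{gridShape(grid)}.
#' @export
resampleToGrid <- function(volume, affine, grid, gridAff = NULL,
                           interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopIfNot3D(volume, "volume")
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  if (is.null(gridAff)) gridAff <- gridAffine(grid, dim(volume), affine)
  resampleBetween(volume, affine, grid@shape, gridAff, interpolation)
}

#' @rdname resampleToGrid
#' @param gridVolume 3-D array on the grid.
#' @param targetShape,targetAffine subject-space geometry to map back to.
#' @export
resampleFromGrid <- function(gridVolume, grid, gridAff, targetShape,
                             targetAffine,
                             interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopIfNot3D(gridVolume, "gridVolume")
  resampleBetween(gridVolume, gridAff, targetShape, targetAffine,
                  interpolation)
}

# Sample `src` (with srcAffine) at the voxel centres of a target raster.
# Chunked by target z-slice to bound memory on large grids.
resampleBetween <- function(src, srcAffine, dstShape, dstAffine,
                            interpolation) {
  map <- solve(srcAffine) %*% dstAffine
  out <- array(0, dim = dstShape)
  xy <- cbind(as.matrix(expand.grid(x = 0:(dstShape[1] - 1),
                                    y = 0:(dstShape[2] - 1))), z = 0, h = 1)
  sampler <- if (interpolation == "linear") sampleTrilinear else sampleNearest
  for (z in 0:(dstShape[3] - 1)) {
    xy[, 3] <- z
    srcCoords <- map %*% t(xy)
    out[, , z + 1] <- sampler(src, srcCoords[1:3, , drop = FALSE])
  }
  out
}
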