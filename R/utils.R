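# Internal helpers shared across modules.

# round() in R rounds half to even; cutoff slice counts need half away from
# zero so that e.g. 2.5 mm at 1 mm voxels always removes 3 slices.
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

viewAxis <- function(view) {
  switch(view,
         sagittal = 1L,
         coronal = 2L,
         axial = stop("the axial view is not supported for 2.5D modelling"),
         stop("unknown view: ", view))
}

# Extract slice i (1-based) of a 3-D volume perpendicular to `axis`,
# zero-filled when i is out of range (neighbour slices beyond the volume).
getSliceZero <- function(vol, axis, i) {
  d <- dim(vol)
  sliceDim <- d[-axis]
  if (i < 1 || i > d[axis]) return(matrix(0, sliceDim[1], sliceDim[2]))
  switch(axis, vol[i, , ], vol[, i, ], vol[, , i])
}

setSlice <- function(vol, axis, i, slice) {
  switch(axis,
         vol[i, , ] <- slice,
         vol[, i, ] <- slice,
         vol[, , i] <- slice)
  vol
}

# Bounding box of a binary mask along one axis: c(min, max) 1-based indices.
maskExtent <- function(mask, axis) {
  pres <- apply(mask, axis, function(s) any(s > 0))
  idx <- which(pres)
  if (!length(idx)) stop("mask is empty along axis ", axis)
  c(min(idx), max(idx))
}

# Trilinear sampling of `vol` at 0-based voxel coordinates (columns of a
# 3 x N matrix). Coordinates outside the volume contribute zero.
sampleTrilinear <- function(vol, coords) {
  d <- dim(vol)
  x <- coords[1, ]; y <- coords[2, ]; z <- coords[3, ]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- numeric(length(x))
  corner <- function(ix, iy, iz) {
    inb <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 &
      iz >= 0 & iz <= d[3] - 1
    v <- numeric(length(ix))
    if (any(inb)) {
      lin <- ix[inb] + d[1] * (iy[inb] + d[2] * iz[inb]) + 1
      v[inb] <- vol[lin]
    }
    v
  }
  out <- corner(x0,     y0,     z0)     * (1 - fx) * (1 - fy) * (1 - fz) +
         corner(x0 + 1, y0,     z0)     * fx       * (1 - fy) * (1 - fz) +
         corner(x0,     y0 + 1, z0)     * (1 - fx) * fy       * (1 - fz) +
         corner(x0 + 1, y0 + 1, z0)     * fx       * fy       * (1 - fz) +
         corner(x0,     y0,     z0 + 1) * (1 - fx) * (1 - fy) * fz +
         corner(x0 + 1, y0,     z0 + 1) * fx       * (1 - fy) * fz +
         corner(x0,     y0 + 1, z0 + 1) * (1 - fx) * fy       * fz +
         corner(x0 + 1, y0 + 1, z0 + 1) * fx       * fy       * fz
  out
}

# Nearest-neighbour sampling at 0-based voxel coordinates; zero outside.
sampleNearest <- function(vol, coords) {
  d <- dim(vol)
  ix <- round(coords[1, ]); iy <- round(coords[2, ]); iz <- round(coords[3, ])
  inb <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 &
    iz >= 0 & iz <= d[3] - 1
  out <- numeric(ncol(coords))
  if (any(inb))
    out[inb] <- vol[ix[inb] + d[1] * (iy[inb] + d[2] * iz[inb]) + 1]
  out
}

# Derive a seed stream: deterministic child seeds below 2^31 from one master.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %%
               2147483629)
}

stopIfNot3D <- function(x, what) {
  if (length(dim(x)) != 3) stop(what, " must be a 3-D array")
  invisible(x)
}
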