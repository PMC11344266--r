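#' Specification of a synthetic diffusion phantom
#'
#' The phantom is a nested-ellipsoid "head": a background of zeros, an outer
#' CSF shell, a gray-matter shell and a white-matter core, each with its own
#' unattenuated signal S0, structural (T1w-like) intensity and diffusion
#' tensor. White matter carries a prolate tensor whose principal axis
#' follows a smooth swirl field, so diffusion-weighted contrast depends on
#' the gradient direction. DWI signals follow the tensor model
#' \code{S = S0 * exp(-b * g' D g)} with Rician magnitude noise; the
#' structural channel has distinct per-compartment contrast with independent
#' noise, correlated with but different from the DWI contrast.
#'
#' @param shape grid extent in voxels (default 48^3, the desk-scale grid).
#' @param voxelMM isotropic voxel size in mm.
#' @param nB0 number of b = 0 volumes.
#' @param nDir number of diffusion-weighted directions (golden-spiral layout
#'   on the hemisphere).
#' @param bValue shell b-value in s/mm^2 (default 1300).
#' @param sigma Rician noise sigma relative to the maximum S0 (default 0.02;
#'   0 disables noise).
#' @param sigmaT1 structural-channel noise sigma.
#' @param axesFrac outer-ellipsoid semi-axes as fractions of the grid shape.
#' @param grayFrac,whiteFrac nesting radii of the gray shell and white core
#'   (fractions of the outer ellipsoid).
#' @param S0 named vector of unattenuated signals per compartment.
#' @param t1Contrast named vector of structural intensities per compartment.
#' @param adcIso named vector: isotropic diffusivities (mm^2/s) of csf and
#'   gray compartments.
#' @param whiteEigen eigenvalues (mm^2/s) of the prolate white-matter tensor.
#' @param jitterAxes,jitterRot geometric jitter (relative axis scale, max
#'   rotation in radians) drawn per case.
#' @param seed RNG seed; the phantom is fully determined by it.
#' @return list of class \code{dwifovPhantomSpec}.
#' @export
phantomSpec <- function(shape = c(48L, 48L, 48L), voxelMM = 1, nB0 = 1,
                        nDir = 6, bValue = 1300, sigma = 0.02,
                        sigmaT1 = 0.02,
                        axesFrac = c(0.42, 0.40, 0.38),
                        grayFrac = 0.85, whiteFrac = 0.55,
                        S0 = c(csf = 1.0, gray = 0.75, white = 0.62),
                        t1Contrast = c(csf = 0.15, gray = 0.60,
                                       white = 0.95),
                        adcIso = c(csf = 3.0e-3, gray = 0.8e-3),
                        whiteEigen = c(1.7e-3, 0.2e-3, 0.2e-3),
                        jitterAxes = 0.08, jitterRot = 0.15, seed = 1) {
  if (whiteFrac <= 0 || whiteFrac >= grayFrac || grayFrac >= 1)
    stop("compartments must nest: 0 < whiteFrac < grayFrac < 1")
  if (nDir < 1 || nB0 < 1) stop("need at least one b0 and one direction")
  structure(as.list(environment()), class = "dwifovPhantomSpec")
}

# well-spread unit directions on the upper hemisphere (golden spiral)
goldenSpiralDirections <- function(n) {
  i <- seq_len(n)
  z <- (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  rbind(r * cos(phi), r * sin(phi), z)
}

rotationMatrix <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Generate one synthetic phantom case
#'
#' Fully determined by \code{spec$seed}: geometry jitter, noise draws and
#' gradient scheme reproduce exactly for the same spec.
#'
#' @param spec a [phantomSpec()].
#' @return list with \code{dwi} ([DWIStudy-class]), \code{t1}
#'   ([StructuralImage-class]), \code{brain} (ground-truth
#'   [BrainMask-class]) and \code{tensors} (X x Y x Z x 6 array of tensor
#'   components xx, yy, zz, xy, xz, yz in mm^2/s).
#' @export
generatePhantom <- function(spec) {
  if (!inherits(spec, "dwifovPhantomSpec")) stop("spec must be a phantomSpec")
  set.seed(spec$seed)
  d <- as.integer(spec$shape)
  ctr <- (d + 1) / 2
  axes <- spec$axesFrac * d *
    stats::runif(3, 1 - spec$jitterAxes, 1 + spec$jitterAxes)
  R <- rotationMatrix(stats::runif(1, -spec$jitterRot, spec$jitterRot),
                      stats::runif(1, -spec$jitterRot, spec$jitterRot),
                      stats::runif(1, -spec$jitterRot, spec$jitterRot))
  g <- expand.grid(x = seq_len(d[1]) - ctr[1],
                   y = seq_len(d[2]) - ctr[2],
                   z = seq_len(d[3]) - ctr[3])
  u <- t(R) %*% t(as.matrix(g))                  # rotate into ellipsoid frame
  rho <- sqrt((u[1, ] / axes[1])^2 + (u[2, ] / axes[2])^2 +
                (u[3, ] / axes[3])^2)
  comp <- integer(length(rho))                   # 0 bg, 1 csf, 2 gray, 3 white
  comp[rho <= 1] <- 1L
  comp[rho <= spec$grayFrac] <- 2L
  comp[rho <= spec$whiteFrac] <- 3L
  inBrain <- comp > 0
  S0f <- c(0, spec$S0["csf"], spec$S0["gray"], spec$S0["white"])[comp + 1]
  t1f <- c(0, spec$t1Contrast["csf"], spec$t1Contrast["gray"],
           spec$t1Contrast["white"])[comp + 1]
  # tensor field: iso in csf/gray, prolate swirl in white
  Dxx <- Dyy <- Dzz <- Dxy <- Dxz <- Dyz <- numeric(length(comp))
  iso <- c(0, spec$adcIso["csf"], spec$adcIso["gray"], 0)[comp + 1]
  Dxx <- Dyy <- Dzz <- iso
  wm <- comp == 3L
  if (any(wm)) {
    lam <- spec$whiteEigen
    ex <- -g$y[wm]; ey <- g$x[wm]
    ez <- 0.3 * axes[3] * sin(2 * pi * g$z[wm] / d[3])
    nrm <- sqrt(ex^2 + ey^2 + ez^2)
    degen <- nrm < 1e-6
    ex[degen] <- 1; ey[degen] <- 0; ez[degen] <- 0; nrm[degen] <- 1
    ex <- ex / nrm; ey <- ey / nrm; ez <- ez / nrm
    dl <- lam[1] - lam[2]
    Dxx[wm] <- lam[2] + dl * ex^2
    Dyy[wm] <- lam[2] + dl * ey^2
    Dzz[wm] <- lam[2] + dl * ez^2
    Dxy[wm] <- dl * ex * ey
    Dxz[wm] <- dl * ex * ez
    Dyz[wm] <- dl * ey * ez
  }
  dirs <- goldenSpiralDirections(spec$nDir)
  V <- spec$nB0 + spec$nDir
  bvals <- c(rep(0, spec$nB0), rep(spec$bValue, spec$nDir))
  bvecs <- cbind(matrix(0, 3, spec$nB0), dirs)
  nvox <- prod(d)
  data <- array(0, dim = c(d, V))
  for (v in seq_len(V)) {
    if (bvals[v] == 0) {
      S <- S0f
    } else {
      gv <- bvecs[, v]
      q <- gv[1]^2 * Dxx + gv[2]^2 * Dyy + gv[3]^2 * Dzz +
        2 * (gv[1] * gv[2] * Dxy + gv[1] * gv[3] * Dxz +
               gv[2] * gv[3] * Dyz)
      S <- S0f * exp(-bvals[v] * q)
    }
    if (spec$sigma > 0) {
      s <- spec$sigma * max(spec$S0)
      S <- sqrt((S + stats::rnorm(nvox, 0, s))^2 +
                  stats::rnorm(nvox, 0, s)^2)
    }
    data[, , , v] <- S
  }
  t1 <- t1f
  if (spec$sigmaT1 > 0) {
    s <- spec$sigmaT1 * max(spec$t1Contrast)
    t1 <- sqrt((t1 + stats::rnorm(nvox, 0, s))^2 +
                 stats::rnorm(nvox, 0, s)^2)
  }
  tensors <- array(c(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), dim = c(d, 6))
  vox <- rep(spec$voxelMM, 3)
  list(dwi = dwiStudy(data, gradientTable(bvals, bvecs), voxelSize = vox),
       t1 = structuralImage(array(t1, dim = d), voxelSize = vox),
       brain = brainMask(array(as.numeric(inBrain), dim = d)),
       tensors = tensors)
}

#' Generate a phantom dataset on disk
#'
#' Writes train/val/test splits of phantom cases, each in its own
#' subdirectory with NIfTI images, FSL gradient table and ground-truth files
#' (brain mask and tensor field as NIfTI). Per-case seeds are derived
#' deterministically from the master seed, and geometry jitter varies across
#' cases, so the same master seed regenerates an identical dataset.
#'
#' @param spec a [phantomSpec()]; its seed is overridden per case.
#' @param nTrain,nVal,nTest split sizes (>= 0).
#' @param seed master seed.
#' @param outDir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return named list of case-directory vectors (\code{train}, \code{val},
#'   \code{test}), invisibly also written to \code{manifest.json}.
#' @export
makeDataset <- function(spec, nTrain, nVal, nTest, seed, outDir,
                        overwrite = FALSE) {
  if (any(c(nTrain, nVal, nTest) < 0)) stop("split sizes must be >= 0")
  if (dir.exists(outDir) && length(list.files(outDir)) && !overwrite)
    stop("output directory exists and is not empty: ", outDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  splits <- list(train = nTrain, val = nVal, test = nTest)
  out <- list(); seeds <- list()
  idx <- 0L
  for (sp in names(splits)) {
    dirs <- character(0)
    for (i in seq_len(splits[[sp]])) {
      idx <- idx + 1L
      caseSeed <- childSeed(seed, idx)
      caseSpec <- spec
      caseSpec$seed <- caseSeed
      ph <- generatePhantom(caseSpec)
      caseDir <- file.path(outDir, sp, sprintf("case_%03d", i))
      dir.create(caseDir, showWarnings = FALSE, recursive = TRUE)
      writeDWI(ph$dwi, file.path(caseDir, "dwi.nii.gz"),
               file.path(caseDir, "dwi.bval"), file.path(caseDir, "dwi.bvec"))
      writeStructural(ph$t1, file.path(caseDir, "t1.nii.gz"))
      writeMaskImage(ph$brain@mask, file.path(caseDir, "brain_mask.nii.gz"),
                     voxelSize = rep(spec$voxelMM, 3))
      tn <- niftiFromArray(ph$tensors, rep(spec$voxelMM, 3),
                           diag(c(rep(spec$voxelMM, 3), 1)))
      RNifti::writeNifti(tn, file.path(caseDir, "tensors.nii.gz"),
                         datatype = "double")
      dirs <- c(dirs, caseDir)
      seeds[[sp]] <- c(seeds[[sp]], caseSeed)
    }
    out[[sp]] <- dirs
  }
  jsonlite::write_json(
    list(seed = seed, splits = lapply(out, basename), seeds = seeds,
         shape = spec$shape, voxelMM = spec$voxelMM, nB0 = spec$nB0,
         nDir = spec$nDir, bValue = spec$bValue, sigma = spec$sigma),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  out
}

#' Load one phantom case directory
#'
#' Reads back the files written by [makeDataset()].
#'
#' @param caseDir path to a case directory.
#' @return list with \code{dwi}, \code{t1}, \code{brain}, \code{tensors}.
#' @export
loadPhantomCase <- function(caseDir) {
  dwi <- readDWI(file.path(caseDir, "dwi.nii.gz"),
                 file.path(caseDir, "dwi.bval"),
                 file.path(caseDir, "dwi.bvec"))
  t1 <- readStructural(file.path(caseDir, "t1.nii.gz"))
  bm <- readMaskImage(file.path(caseDir, "brain_mask.nii.gz"))
  tn <- RNifti::readNifti(file.path(caseDir, "tensors.nii.gz"))
  list(dwi = dwi, t1 = t1, brain = brainMask(array(bm, dim = dim(bm))),
       tensors = array(as.numeric(tn), dim = dim(tn)))
}
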