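---
title: "Extending the field of view of brain diffusion MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extending the field of view of brain diffusion MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical brain diffusion MRI is frequently acquired with an incomplete
field of view (FOV): a contiguous block of axial slices at the superior or
inferior end of the brain is simply never scanned. Whole-brain analyses —
tractography, atlas registration, bundle statistics — then either fail or
silently truncate. The same session usually contains a T1-weighted
structural image with a complete FOV, co-registered to the diffusion data.
`dwifov` imputes the missing diffusion-weighted slices conditioned on that
structural image, so that downstream whole-brain pipelines can run.

The corrupted object is a 4-D diffusion study: V volumes
`x[, , , v]`, each acquired under a b-value `b_v` (s/mm^2) and a unit
gradient direction (b-vector) `g_v`. Volumes with `b_v` at or below a small
threshold (50 s/mm^2 by default, absorbing scanner jitter around zero) form
the unweighted b0 group; the remainder form the diffusion-weighted shell.
The model learns the mapping `G: {structural, truncated volume} -> complete
volume`, one volume at a time.

## The model

### 2.5D slice stacks

Each training or inference unit is a slice stack: for a target slice `i` in
a given view, the `2n + 1` neighbouring DWI slices `i - n .. i + n` are
concatenated with the `2n + 1` structural slices at identical spatial
indices, giving `2(2n + 1)` input channels; the output is the single
ground-truth DWI slice `i`. Only the **sagittal** and **coronal** views are
used. This is deliberate: the missing region consists of complete *axial*
slices, so an axial model would have to generate slices from no in-plane
signal at all, while sagittal and coronal slices each contain the full
superior-inferior extent — the missing band appears as a zeroed stripe
inside an otherwise observed slice, which is an inpainting problem with
usable context. Out-of-volume neighbour slices are zero-filled, consistent
with the zero-padding of the normalized grid.

At full scale the neighbourhood half-width is `n = 7` (30 channels); the
desk-scale configuration used in the tests and the acceptance run is
`n = 1` (6 channels).

### Four generators

Unweighted and diffusion-weighted volumes have very different contrast
(CSF is bright in b0, attenuated in weighted volumes), so one generator per
shell group is trained; combined with the two views this yields four
generators — (b0, sagittal), (b0, coronal), (bweighted, sagittal),
(bweighted, coronal) — each trained only on its own group and view. At
inference each volume is routed to its group's two generators, every slice
along each view axis is predicted, and the two predicted volumes are merged
by voxel-wise averaging with equal weights (no weighting information is
available to prefer one view).

### Objective

The generator G and a convolutional patch discriminator D play the
standard conditional minimax game

```
L_GAN(G, D) = E[log D(y)] + E[log(1 - D(G(x)))]
L_L1(G)     = E‖y - G(x)‖₁
G* = arg min_G max_D  L_GAN(G, D) + λ L_L1(G)
```

with the expectation of the adversarial term taken as the per-pixel mean
over the discriminator's patch score map. λ = 100, the convention of this
generator family; the L1 term carries the reconstruction burden and the
adversarial term sharpens the output. G is deterministic — no latent noise
is sampled — so imputation is reproducible bit-for-bit given fixed weights.
Losses are implemented in logit space (`log D = -softplus(-z)`), which is
algebraically identical to the probability-space formulas; the test suite
checks the equality to 1e-6.

### Networks

The generator is a residual encoder–decoder: a stride-1 convolution, one
stride-2 downsampling stage, residual blocks at the bottleneck,
nearest-neighbour upsampling, and a tanh head. A long skip connection
wraps the down/up path, so full-resolution features bypass the bottleneck
— without it the model reproduces fine detail near the acquired boundary
poorly, since every feature would have to survive the downsampled
representation. The network operates
internally on [-1, 1] intensities with an affine map to and from the
normalized [0, 1] range at the module boundary. Depth follows the slice
size: 9 residual blocks at ≥ 128² slices (the full-scale setting), 1 below
that. The discriminator is a 3-layer strided convolutional classifier
producing a spatial map of real/fake logits.

The convolution engine is part of the package: im2col/col2im patch kernels
in C++ with BLAS matrix products and analytic backprop, optimized with
Adam. Gradients are verified against finite differences in the test suite.

## Preprocessing and normalization

All images are resampled to an isotropic normalized grid (256³ at 1 mm at
full scale; desk-scale work uses 48³ at 1 mm) with centred zero-padding or
cropping; the grid frame is anchored on the DWI study's centre so the
structural image lands in the same frame. Trilinear interpolation is used
for intensities, nearest-neighbour for masks — the resampling order is not
dictated by the method, and these are the conventional choices.

Intensities are normalized per study: the 99.9th-percentile intensity over
*all voxels of all volumes jointly* maps to 1, the floor is 0, and values
clip to [0, 1]. A single shared scale per DWI study preserves the relative
attenuation between volumes, which is what the diffusion signal encodes;
the structural image receives its own scale. Whether background air should
be excluded from the percentile is genuinely open; the package computes it
over all voxels by default and exposes `excludeZeros` for the alternative.
On reconstruction the scale is multiplied back, so imputed intensities
return to the study's native range.

Brain masks are median-filter + Otsu threshold + largest connected
component (`computeBrainMask()`), a deliberately simple substitute for
atlas-based masking; it is used to locate the brain's z-extent, to restrict
metrics, and (optionally) to zero imputed voxels outside tissue before
recombination, suppressing halo artifacts.

## FOV simulation and training

Truncation is simulated, never acquired: `simulateCutoff()` zeroes the
`k = round(cut_mm / voxel)` axial slices adjacent to the brain's superior
or inferior boundary (ties round half away from zero) and records them in
an FOV mask; array shapes never change, the mask carries the semantics.
During training each step draws a study, a volume within the generator's
shell group, a cutoff extent uniform on the configured range, and a cut
side with probability 1/2 each; targets are the uncorrupted slices of both
cutoff and non-cutoff regions, so the model learns full-brain prediction,
not only inpainting. Slice indices are sampled inside the brain's bounding
box along the view axis — outside it both input and target are identically
zero and would only dilute the loss.

At full scale the cutoff range is 0–50 mm. At desk scale (48³ phantoms,
brain ≈ 36 slices tall) the same fraction of the brain is covered by
0–12 mm, which is the default the package's acceptance experiment uses;
50 mm would decapitate the phantom entirely.

Model selection is validation-based: at a fixed cadence the mean squared
error on the validation studies' **missing regions only** (within the brain
mask) is computed under a *fixed* cutoff — 30 mm from the top at full
scale, scaled proportionally to the grid's z-extent (5.6 mm at 48³) — and
the checkpoint minimizing that error is returned. A fixed validation
cutoff keeps checkpoint scores comparable; random cutoffs would add
selection noise.

Optimization is Adam with momentum (0.5, 0.999). The full-scale
convention for this generator family is a learning rate of 2e-4; at desk
scale — 8-filter networks, 48² slices, a few hundred optimization steps —
that rate leaves the validation error barely moved, so the package default
is 1.5e-3, held constant for the first half of training and decayed
linearly afterwards. Batch size is 8 at desk scale (24 at full scale). All of these
are `trainConfig()` fields.

The T1w-ablation baseline ("what does the structural image buy?") is
trained with `ablateStructural = TRUE`, which zeroes the structural
channels instead of removing them, so checkpoints stay shape-compatible
with the full model; the comparison in the acceptance experiment holds
seeds and all other settings fixed.

## Inference

`imputeStudy()` runs the full pipeline: resample to the grid if needed,
normalize, derive the FOV mask from zero-slice runs adjacent to the brain's
z-extremes when none is supplied, predict per volume in both views, merge,
optionally mask to brain, undo the normalization, resample the imputed
slices back to subject geometry, and recombine as

```
output = m ⊙ acquired + (1 - m) ⊙ imputed
```

where `m` is the FOV mask. Acquired voxels are therefore **bit-identical**
to the input — the hard guarantee the test suite asserts voxel-wise — and
the gradient table passes through unchanged.

## Evaluation

Metrics are computed on the normalized [0, 1] scale (`dataRange = 1`,
stated in every report) within (brain mask ∩ missing region):

* masked MSE and PSNR (`10·log10(range²/MSE)`; identical volumes report a
  +Inf sentinel);
* 3-D SSIM with a uniform cubic window of side 7 (a box window, since only
  the window size is conventionally fixed), averaged over window centres
  inside the mask;
* distance-stratified PSNR/SSIM: each missing axial slice is assigned its
  distance in mm — measured along the axial axis — to the nearest acquired
  slice that intersects the brain (acquired background slices beyond the
  cut carry no signal and are not a data boundary), and metrics are
  reported per distance bin, quantifying how error grows deeper into the
  missing region;
* per-direction ADC analysis: `ADC = -ln(S/S0)/b` per voxel with S0 the
  mean b0 (non-positive ratios become NA and are excluded), compared
  across gradient directions with a Kruskal–Wallis rank test (tie-corrected;
  the all-identical degenerate case reports H = 0, p = 1). A large p-value
  indicates no direction is systematically imputed worse.
* method comparison tables: per-study metrics first, then mean ± sd across
  studies, per shell group and method.

## The phantom generator

Clinical data cannot ship with the package, so training and all acceptance
checks run on a synthetic head phantom with exactly the statistical
structure the pipeline assumes:

* nested ellipsoids — background, "CSF" shell, "gray" shell, "white" core —
  with per-compartment unattenuated signal S0 (1.0 / 0.75 / 0.62) and a
  structural channel with *differently ordered* contrast (0.15 / 0.60 /
  0.95), so the structural image is informative but not a copy;
* tensor-model diffusion signal `S = S0 · exp(-b gᵀDg)`: isotropic tensors
  in CSF (3.0e-3 mm²/s) and gray (0.8e-3), a prolate tensor (1.7, 0.2,
  0.2)e-3 in white matter whose principal axis follows a smooth swirl
  field, so diffusion-weighted contrast genuinely depends on direction;
* one b0 plus 6 golden-spiral directions at b = 1300 s/mm² by default,
  48³ voxels at 1 mm;
* Rician magnitude noise at σ = 0.02·S0 (the standard magnitude-MRI model),
  independent Rician noise on the structural channel;
* per-case geometric jitter (semi-axes ±8%, rotations ±0.15 rad) driven by
  seeds derived deterministically from one master seed, so datasets
  regenerate byte-identically.

What the phantom does *not* emulate: gyral folding and fine anatomy,
susceptibility/eddy/motion artifacts, multi-shell schemes, partial-volume
mixtures. Passing tests on phantoms therefore demonstrates that the
machinery is correct and that the conditional model exploits the structural
channel — not that clinical-grade image quality is reached on real brains.

One consequence deserves emphasis. On real brains, imputation error grows
with distance into the missing region: anatomical complexity persists to
the vertex, and the model's in-plane context decays with every slice. On
the ellipsoid phantom this pattern *inverts*: the deepest missing slices
are small, smooth CSF/gray pole caps that the structural channel
determines almost completely, so per-slice difficulty anti-correlates
with distance and dominates the context-decay effect (the
slice-replication baseline, whose error is trivially the slice-to-boundary
difference, still shows the canonical decreasing profile on the same
data). The distance-stratified machinery itself is validated against a
constructed linear-error oracle; the increasing phantom profile is a
statement about nested-ellipsoid geometry, not about the method or the
metric.

The simulator and evaluator close a loop the tests exploit: on a noiseless
phantom, `adcMap()` recovers the specified `gᵀDg` field to 1e-8, which
validates both the signal synthesis and the ADC computation against each
other.

## Numerical choices and degenerate inputs

* b0 separation threshold: 50 s/mm².
* b-vectors off unit norm by more than 1e-3 are renormalized with a
  warning; b-vectors of b0 volumes are forced to zero.
* `round(cut_mm/voxel)` ties round half away from zero.
* An all-zero study has no valid normalization scale and errors.
* A constant-valued volume cannot be brain-masked and errors; an empty
  post-threshold mask errors.
* `simulateCutoff` rejects cutoffs exceeding the brain extent; the
  training loop clamps its random draws to the brain instead, since a
  clamped draw is still a valid augmentation.
* SSIM windows never cross the volume boundary (valid-center convention);
  PSNR of identical inputs is reported as +Inf rather than an error.
* Checkpoint-selection ties resolve to the earliest checkpoint.

## Problem sizes

The package's experiments are sized for a single CPU: 48³ phantoms, 1 b0 +
6 directions, four generators with 8 base filters, n = 1, batch 8, and a
few hundred optimization steps per generator. These sizes are the
documented desk-scale study conditions; every component scales to the
full-size configuration (256³, n = 7, 9 residual blocks, batch 24) through
configuration alone.

## Known limitations

* Registration between structural and diffusion images is consumed, not
  computed; misregistered inputs degrade output silently.
* Single-shell routing only (b0 vs one weighted shell); multi-shell data
  would need one generator pair per shell.
* The median-Otsu brain mask is a simple substitute for atlas-based
  masking and can leak on low-contrast data.
* Imputed intensities inherit the normalization of the truncated study; if
  the truncation removes a large fraction of bright tissue the percentile
  scale shifts slightly relative to the complete study.
* The axial view is intentionally unsupported.
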