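---
title: "A simulation-free lattice radiotherapy workflow in miniature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A simulation-free lattice radiotherapy workflow in miniature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticeplan)
```

## The problem

Lattice radiation therapy (LRT) is a spatially fractionated technique for
bulky tumors: ablative dose is delivered to a three-dimensional lattice of
small spheres inside the gross tumor volume (GTV) while the tissue between
the spheres only receives a low "valley" dose, typically 30--40% of the
prescription. Planning is slow partly because it waits on a dedicated
planning CT (pCT). A simulation-free workflow instead predicts a synthetic
CT (sCT) from the diagnostic CT (dCT) the patient already has: the dCT is
cleaned up (couch removal, bone-based rigid alignment, resampling), a
network predicts a dense deformation vector field (DVF), and the sCT --
the dCT warped by that field -- stands in for the pCT during planning. The
plan is later verified by recalculation.

`latticeplan` implements that whole chain as a testable miniature: every
stage runs on seeded digital phantoms with a known ground-truth
deformation, so each component's claim can be checked quantitatively
without patient data.

## Raster conventions

All volumes (`image_volume`, `binary_mask`, `dose_grid`,
`deformation_field`) are 3D arrays ordered x, y, z (z = axial slice) with a
positive `spacing` (mm) and an `origin` giving the mm position of the
*center* of voxel (0,0,0) in patient LPS coordinates. Displacement fields
are stored in mm on the fixed grid, so a zero field is the identity warp
regardless of spacing. Out-of-grid samples take -1024 HU (air), the same
value used for background fill after couch removal; dose is always cGy.
`resample_to_shape()` preserves the physical field of view (edges stay
fixed, spacing rescales), which keeps constants exact and makes a linear
intensity ramp resample without error in the interior.

## The phantom generator

`make_phantom()` renders a paired dCT/pCT study analytically:

* a soft-tissue body ellipsoid (40 HU) in air (-1000 HU), with lungs
  (-700 HU) in the thorax preset and an optional gastric gas pocket
  (-1000 HU) in the abdomen preset -- gas can appear in only one of the two
  scans, mimicking inter-scan physiology;
* bony anatomy (700 HU): a spine with *aperiodically* spaced vertebral
  bodies plus two asymmetric rib blocks. The chirped spacing and asymmetry
  are deliberate: a plain cylindrical spine makes axial shifts and z-axis
  rotations unobservable to a registration metric, and bone that runs to
  the grid edge makes every trial shift pay a truncation penalty that can
  exceed the alignment reward. The bone therefore ends 42 mm short of the
  axial faces;
* partial-volume transition bands at tissue interfaces (6 mm for
  soft-tissue boundaries, 2 mm radially for bone), as CT reconstruction
  produces. Besides realism this has a numerical purpose: with
  infinitely sharp edges, trilinearly warping the rendered dCT could never
  agree with the analytically rendered pCT at boundary voxels, and
  sub-voxel registration would be limited by binarization quantization;
* a tumour ellipsoid (GTV, 60 HU) and geometric OAR primitives (spheres,
  axial cylinders, slabs);
* a diagnostic couch (curved shell, 200 HU) versus a flat planning couch;
* the ground-truth deformation `true_dvf`: a Gaussian-filtered random
  vector field scaled to a chosen maximum amplitude (default 4 mm,
  kernel 25 mm) plus a systematic 3 mm posterior "sag" shared by all
  phantoms -- the anatomy change a flat table induces relative to a curved
  diagnostic couch. The pCT is rendered by evaluating the analytic anatomy
  at displaced positions, so `warp(dct, true_dvf)` matches the pCT exactly
  up to noise and interpolation;
* independent Gaussian HU noise (default sd 10 HU) on both scans.

Everything is drawn under the spec's seed, and a fixed seed reproduces the
bundle bit for bit.

What the phantom does *not* emulate: realistic organ shapes and texture,
scanner-specific reconstruction kernels, respiratory motion, truncated
fields of view, or arm-position changes. Passing tests therefore
demonstrate the algorithms' correctness under controlled geometry, not
clinical-grade accuracy on real scans.

## Pre-processing

`remove_couch()` follows the classic recipe: threshold at -200 HU, keep
the largest 8-connected 2D region per axial slice, then a 3D morphological
closing (ball radius 3 voxels) and dilation (radius 2) implemented through
exact Euclidean distance transforms. Two refinements matter in practice.
First, enclosed holes in each slice (lung fields, gas pockets) are filled
before the closing: kernels small enough not to swallow the couch can
never bridge a lung-sized cavity, yet interior anatomy obviously belongs
to the body. Second, the returned image equals the input *exactly* inside
the final mask and is exactly -1024 outside it, which makes the operation
idempotent. The couch must be separated from the skin by more than the
dilation radius -- true for the phantoms and for real couch gaps.

`rigid_register()` maximizes normalized cross-correlation between
bone-emphasized images (binarized above 200 HU, Gaussian-blurred) over the
6 rigid parameters. Because the bone maps leave the metric extremely flat
in some directions (a near-cylindrical spine barely constrains z-axis
rotation), general-purpose simplex or quasi-Newton optimizers stall; the
package instead uses deterministic coordinate descent with Brent line
searches, swept until the largest parameter step is below 0.01 mm /
0.01 degrees, over a coarse-to-fine schedule (half-resolution with sigma 6
voxels, then full resolution with sigma 2.5). On noise-free-geometry
phantoms this recovers simulated transforms to a few tenths of a mm and
degree; part of the residual is quantization, since a resampled-then-
binarized bone map can only shift in whole voxels.

`preprocess_pair()` chains couch removal, dCT-to-pCT alignment, and
field-of-view-preserving resampling of both scans to one grid (the
reference target is 128 x 128 x 64).

## The deformation model

The sCT predictor is a small residual U-Net style encoder-decoder,
written directly on compiled 3D convolution kernels: one 3x3x3 convolution
+ leaky ReLU per resolution level, 2x average pooling downward, nearest
upsampling with additive skips upward, channels doubling per level, and a
*zero-initialized* 3-channel output convolution so the untrained model is
exactly the identity warp. The DVF is produced in mm; the sCT is the dCT
warped by it, so sCT intensities are always trilinear combinations of dCT
intensities -- the model cannot hallucinate HU values.

The loss is `similarity + lambda * reg`: MSE on intensities in kHU by
default (a windowed local-NCC option exists; window 9 voxels), plus a
diffusion regularizer -- the mean squared forward difference of each
displacement component, zero for any constant field -- with
`lambda = 0.01`. Training is full-precision deterministic Adam (one step
per pair per epoch, fixed order, no stochastic batching), and the returned
parameters are those of the best epoch, so the final loss never exceeds
the identity-warp loss. Backpropagation, including the gradient through
the trilinear warp, is verified against central finite differences in the
tests.

One numerical choice deserves a note: the training/prediction warp uses
*border-clamped* sampling rather than the -1024 fill of the generic
`warp()` operation. Where anatomy touches a grid face, a constant fill
turns any outward boundary displacement into a large loss penalty with
identically zero gradient -- the optimizer cannot see, only suffer, it.
Clamping keeps the loss smooth; it is also the default in mainstream
registration-network implementations.

At the package's toy scale (64 x 64 x 32 grids, 2 levels, 4 starting
channels, ~20 epochs, learning rate 0.01) training four phantom pairs
takes well under a minute per seed on one CPU and cuts the dCT-vs-pCT MAE
by roughly 40%, with the SSIM ordering moving the same way; a held-out
phantom also improves because the couch-induced sag component of the
deformation is systematic across the cohort. The clinical-scale
description (3 levels, 32 channels, 128 x 128 x 64) is expressible with
the same `model_spec()` but is not what the tests run.

## Similarity metrics

`mae`, `ncc`, `ssim`, `gmsd` (and `similarity_report`) are global, masked
metrics between co-registered volumes. NCC uses population standard
deviations so identical non-constant images score exactly 1. SSIM is the
single-window global closed form with `c1 = (0.01 L)^2`,
`c2 = (0.03 L)^2`, and `L = 4095` by default (the HU scale shifted
by +1024). GMSD follows the 2D convention of its reference
implementation: per axial slice, Prewitt gradient magnitudes (kernels
scaled by 1/3, 'same' convolution with replicated borders) on intensities
linearly rescaled to [0, 255], `GMS = (2 m1 m2 + C)/(m1^2 + m2^2 + C)`
with `C = 170`, and GMSD the population standard deviation of GMS over
the evaluated voxels. Replicated (not zero) borders keep GMSD exactly
invariant to a global intensity offset, which the definition promises.
Masked evaluation defaults to the body-mask region in the pipeline; both
masked and whole-grid modes are exposed.

## Sphere placement

`place_spheres()` is a deterministic, auditable interpretation of the
clinical protocol: 1.5 cm spheres whose centres lie at least 1.0 cm inside
the GTV surface and 1.5 cm from every OAR voxel, same-plane
centre-to-centre spacing within 6--8 cm, and at least 3 cm between centres
in different axial planes. Distances are Euclidean mm computed by exact
(anisotropic Felzenszwalb) distance transforms plus exact point-to-voxel
checks. Two design choices were genuinely open:

* *Feasibility.* The whole sphere must fit inside the contracted GTV
  (centre at least contraction + radius = 17.5 mm from the surface), so a
  target whose 1 cm contraction leaves less than one sphere yields an
  empty set with a structured warning rather than a degenerate "lattice"
  of one clipped sphere.
* *Search.* Axial planes are chosen greedily by candidate capacity subject
  to the 3 cm cross-plane rule; within a plane, centres sit on a hexagonal
  lattice with pitch 7 cm (the midpoint of the 6--8 cm rule, giving all
  nearest neighbours that spacing) with offset rows. The lattice is
  anchored on a half-pitch grid about the volume centre and the phase with
  the highest sphere count is kept. Because each phase's count can only
  drop when the candidate region shrinks, a smaller GTV can never gain
  spheres. Points whose nearest same-plane neighbour would exceed 8 cm are
  pruned; single-sphere planes are accepted (the protocol's 6--8 cm figure
  is "normally, depending on the case").

`audit_placement()` recomputes every constraint minimum from scratch and
returns a machine-readable violation list; `rasterize_spheres()` produces
the per-sphere and union masks used for DVH scoring.

## Synthetic lattice dose

The treatment planning system itself is out of scope; dose optimization is
replaced by an analytic painter with the published envelopes.
`synth_lattice_dose()` lays a valley plateau of
`valley_ratio x prescription` (default ratio 0.3--0.4 regime, 0.35) inside
the GTV, adds a spherically symmetric kernel per sphere -- a smoothstep
falloff from `peak_factor x prescription` (default 1.3, inside the
120--150% Dmax envelope) at the centre to the valley at 1.5x the sphere
radius -- and decays with a Gaussian (8 mm) outside the GTV. Each
kernel's radial exponent is calibrated per sphere so that the *median*
dose over that sphere's voxels equals the prescription, honouring the
"D50% within +-50 cGy of 2000 cGy" aim by construction; the whole field is
linear in the prescription.

## Dosimetric evaluation

`dvh_curve()`/`dvh_metrics()` use exact voxel-volume weighting; `Dx%` is
the minimum dose to the hottest x% of the structure with linear
interpolation between sorted voxel doses, `DV-cc` the analogue at absolute
volume, `Dmin`/`Dmax` point doses (the volume-buffered reading is covered
by `D0.03cc`), heterogeneity `D10%/D90%`, and `MVS(d)` the absolute volume
receiving strictly less than `d` -- reported against the lung
(740 cGy / 1000 cc) and liver (910 cGy / 700 cc) sparing requirements.

`fit_spheres_from_isodose()` reproduces the published contour-fitting
trick: threshold the dose at 50% of prescription (of prescription, not of
maximum -- the valley at 30--40% stays below it by construction),
26-connected 3D components, drop components under 0.1 cc (speckle; the
reference doses are smooth so the filter is inert there), and place a
fixed 1.5 cm sphere at each component centroid.

`wilcoxon_signed_rank()` implements the classic paired test: zeros
dropped, midranks, and for n <= 25 the *exact* two-sided p-value from the
null distribution of the positive-rank sum computed by dynamic programming
over doubled ranks (valid under ties, and equal to full 2^n enumeration);
beyond that a normal approximation with tie and continuity corrections.
`compare_plans()` applies it per structure and metric across cases,
requiring 5 paired cases for the test and flagging all-zero comparisons as
degenerate rather than inventing a p-value.

## The reference pipeline

`run_pipeline()` chains everything on a small cohort (default 5 thorax
phantoms with a large central GTV and a posterior cylindrical OAR,
seed-derived): preprocess each pair at 48 x 48 x 24, train the toy model
on all pairs, predict each sCT and score similarity, then -- mirroring the
clinical logic -- *plan on the prediction and recalculate on the truth*:
the diagnostic-frame GTV is carried through the predicted DVF to give the
planning target, spheres are placed and dose painted on that predicted
target, and the same plan is re-painted on the true planning-frame GTV,
where contours are also re-fitted from the 50% isodose. The paired
deviations between the two metric sets therefore measure exactly what the
workflow risks: the residual error of the deformation prediction. Reports
are JSON with every number traceable to a module call, and a rerun from
the same config and seed is byte-identical. The problem sizes above keep
a full run within a few minutes on one CPU; they are configuration, not
limits -- the same config object expresses the 128 x 128 x 64 scale.

A thin command-line front end (`inst/cli/latticeplan`) exposes the stages
(`phantom`, `preprocess`, `compare`, `plan`, `dose-eval`, `fit-spheres`,
`run`) as subcommands over NIfTI files; all computation stays in the
package functions.

## Known limitations

* The phantoms are smooth geometric primitives; none of the texture,
  beam-hardening or motion artifacts of real CT exist here, so measured
  similarity values are far better than clinical ones and are meaningful
  only as orderings and recovery checks.
* The dose painter is an analytic stand-in: it honours the published
  valley/peak/median envelopes but has no beam model, so absolute OAR
  doses reflect geometry, not physics.
* Registration accuracy is quoted for the bone-rich phantom family;
  degenerate bone distributions (truncated or symmetric) reduce
  identifiability, which is why the phantom bone is aperiodic, asymmetric
  and axially compact.
* The deformation model is trained at toy scale with MSE; no claim is
  made that the toy optimum transfers to clinical resolution.
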