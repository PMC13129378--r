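---
title: "Weakly supervised MRI to 4D-CT contour propagation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised MRI to 4D-CT contour propagation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

Liver SBRT planning needs organ and target contours on every respiratory
phase of the planning 4D-CT, while the contours themselves are best drawn on
a breath-hold MRI with superior soft-tissue contrast. Mapping MR contours
onto every CT phase therefore requires solving two coupled problems at once:
cross-modality alignment (MR and CT intensities are not comparable) and
respiratory motion tracking (each phase is deformed relative to the
end-expiration reference, CT-50). `mr4dctreg` implements a learning-based
pipeline for this task together with the deformation-QA machinery needed to
trust its output, and a synthetic 4D dual-modality phantom generator that
provides ground truth for end-to-end validation.

## Transformation model

All deformable transforms are parametrized by a stationary velocity field
(SVF) $v$: the deformation is the flow $\Phi = \exp(v)$, computed by
scaling-and-squaring — $v$ is scaled by $2^{-7}$ and the resulting small
displacement is self-composed 7 times. Because the flow of a smooth velocity
field is a diffeomorphism, the integrated fields are near-diffeomorphic by
construction; the package verifies this numerically (folding fraction below
0.1%, inverse consistency $\exp(v)\circ\exp(-v)\approx\mathrm{id}$ within
0.05 voxel for the smooth test family). Displacements are kept in voxel
units internally and converted to millimetres only at NIfTI export.

A registration network — a 3D encoder-decoder with optional attention-gated
skip connections — maps the channel-stacked (fixed, moving) pair to the SVF.
The final layer is initialized near zero so the untrained network predicts
the identity; registration training from a non-identity start destroys the
moving image before similarity gradients can stabilize it.

## Training objectives

Two networks are trained on different objectives and composed at inference
("Pipeline"), and a third ("Direct") maps MR to any phase with one network:

* **Temporal (mono-modal, CT-50 to CT-phase)** — local normalized
  cross-correlation (window 9^3 at the working resolution, squared so the
  loss is insensitive to contrast sign), plus a Jacobian-determinant penalty
  $\mathrm{mean}((|\nabla\Phi| - 1)^2)$ that discourages volume change and
  folding without penalizing large but plausible displacements, plus a soft
  Dice term on the supervised organ channels. Weights $\lambda = 0.3$,
  $\gamma = 0.7$.
* **Multi-modal (MR to CT-50)** — negative mutual information from a
  differentiable Parzen-window joint histogram (32 Gaussian kernels of one
  bin width, per-voxel normalized), evaluated only inside the overlap region
  $\Omega_\cap$; a first-order penalty on the field gradient keeps the warp
  small (rigid pre-alignment has already done the coarse work); and the same
  soft Dice term. Weights $\lambda = 0.5$, $\gamma = 0.5$.
* **Direct** — the multi-modal objective applied to (MR, CT-phase) pairs for
  every phase: mutual information is the only similarity in the set that is
  valid across modalities at all phases.

Weak supervision uses the four abdominal organs that are reliably visible in
both modalities (liver, spleen, both kidneys), restricted to organs fully
inside the MR field of view. During training the organ indicators are warped
as soft probability channels (trilinear) so the Dice term stays
differentiable; exported contours are always warped nearest-neighbour.

The optimizer is Adam (learning rate $10^{-3}$, batch size one) with all
sampling and initialization seeded; the checkpoint with the best validation
loss is retained. The backward pass — through the losses, the
spatial-transformer warp, the scaling-and-squaring recursion and the network
— is implemented analytically and verified against finite differences in
the test suite.

## Rigid pre-alignment and the overlap region

The multi-modal branch starts from a 6-DOF rigid alignment of the
(resampled, zero-padded) MR to CT-50, found by maximizing a 48-bin histogram
mutual information over a 3-level multi-resolution pyramid. Two details
matter in practice and are easy to get wrong:

* the MI is evaluated inside the *transported MR support mask*, not over
  voxels with non-zero warped intensity — the latter induces a zero-padding
  artifact that corrupts the objective away from integer-voxel shifts;
* local search alone is unreliable (the thorax-abdomen intensity profile
  creates false optima along the superior-inferior axis), so the coarsest
  level runs an exhaustive translation grid (±12 mm in 4 mm steps) and
  Nelder-Mead refines the best cells.

The recovered map, applied to the native MR support, defines
$\Omega_\cap$; multi-modal similarity and metrics for partially covered
organs are computed only inside it. The rigid map is exported as a dense
displacement field so rigid and deformable transforms compose uniformly:
the end-to-end field for phase $\varphi$ is
$\Phi_{\mathrm{rigid}} \circ \Phi_{\mathrm{MR}\to\mathrm{CT50}} \circ
\Phi_{\mathrm{CT50}\to\mathrm{CT}\varphi}$ (composition implemented as
`compose_fields(phi_then, phi_after)` with trilinear resampling of the
earlier field).

## Working resolution

Deformable fields are predicted at a low working resolution and trilinearly
upsampled to the native grid before labels are warped (displacement
magnitudes are rescaled so the physical displacement in mm is preserved).
The desk-scale profile used throughout the tests and the acceptance script
is a 48x48x32 native grid at 2 mm with a 24x24x16 working grid at 4 mm and
16 base channels — a 2x upsampling factor mirroring the full-scale protocol
(512x512xD native, 128x128x64 working grid), which exists as configuration
but is not exercised by the tests. The experiment sizes (6 training + 3
held-out phantoms, 250 iterations per network) were chosen as the smallest
configuration at which the three methods separate cleanly and reproducibly.

## The synthetic phantom

No public MR/4D-CT cohort with ground truth exists, so validation runs on a
seeded synthetic phantom that emulates the salient difficulties of the
clinical data:

* **anatomy** — ten ellipsoid organs (liver, spleen, kidneys, lungs, heart,
  stomach, vertebral column, body) at plausible relative positions, with
  HU-like CT intensities plus Gaussian texture; per-subject seeded jitter of
  organ positions (±2% of the extent) and sizes (±6%) provides anatomical
  variation across a cohort;
* **respiratory motion** — an analytic SVF whose superior-inferior component
  is $a(\varphi)\,A\,w(x)$ with $a(\varphi) = (\cos 2\pi\varphi + 1)/2$
  (zero at the 50% reference, maximal at 0%) and a spatial weight $w$ that
  plateaus below the diaphragm and decays to zero at the lung apex, the
  inferior face and the body boundary; small lateral drift components (20%
  of $A$, correlation length 8 voxels) add realism. The default amplitude
  is $A = 10$ mm, the typical mean liver excursion;
* **modality gap** — the MR intensity table is deliberately not a monotone
  remap of the CT table (rank correlation 0.42), plus a smooth
  multiplicative bias field and noise, so MR/CT alignment genuinely requires
  mutual information;
* **field-of-view mismatch and misalignment** — the MR volume is cropped to
  75% of the z-extent and misaligned by a known rigid transform (default
  (6, −4, 8) mm), which the pipeline must recover;
* **binning artifacts** — optionally, a duplicated shifted axial slab per
  phase emulates irregular-breathing 4D-CT reconstruction errors.

Ground truth (per-phase velocity and displacement fields, the rigid
transform) is retained, enabling parameter-recovery experiments: rigid
recovery to within 1 mm, ground-truth label transport consistency, and the
rigid-vs-deformable comparison on held-out subjects.

Design notes on the motion field, decided once and kept:

* organs sit in the upper two thirds of the volume so the inferior ramp-off
  of the motion weight runs through unlabelled tissue; placing small organs
  inside a high-velocity-gradient zone makes discrete label transport
  rounding-limited instead of interpolation-limited;
* the lateral drift components are smooth at organ scale for the same
  reason;
* the "apex moves by $a(\varphi) A$" property holds at the apex landmark of
  the *phase-frame* labels. At the reference-frame apex the pull-warp
  trajectory necessarily runs into the apex decay zone, so the displacement
  read there is smaller — true of any motion field that vanishes at the
  lung apex.

## What the phantom does not show

The phantom demonstrates that the implementation works — losses optimize the
right thing, fields compose correctly, ground truth is recovered — not that
the method reaches clinical accuracy. Real data differ in ways the phantom
does not emulate: soft-tissue texture and boundary diffusivity, liver
sliding against the chest wall (a discontinuity an SVF cannot represent),
scanner-specific MR distortions, automatic-segmentation label noise (the QC
filter exists for this, but the phantom's labels are exact), andanatomical
diversity far beyond jittered ellipsoids. Absolute Dice values on the
phantom are not comparable to clinical values in either direction: organs
are coarsely resolved (a phantom kidney spans ~8 voxels), which depresses
overlap scores for small structures, while the absence of appearance
variability flatters the networks.

## Numerical choices and degenerate inputs

* Folding criterion: $|\nabla\Phi| \le 0$ (determinant exactly zero is
  degenerate and counted as folded); the log-Jacobian statistics exclude
  determinants below $10^{-6}$.
* LNCC denominators are stabilized with $\varepsilon = 10^{-5}$; constant
  windows contribute zero correlation rather than dividing by zero. The
  squared-NCC convention makes the loss insensitive to local contrast
  inversion, which matters for nothing in the mono-modal branch but keeps
  the loss bounded in $[0, 1]$.
* The soft Dice $\varepsilon$-convention makes organs empty on both sides
  contribute zero loss.
* Warping samples outside the input grid return zero (matching the
  zero-padding convention); field self-composition during integration
  clamps sample coordinates to the border instead, which keeps the
  scaling-and-squaring recursion stable at the faces (clamped coordinates
  propagate no gradient).
* Intensity normalization: CT is clamped to [−1000, 1000] and mapped
  linearly to [0, 1]; MR is rescaled by its 1st-99th percentiles. Bounded
  intensities are a precondition of the histogram-based MI terms.
* Oblique NIfTI affines are rejected rather than silently resampled; the
  pipeline resamples everything onto the CT-50 grid explicitly.
* Training phantoms may be rigidly pre-aligned with the generator's true
  transform (the supervision labels are ground truth anyway); held-out
  evaluation always runs the estimated alignment.

## Known limitations

* Double nearest-neighbour label transport loses a one-voxel cap on the
  smallest organs when a phase displacement lands within ~0.15 voxel of a
  half-integer; at the default amplitude no phase does, but e.g. a 15 mm
  amplitude on the 2 mm grid puts phase 0 exactly at 7.5 voxels and
  round-trip Dice for a phantom kidney drops to ~0.93. This is a property
  of discrete label transport, not of the registration.
* The hand-written backward pass covers exactly the architecture shipped;
  structural changes to the network require extending it (each block is
  finite-difference-tested, which makes that tractable).
* The statistics layer (`compare_methods`) reduces each subject to a median
  before testing, the conservative reading of patient-level pairing; with
  six phases per subject other reductions are defensible and would change
  p-values.
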