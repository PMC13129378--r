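# mr4dctreg

Deformable registration for mapping MRI-defined organ contours onto every
respiratory phase of a planning 4D-CT, the contour-propagation problem of
liver stereotactic body radiotherapy (SBRT). Planning contours are best
drawn on a breath-hold MR with good soft-tissue contrast, but dose is
planned on a 4D-CT whose phases move with respiration — so the contours
must cross both a modality gap and a motion gap.

The package implements the full pipeline in R (with Rcpp kernels):

* **Transformation model** — stationary velocity fields (SVF) integrated by
  7-step scaling-and-squaring, `Φ = exp(v)`, giving near-diffeomorphic
  warps; dense-field composition, trilinear upsampling, and a
  Jacobian-determinant QA suite (foldings %, log-Jacobian SD, masked
  variants).
* **Registration networks** — a 3D attention-gated encoder-decoder predicts
  the SVF from a channel-stacked (fixed, moving) pair. Training is weakly
  supervised:

  - temporal (CT-50 → CT-phase): `LNCC + 0.3·mean((|∇Φ|−1)²) + 0.7·Dice`
  - multi-modal (MR → CT-50): `−MI(Ω∩) + 0.5·‖∇u‖² + 0.5·Dice`
  - direct (MR → any phase): the multi-modal objective on all-phase pairs

  with the Dice term on four supervised abdominal organs (liver, spleen,
  kidneys). Forward and backward passes (losses, spatial-transformer warp,
  scaling-and-squaring, network) are implemented analytically and
  finite-difference tested.
* **Rigid pre-alignment** — seeded multi-resolution mutual-information
  optimization with a coarse translation grid search; its transported MR
  support mask defines the overlap region `Ω∩` used by multi-modal
  similarity and partial-organ metrics.
* **Propagation** — `propagate_rigid()` (clinical baseline),
  `propagate_direct()`, and `propagate_pipeline()` (per-phase composition
  `Φ_rigid ∘ Φ_MR→CT50 ∘ Φ_CT50→CTφ`), with fields predicted at a low
  working resolution and upsampled before nearest-neighbour label export.
* **Evaluation** — Dice, 95th-percentile Hausdorff distance (exact
  anisotropic distance transform), MI whole-image and within `Ω∩`,
  folding statistics; paired Wilcoxon signed-rank tests on patient-level
  medians with Benjamini-Hochberg FDR correction; binned
  improvement-over-rigid analysis; tidy tibble outputs with `tidy()` /
  `glance()` / `autoplot()` methods.
* **Synthetic 4D phantom** — a seeded dual-modality abdominal phantom with
  analytic diffeomorphic respiratory motion (zero at the 50% reference
  phase), genuinely non-monotone MR/CT contrast, MR field-of-view cropping,
  a known rigid misalignment and optional 4D-CT binning artifacts — the
  ground-truth substrate for every end-to-end test.

## Worked example

```r
library(mr4dctreg)

# one synthetic subject: 6 CT phases + misaligned, cropped MR + labels
study <- make_study(phantom_config(seed = 1))
study
#> <4D study: 6 phases on 48x48x32, MR FoV 48x48x24, A = 10 mm>

# the clinical baseline: rigid MI alignment only
r <- propagate_rigid(study, seed = 1)
r$rigid$params
#> <rigid: t = (6.00, -3.98, 7.79) mm, r = (-0.0010, -0.0014, -0.0001) rad>
# (the phantom's true misalignment is (6, -4, 8) mm)

rec <- evaluate_result(r, study$labels_ct,
                       fixed = lapply(study$ct, normalize_intensities),
                       subject = "subj01")
dplyr::filter(rec, organ == "seen")[, c("phase", "dsc")]
#>   phase   dsc
#> 1     0 0.088
#> 2    16 0.206
#> 3    33 0.767
#> 4    50 1.000
#> 5    66 0.767
#> 6    83 0.207
```

The rigid baseline is perfect at the reference phase and collapses with
increasing respiratory displacement — exactly why deformable propagation is
needed. The full comparison (train the three networks, evaluate Direct and
Pipeline against the rigid baseline on held-out phantoms):

```r
ex <- run_phantom_experiment(n_train = 5, n_val = 1, n_test = 3,
                             iterations = 250, seed = 1)
ex$summary
#> # A tibble: 3 × 6
#>   method   mean_seen_dsc mean_seen_h95 mean_foldings_pct mean_stdlj ...
#> 1 direct           0.652          5.18                 0      0.170
#> 2 pipeline         0.622          4.01                 0      0.202
#> 3 rigid            0.509          4.99                 0      0.000
```

Both learned methods improve mean supervised-organ Dice over the rigid
baseline by more than 0.10 while keeping the deformations fold-free; the
two-step pipeline buys its cleaner decomposition at a small Dice cost
relative to the single direct network on this phantom family.

A command-line wrapper for the generator and propagation lives at
`inst/scripts/mr4dctreg`:

```sh
Rscript inst/scripts/mr4dctreg phantom --out study/ --seed 1
Rscript inst/scripts/mr4dctreg propagate --study study/ --method rigid --out out/
```

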