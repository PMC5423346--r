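# pcasl

Quantitative cerebral blood flow (CBF) mapping from pseudo-continuous
arterial spin labeling (pCASL), built for the intraoperative use case:
checking, without contrast agent, whether elevated perfusion at the rim of
a resection cavity indicates residual tumor, and whether absolute CBF
values are interchangeable across the scanners a patient meets before,
during and after surgery.

The package is aimed at perfusion-MRI methods researchers and at anyone who
needs a fully synthetic, ground-truthed test bed for single-delay ASL
pipelines: every stage can be exercised against a digital head phantom
whose true perfusion is known exactly.

## What it computes

CBF is quantified with the single post-labeling-delay equation recommended
by the ISMRM perfusion study group and the ASL consortium:

    CBF [ml/100 g/min] = 6000 · λ · ΔM · e^(PLD/T1b)
                         ─────────────────────────────────
                         2 · α · T1b · M0 · (1 − e^(−τ/T1b))

where ΔM is the mean control-minus-label difference signal, M0 the
equilibrium-magnetization image, λ = 0.9 ml/g the blood–brain partition
coefficient, PLD = 1800 ms the post-labeling delay, τ = 1800 ms the
labeling duration, T1b the blood T1 (1650 ms at 3T, 1350 ms at 1.5T) and
α = 0.85 the labeling efficiency (configurable; it has no universal value).
Times are stored in ms and converted to seconds inside the equation.

Around that core the package provides:

* **Digital phantom + scanner simulator** — an ellipsoidal head with GM
  shell, WM core, CSF ventricles, optional hyperperfused lesions and a
  resection cavity; acquisitions simulated for three packaged profiles
  (3T head coil / 20 pairs, 1.5T head coil / 30 pairs, 1.5T
  intraoperative surface coils / 40 pairs with a multiplicative coil bias
  field) on a 240 × 240 × 95 mm FOV, 3.6 × 3.5 mm in-plane, 16 slices.
* **Quantification pipeline** — pairwise subtraction, voxel-wise
  quantification with sentinel-flagged invalid voxels, gray-matter masking
  and ROI statistics.
* **Agreement statistics** — pairwise Pearson correlation of per-subject
  GM means across scanners, and a single-measurement intraclass
  correlation (ICC(2,1) by default) computed directly from the ANOVA
  mean squares.
* **Residual-tumor rating** — a reproducible operationalization of
  "elevated CBF near the cavity": threshold at mean + 2·sd of
  contralateral gray matter, 26-connected clusters of at least 5 voxels
  inside a 10 mm shell around the cavity.
* **Study drivers** — `run_volunteer_study()` (multi-scanner
  reproducibility cohort) and `run_patient_study()` (pre-, intra- and
  postoperative resection-control scenarios), plus NIfTI/CSV/JSON/YAML
  I/O for every interface.

## Worked example

```r
library(pcasl)

prof <- asl_profiles("3t")
ph   <- generate_phantom(phantom_spec(grid = prof$grid,
                                      voxel_size = prof$voxel_size),
                         seed = 42)
ser  <- simulate_acquisition(ph, prof, seed = 42)
cmap <- quantify_series(ser)
mean_roi_cbf(cmap, gm_mask_from_phantom(ph))
#> $mean        50.1      # true GM CBF is 50 ml/100 g/min
#> $sd          13.6
#> $n           6608      # GM voxels averaged
#> $n_excluded  0

run_volunteer_study(run_config("volunteer", seed = 42))$agreement
#> Cross-scanner agreement (10 subjects)
#>   r(3t vs 1p5t_rad) = 0.999
#>   r(3t vs 1p5t_or) = 0.999
#>   r(1p5t_rad vs 1p5t_or) = 0.999
#>   3t:       mean GM CBF 54.73 (sd 8.43) ml/100 g/min
#>   1p5t_rad: mean GM CBF 54.74 (sd 8.53) ml/100 g/min
#>   1p5t_or:  mean GM CBF 54.64 (sd 8.53) ml/100 g/min
```

The single-scan GM mean lands on the phantom's true 50 ml/100 g/min (the
voxel-level sd reflects acquisition noise, which averages out of the ROI
mean). In the simulated cohort the per-scanner means agree to a fraction
of a ml/100 g/min and the per-subject values correlate near-perfectly
across scanners — the between-subject spread (sd ≈ 8.5) dominates the
measurement noise, which is precisely what makes absolute CBF values
interchangeable between scanners.

For the patient side:

```r
lesion <- list(center = c(45, 40, 5), radius = 14, cbf = 150)
patients <- c(rep(list(list(lesion = lesion, resected_fraction = 0.5)), 5),
              rep(list(list(lesion = lesion, resected_fraction = 1)), 3))
run_patient_study(run_config("patient", patients = patients, seed = 5))$summary
#> $intraop_residual    5
#> $postop_residual     5
#> $complete_at_surgery 3
```

## Vignette

`vignettes/pcasl-quantification.Rmd` documents the signal model, every
tunable parameter with units and defaults, what the phantom does and does
not emulate about real ASL data, the numerical conventions, and known
limitations.
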