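---
title: "Single-delay pCASL quantification, simulation and agreement: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-delay pCASL quantification, simulation and agreement: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcasl)
```

## The signal model

In pseudo-continuous arterial spin labeling, arterial blood water is
magnetically inverted at a tagging plane in the neck; after a post-labeling
delay, label and control images are acquired and subtracted. The mean
control-minus-label difference $\Delta M$ is proportional to perfusion, and
the consensus single-delay model converts it to absolute cerebral blood
flow:

$$
\mathrm{CBF} = \frac{6000\,\lambda\,\Delta M\, e^{PLD/T_{1b}}}
  {2\,\alpha\,T_{1b}\,M_0\,(1 - e^{-\tau/T_{1b}})}
  \quad [\mathrm{ml}/100\,\mathrm{g}/\mathrm{min}]
$$

The model assumes the post-labeling delay exceeds the arterial transit
time (all labeled blood has reached tissue at readout), a single blood
compartment relaxing with $T_{1b}$, and no outflow of labeled water during
the delay. It is a closed-form map, not a kinetic-model fit: `pcasl` does
not estimate transit times, fit multi-delay data, or model vascular
signal, and intravascular "overshoot" from slowed flow is out of scope.

### Parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| $\lambda$ | blood–brain partition coefficient (ml/g) | 0.9 | standard whole-brain value |
| $PLD$ | post-labeling delay (ms) | 1800 | common single-delay protocol choice |
| $\tau$ | labeling duration (ms) | 1800 | matched to the acquisition protocol |
| $T_{1b}$ | blood longitudinal relaxation (ms) | 1650 at 3T / 1350 at 1.5T | field-strength dependent literature values |
| $\alpha$ | labeling efficiency | 0.85 | consensus pCASL value; protocols differ, so it is explicit in config and provenance |

All times are stored in milliseconds, exactly as protocols print them; the
implementation converts to seconds inside the equation so that the 6000
pre-factor yields ml/100 g/min. This keeps configuration files verbatim
with respect to protocol sheets while avoiding the classic unit slip that
inflates CBF by a factor of 1000.

### Numerical conventions

* **Invalid voxels.** Wherever M0 is at or below a floor of $10^{-6}$
  times its robust maximum (99th percentile) — air, background, the
  resection cavity — the map carries an `NA` sentinel and a count, never a
  silent zero: dividing by near-zero M0 would fabricate perfusion outside
  the head. The scalar API (`quantify_voxel()`) instead raises on invalid
  input, so programming errors fail loudly while map-level processing
  degrades gracefully.
* **Averaging order.** Pairs are subtracted and averaged *before*
  quantification. The equation is linear in $\Delta M$, so
  quantify-then-average would give the identical result; averaging first
  keeps invalid-voxel bookkeeping in one place.
* **Interleave order.** Series are control-first, recorded in metadata;
  subtraction consults the metadata, so a label-first series cannot
  silently flip sign.
* **No smoothing, no partial-volume correction** anywhere in the pipeline.

## The phantom and the acquisition simulator

`phantom_spec()` describes an ellipsoidal head with a cortical gray-matter
shell, a white-matter core, paired CSF ventricles, optional hyperperfused
spherical lesions (tumor) and an optional spherical resection cavity that
removes both tissue and signal. Default true perfusion is GM 50, WM 20,
CSF 0 ml/100 g/min — the GM value calibrated to healthy-volunteer
gray-matter means near 49 ml/100 g/min; tissue labels are crisp, and the
true CBF field is exactly the class mixture with lesion overrides.

`simulate_acquisition()` generates the series the quantification stage
assumes: M0 is the proton-density template times a smooth multiplicative
coil-sensitivity field; each control volume is M0 plus i.i.d. Gaussian
noise; each label volume is M0 minus the *exact algebraic inverse* of the
quantification equation applied to the true CBF, plus independent noise.
Because the generator inverts the same closed form the pipeline applies,
noiseless simulate-then-quantify is an identity to machine precision —
which turns parameter recovery into a sharp end-to-end test rather than a
statistical one.

The three packaged profiles mirror a multi-scanner reproducibility design
on a shared geometry (240 × 240 × 95 mm FOV covered by a 67 × 69 × 16 grid
at 3.6 × 3.5 × 5.94 mm; the 5 mm slices of the protocol leave small gaps,
which the phantom absorbs into the slice spacing):

* `3t` — 20 label/control pairs, $T_{1b}$ 1650 ms, noise sd 5;
* `1p5t_rad` — 30 pairs, $T_{1b}$ 1350 ms, noise sd 6;
* `1p5t_or` — 40 pairs, $T_{1b}$ 1350 ms, noise sd 8, bias-field
  amplitude 0.3 (two circular surface coils anterior/posterior of the
  head, modelled as a low-order cosine surface in y and z).

No published SNR figures exist for such setups, so the noise levels are
free design constants chosen once: they make single-pair gray-matter SNR
lowest for the operating-room surface-coil profile, the deficit its 40
averages exist to compensate — the same reasoning that motivates more
repeats at lower field strength in practice. Since the bias field
multiplies control, label and M0 alike, it cancels exactly from the
$\Delta M/M_0$ ratio; the simulator exposes this as a testable invariance.

`make_cohort()` adds between-subject physiology: each subject draws one
global CBF scale from a lognormal with mean 1 and CV 0.18 (the "rather
high inter-individual spread" regime of healthy cohorts), applied
identically across scanners — emulating volunteers scanned on all three
machines within an hour, when physiology is shared. Subject variability
is purely a global scale; only cohort-level GM means enter the agreement
statistics, so spatial heterogeneity between subjects would add cost
without information.

### What the simulation does *not* emulate

Rician magnitude noise, physiological (cardiac/respiratory) fluctuations,
motion, EPI distortion and susceptibility artifacts near air–fluid levels,
arterial-transit-time heterogeneity, partial-volume mixing at tissue
boundaries, and anatomical asymmetry. Passing tests therefore certify the
*pipeline arithmetic and its statistical behavior under the stated model*,
not robustness to those acquisition artifacts on real scanners.

## Agreement statistics

Cross-scanner reproducibility is assessed on per-subject scalar GM means
(never voxel-wise, since sessions are not registered to each other):
pairwise Pearson correlations plus per-scanner cohort mean ± sd.

Inter-rater agreement uses the single-measurement intraclass correlation.
The form is deliberately explicit: the default is ICC(2,1) — two-way
random effects, absolute agreement — the standard choice for a fixed pair
of raters judging the same subjects, with `"consistency"` (ICC(3,1)) and
`"oneway"` (ICC(1,1)) as options. The ANOVA mean squares are computed from
explicit sums inside the package and cross-checked in the test suite
against an independent `aov()` decomposition to $10^{-10}$. An
all-identical table makes every mean square zero; that is reported as
ICC 1 with a degeneracy flag rather than 0/0.

The packaged rating fixture (`inst/extdata/table2_ratings.csv`, eight
glioblastoma resections rated 0/1 for residual tumor by modality and
timepoint) is used for count bookkeeping only — its two intraoperative
columns are identical, so it cannot reproduce a non-unit ICC; ICC
correctness is established against the ANOVA oracle instead. The fixture
encodes one patient's postoperative anatomical reading both as initially
rated (1) and as later amended (0, an adjacent-artery partial-volume
effect).

## Residual-tumor rating

The clinical reading "elevated CBF at the cavity rim indicates residual
tumor" is operationalized as: threshold = mean + $z$·sd of CBF over a
reference gray-matter region; supra-threshold voxels inside a shell
(cavity dilated by `shell_mm`, minus the cavity, mm-accurate under
anisotropic voxels) are grouped by 26-connectivity; rating is 1 iff the
largest cluster reaches `min_cluster` voxels. Defaults: $z = 2$,
`min_cluster` 5 voxels, shell 10 mm. These constants are this package's
design choices — no quantitative threshold for "elevated" exists in the
visual-reading literature this emulates — and all are explicit config; on
coarser grids `min_cluster` should be scaled with voxel volume. No
equivalence to expert human readers is claimed.

The reference region is the gray matter of the hemisphere contralateral to
the shell (reflection through the grid's midsagittal plane decides the
side), excluding the shell, falling back to whole GM minus shell when the
contralateral sample is too small. Contralateral tissue is the natural
internal control: it shares the subject's global perfusion level but not
the perioperative pathology.

## Problem sizes and test design

The test suite exercises unit-level properties on a 20 × 20 × 8 phantom at
8 mm isotropic voxels (fast, yet all tissue classes and lesion/cavity
geometry present) and the study-level checks at the full acquisition
geometry: noiseless recovery on all three profiles, 100 noisy replicates
per profile for GM-mean recovery within ±2 ml/100 g/min, 20 replicate
10-subject cohorts for the all-pairwise-$r > 0.9$ regime, and 50
replicates per arm for residual-lesion detection and false-positive rates.
The quantification equation is verified against a 50-digit
arbitrary-precision evaluation on 1000 random parameter sets, and
`scripts/acceptance.R` re-derives all headline quantities from scratch
under a caller-supplied seed.

## Known limitations

* Single-compartment, single-delay quantification only; no
  arterial-transit-time or multi-delay support.
* The phantom's crisp tissue labels mean no partial-volume bias exists to
  detect; real GM means are partial-volume depressed.
* Gaussian additive noise understates low-SNR magnitude-image bias.
* The rating rule's constants are simulation-calibrated conventions, not
  clinically validated thresholds.
* The simulated intraoperative scenario models resection as a spherical
  void with an optional residual rind; real cavities are irregular and
  brain shift deforms the anatomy between timepoints.
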