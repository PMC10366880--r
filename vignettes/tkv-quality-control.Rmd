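---
title: "Quality control for multi-sequence kidney volumetry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control for multi-sequence kidney volumetry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkvqc)
```

## The measurement problem

Total kidney volume (TKV) is the imaging biomarker used to stage autosomal
dominant polycystic kidney disease and to monitor treatment response. A
routine abdominal MRI exam acquires several pulse sequences — here axial
and coronal T2-weighted, axial 3D T1, and axial and coronal SSFP — and each
yields an independent segmentation and hence an independent TKV estimate of
the *same* kidneys. In practice those five numbers disagree, for two
distinct reasons:

1. **Acquisition errors.** Patient breathing during a 2D multi-slice scan
   misregisters slices (duplicating or skipping anatomy); acquisitions
   completed over several breath holds sample the kidney at two different
   positions; composing two overlapping stations double-counts anatomy in
   the overlap; and a mis-planned field of view truncates the kidney.
   These produce outlying TKVs, with deviations up to tens of percent.
2. **Sequence bias.** After removing such errors, small systematic offsets
   remain between sequences (T2-weighted images reading a few percent
   high, axial T1 and coronal SSFP a few percent low), attributable to the
   different contrast mechanisms at the kidney boundary.

`tkvqc` implements the corresponding quality-control pipeline on binary
segmentation masks: per-sequence volumetry, an inter-sequence outlier
screen, geometric detectors and (where possible) corrections for the four
error types, a reference TKV from the error-free sequences, and cohort
agreement statistics. Because no patient masks are distributed, the package
ships a synthetic phantom generator with a complete ground-truth ledger;
every quantitative claim the test suite makes is made against that ledger.

## Volumetry

A `slice_stack` holds ordered binary mask slices with in-plane pixel
spacing, recorded per-slice positions along the stack normal, and the
patient left–right axis convention (patient-left at increasing column
coordinate). Volumes follow the voxel-counting rule

\[ V~[\mathrm{mL}] = N_{\mathrm{voxels}} \times a_{\mathrm{pixel}}
   ~[\mathrm{mm}^2] \times t~[\mathrm{mm}] / 1000, \]

where the effective slice spacing \(t\) is the *median absolute difference
of consecutive recorded positions* when positions are available, else the
nominal spacing. The median makes the spacing robust to the position jumps
left by composing overlaps, and it is what allows a recomposed stack to be
re-thicknessed from its actually recorded positions.

Right and left kidney are separated by 3D connected-component labeling
(26-connectivity, compiled code): the two largest components are kept,
everything else is discarded as stray labeling (remote false-positive
voxels), and the two are assigned right/left by their centroid along the
left–right axis. If the mask is a single fused component the stack is split
at the image mid-plane, mid-plane voxels following their row-wise centroid.
Ties between equal-sized components resolve by raster-scan discovery order,
so labeling is deterministic.

## Screening and the reference TKV

Two sequences disagree when their symmetric percent difference
\(100\,|a-b|/\frac{a+b}{2}\) exceeds a threshold, 10% by default. Any
flagged pair marks the exam for error review. The reference TKV of an exam
is the arithmetic mean of the TKVs of sequences free of (or corrected for)
acquisition errors; with no errors it is the mean of all five. Per-sequence
deviations are signed percent differences from that reference,
\(100\,(x - \mathrm{ref})/\mathrm{ref}\). With several observers the
reference is computed per observer and then averaged.

The denominators are deliberate: the pairwise screen uses the mean of the
pair (symmetric, neither sequence privileged), while deviations use the
reference (so the printed deviation of a sequence average from a printed
cohort mean is reproduced exactly by the same arithmetic).

## Error detection

The study this pipeline automates identified the four error types by
radiologists reviewing orthogonal reformations. The detectors quantify the
same geometric signatures; all thresholds are artifact-defined (the manual
review had none) and are echoed into the output metadata.

* **Discontinuity profile.** For each pair of adjacent slices within a
  kidney's span, the Dice overlap of the kidney masks and the in-plane
  centroid displacement normalized by the kidney's equivalent radius; the
  junction score is \(\max(1-\mathrm{Dice}, \hat d)\), maximized over the
  two kidneys. Junctions are only scored where both slices hold at least
  30% of the kidney's peak slice area — below that, normal apex/base taper
  mimics discontinuity (on clean phantoms junction scores stay below
  ≈0.25, with the largest values near the taper boundary).
* **Breathing motion** (2D sequences only; a 3D acquisition cannot
  misregister within the stack): at least two separated junctions above
  the 0.35 threshold, or an isolated exactly-duplicated adjacent slice
  pair at non-composed positions. The isolation condition matters: a
  smooth body sampled coarsely across its flat equator produces *runs* of
  identical slices, whereas a re-acquired slice duplicates exactly one
  neighbor. Not correctable; the sequence is excluded.
* **Breath-hold mismatch** (axial sequences): exactly one interior
  junction above threshold and dominant (more than twice every other
  score) — two internally coherent halves. If the slice-area profile
  immediately after the junction exactly repeats the profile before it,
  the duplicated slices are identified and deletion restores the stack;
  otherwise anatomy is missing and the sequence is excluded.
* **Composing overlap** (axial): non-monotone or near-duplicate recorded
  positions (closer than 0.25 × median spacing). Pure bookkeeping — no
  mask content is read; if a stack carries no positions the detector
  abstains (`NOT_EVALUABLE`, distinct from "no error"). Correctable by
  recomposition.
* **Incomplete field of view**: kidney mask on the first or last slice, or
  more than 10 voxels of in-plane border contact. Not correctable.

When several detectors fire on one sequence the flag type follows the
precedence composing > incomplete > breath-hold > breathing — the
bookkeeping signals outrank the morphological ones — and the remaining
types stay in the evidence list.

By default the detectors audit *every* sequence of every exam
(`detect_scope = "all"`), not only screened exams. The original workflow
gated a costly human review on the 10% screen; the geometric detectors are
cheap, and an error just below the pairwise threshold still biases the
reference. The screening-gated workload is available as
`detect_scope = "flagged"`. When an exam trips the screen but no detector
explains it, the sequence most deviant from the exam median is excluded as
an `UNEXPLAINED_OUTLIER` (configurable via `exclude_unexplained`).

## Correction

Two repairs exist, and corrected volumes are always recomputed through the
volumetry path, never adjusted arithmetically:

* `recompose_stack()` sorts slices by recorded position, collapses
  position groups closer than 0.25 × median spacing keeping the earlier
  acquisition's slice (the middle one, with a warning, if three coincide),
  and lets the effective spacing re-derive from the surviving positions.
* `delete_duplicate_slices()` removes the re-acquired slices identified by
  the breath-hold detector (the later occurrence; the first stays) and
  re-indexes positions.

Breathing misregistration and truncated kidneys cannot be repaired from
masks alone; those sequences are excluded from the reference, matching the
source study's practice. Corrected composing/breath-hold sequences re-enter
the reference by default; `strict_exclusion = TRUE` reproduces pure
exclusion of everything flagged. Both corrections are idempotent, and on
synthetic cohorts the corrected TKV is closer to the clean digitized value
than the uncorrected one in well over 95% of correctable injections
(checked in the test suite).

## Cohort statistics

All standard deviations are sample (n−1) SDs; this is recorded in the
output metadata. The package reports, mirroring the source study's tables
and figures: per-exam inter-sequence CV before and after exclusion (mean,
median, IQR); the 5×5 mean pairwise percent-difference matrices pre/post;
per-sequence mean signed deviation from the reference with fixed
1-percent-point histogram bins over [−10, 10]; per-sequence inter-observer
CV and maximum pairwise percent difference (cohort medians with IQR); and
Bland–Altman mean difference with ±1.96 SD limits of agreement for every
sequence pair. A Shapiro–Wilk screen on the per-exam CVs decides whether
the headline summary is quoted as mean ± SD or median [IQR]; both are
always computed, and no inferential statistics are exposed.

## The synthetic phantom generator

Each kidney is a *star-shaped* body: a superellipsoid radial function
(semi-axes 30 × 36 × 60 mm before scaling, exponent 2.5) modulated by four
low-frequency smooth bumps (amplitudes 1.5–3%), randomly tilted (±12°
about the L–R axis, ±6° about the A–P axis) and placed either side of the
mid-plane. Star shape is what makes the design exact: the analytic volume
is a spherical quadrature of \(\rho^3/3\) and rasterization is a radius
comparison, so a target true volume is imposed by a single linear rescale.

Key conditions, all configurable in `synthetic_config()`:

* **True TKV** is log-normal (median 1279 mL, sdlog 0.6) clipped to
  400–4000 mL — the clinical range of an ADPKD cohort — split ~50:50
  between kidneys with mild asymmetry.
* **Sequence biases** default to +1.2% (AX T2), +1.8% (COR T2), −1.5%
  (AX T1), +0.4% (AX SSFP), −1.7% (COR SSFP), applied as linear rescales
  by the cube root of the volume factor (exact, resolution-independent).
* **Observer noise** is a log-normal multiplicative volume factor with
  CV 0.8%, drawn per observer × sequence × kidney. Per-observer-only noise
  would cancel from every inter-sequence statistic, which is why the draw
  is per sequence; contouring is not modelled.
* **Geometry**: field of view 320 × 260 × 340 mm; 2 mm in-plane pixels;
  5 mm slices for axial T2/SSFP and coronal SSFP, 4 mm for coronal T2 and
  axial T1. These are coarser than clinical reconstructions; they were
  chosen once so that cohort-scale simulation is practical while
  digitization error stays far below the 1% volumetry tolerance. The
  rasterization grid origin is jittered uniformly within one voxel per
  stack, which makes voxel-center counting an unbiased volume estimator
  and decorrelates digitization error between stacks.
* **Error injection** rates default to the observed per-exam frequencies
  of each error type in each sequence (e.g. breathing in 12/109 axial T2
  exams, incomplete FOV only in axial T1). Signed magnitudes come from
  sign-mixed log-normal distributions whose medians reproduce the observed
  per-type medians (+9.3% breathing in axial T2, +7.8% coronal T2, −4.4%
  pooled breath-hold with −6.1% in axial T1, +8.7% composing, −8%
  incomplete); the sampled target is then *realized* by choosing slices
  whose summed area × spacing best matches it, so every injection carries
  an exactly bookkept expected perturbation in the truth ledger. One
  reported incomplete-kidney value ("29%") is internally inconsistent in
  sign and is not reproduced. Injection granularity is one flank slice,
  well under 1% of TKV at default resolution.
* **Reproducibility**: every stochastic routine draws from a stream seeded
  by a stable byte-hash of (master seed, exam, sequence, purpose), so the
  same seed yields a bit-identical cohort on any platform, and adding or
  reordering unrelated draws cannot perturb an existing cohort. The
  clean-anatomy streams are independent of the error streams, so a cohort
  and its error-free twin share identical underlying anatomy.

What the generator deliberately does not emulate: MR signal, banding or
cyst texture, segmentation-model behavior, real contouring variability,
non-rigid motion within a slice, and scanner-dependent calibration. A
passing test suite therefore demonstrates that the *pipeline logic* —
volumetry arithmetic, screening, the geometric signatures, correction
bookkeeping, statistics — is correct on geometry it fully controls, not
that detector sensitivities would transfer unchanged to clinical masks,
whose discontinuity baseline is rougher than a smooth phantom's.

## Numerical choices and degenerate inputs

* Quadrature for shape volumes uses a 300 × 300 midpoint rule in
  (cos θ, φ); relative error is below 10⁻⁴, negligible against the 1%
  digitization tolerance.
* Empty masks yield zero volumes with a warning, never an error; an
  all-flagged exam has an undefined reference and status `MANUAL_REVIEW`.
* Missing slice positions disable the composing detector (abstention) and
  fall back to nominal spacing in volumetry; missing height yields an
  absent (not zero) height-adjusted TKV.
* CV requires at least two values, Bland–Altman at least two pairs.
* The duplicate-position collapse keeps the earlier acquisition because
  the second station of a composed scan is the one acquired at the
  (potentially different) later breath-hold position.

## Validation scales

The test suite validates the full chain at the scales the design
prescribes: bias recovery and the exclusion property on 200-exam
single-observer cohorts (estimates within ±0.5 percent points of injected
biases; post-exclusion CV within ±0.5 points of the error-free cohort's),
detector confusion at 200 injections per type plus 200 clean stacks
(per-type sensitivity ≥ 0.9, specificity ≥ 0.95), magnitude calibration
medians within ±2 points, a 1 mm digitized ellipsoid against its analytic
volume (≤1%), and exact-recovery checks for both corrections. Unit tests
run the same logic on small hand-built fixtures with brute-force oracles.

## Known limitations

* Detection thresholds were calibrated on this generator's clean-versus-
  injected contrast; clinical masks may need retuning (all thresholds are
  config).
* The breath-hold duplicate finder relies on exact slice-area repetition,
  which integer-pixel re-acquisition produces; sub-pixel interpolation in
  real resampled data would blur it.
* Breathing is exclude-only even though partial repair is sometimes
  conceivable.
* The single-component fallback splits fused kidneys at the image
  mid-plane, which misassigns voxels of a kidney crossing the midline.
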