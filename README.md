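# tkvqc — quality control for MRI-based total kidney volume

Total kidney volume (TKV, right + left kidney, in mL) is the imaging
biomarker used to stage autosomal dominant polycystic kidney disease
(ADPKD) and monitor treatment. An abdominal MRI exam acquires several
pulse sequences — axial/coronal T2, axial 3D T1, axial/coronal SSFP — and
each one yields an independent TKV measurement of the same kidneys. Those
five numbers routinely disagree, for two reasons: **acquisition errors**
(breathing-motion slice misregistration, multi-breath-hold position
mismatch, overlap when two acquisitions are composed, kidneys truncated by
the field of view) and small **sequence biases** (T2 reads a few percent
high, axial T1 and coronal SSFP a few percent low).

`tkvqc` turns that redundancy into a quality-control pipeline operating on
binary segmentation mask stacks (NIfTI):

1. **Volumetry** — per-kidney volume as
   `voxel count × pixel area × slice spacing / 1000`, with right/left
   separation by 3D connected components (two largest kept, stray voxels
   discarded, centroid-based side assignment);
2. **Screening** — flag any sequence pair whose symmetric percent
   difference `100·|a−b|/((a+b)/2)` exceeds 10%;
3. **Detection** — geometric detectors for the four acquisition-error
   types, replacing visual review of orthogonal reformations (Dice /
   centroid-displacement discontinuity profiles, exact-duplicate slices,
   non-monotone recorded positions, border contact);
4. **Correction** — recompose overlapping acquisitions, delete duplicated
   breath-hold slices; exclude what cannot be repaired;
5. **Reference & statistics** — reference TKV = mean of error-free (or
   corrected) sequences; per-sequence signed deviations, inter-sequence
   coefficient of variation pre/post exclusion, pairwise
   percent-difference matrices, inter-observer agreement, Bland–Altman
   limits of agreement.

Because no patient data ship with the package, a **synthetic phantom
generator** produces multi-sequence exams from bumpy-superellipsoid
kidneys with known true volume, configurable sequence biases, observer
noise, and error injection at realistic rates and magnitudes — every
injection carries an exactly bookkept expected TKV perturbation in a truth
ledger, so the whole pipeline is validated end to end.

## Worked example

Simulate a 12-exam cohort with three observers and run the full pipeline:

```r
library(tkvqc)
cfg <- synthetic_config(n_exams = 12, seed = 7, n_observers = 3)
b <- run_pipeline(pipeline_config(simulation = cfg, seed = 7))
print(b$stats)
```

```
TKV cohort statistics over 12 exams
  inter-sequence CV: mean 5.76% pre, 1.55% post exclusion
                     median 5.03% pre, 1.56% post
  per-sequence bias (mean % deviation from reference):
    AX_T2      +1.09%  (n = 10)
    COR_T2     +1.63%  (n = 10)
    AX_T1      -1.31%  (n = 8)
    AX_SSFP    +0.39%  (n = 12)
    COR_SSFP   -1.79%  (n = 12)
  inter-observer CV (median [IQR]): 0.53% [0.31-0.64]
```

Excluding the detected acquisition errors cut the mean inter-sequence CV
from 5.8% to 1.6%, and the recovered per-sequence biases sit near the
generator's injected values (+1.2, +1.8, −1.5, +0.4, −1.7 percent). The
flag table shows what was found and whether it was repairable:

```
    exam_id sequence           error_type correctable
1  exam0002    AX_T2     BREATHING_MOTION       FALSE
3  exam0004    AX_T2    COMPOSING_OVERLAP        TRUE
12 exam0010    AX_T1    INCOMPLETE_KIDNEY       FALSE
...
```

For one flagged exam, the excluded axial T2 sat 42% above the reference
(a breathing-motion duplication); the remaining four sequences agree to
within ±1.7%:

```
exam exam0002 status EXCLUSIONS reference 1395.6
   AX_T2   COR_T2    AX_T1  AX_SSFP COR_SSFP
   41.79     1.71    -0.57     0.55    -1.69
```

With `output_dir` set, `run_pipeline()` writes the artifact bundle
(`volumes.csv`, `flags.json`/`flags.csv`, `corrections.csv`,
`qc_summary.csv`, `error_summary.csv`, `stats.json`, `config.yaml`),
byte-identical for identical inputs and seed. A thin command-line wrapper
lives at `inst/scripts/tkvqc.R` (`simulate` / `run` subcommands).

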