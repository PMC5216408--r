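# alffdev

Developmental analysis of spontaneous brain activity via the amplitude of
low-frequency fluctuations (ALFF) in resting-state fMRI.

## The problem this package addresses

Resting-state BOLD signals fluctuate spontaneously at low frequencies
(0.01–0.08 Hz); the amplitude of those fluctuations — ALFF, the mean
square-root power of a voxel's time series over the band — indexes local
spontaneous neural activity. In neurodevelopmental case-control designs
the interesting questions are factorial: does ALFF differ by diagnosis,
does it change with age, and does the *difference* change with age? And
once a region shows a diagnosis-by-age interaction, does its ALFF follow a
different developmental trajectory in each group, and do the affected
regions' voxel patterns predict symptom severity?

`alffdev` implements the complete analysis chain for a
2 (diagnosis: ASD/TC) × 3 (age cohort: child < 11 y, adolescent 11–< 18 y,
adult ≥ 18 y) cross-sectional design, for analysts who want each stage as
a tested, reusable R function:

1. **Temporal preprocessing** — volume discarding, 8 mm Gaussian
   smoothing, linear detrending, nuisance regression (Friston-24 motion
   expansion + white-matter + CSF signals), ideal 0.01–0.08 Hz band-pass;
   gross-motion exclusion (3 mm / 3°) and mean framewise displacement.
2. **ALFF** — voxelwise mean √power over the band, standardized by the
   whole-brain mean: for voxel series *x* with one-sided power spectrum
   *P(f)*, `ALFF = mean over f in [0.01, 0.08] of sqrt(P(f))`, divided by
   the in-mask mean.
3. **Group inference** — voxelwise ANCOVA with sum-to-zero factor coding
   and gender/FIQ/mean-FD covariates; partial (Type-III) F statistics and
   partial η² per effect; F → one-tailed Z; Gaussian-random-field
   cluster-extent correction (voxel Z > 2.33, cluster-level α = 0.05) with
   residual-based smoothness estimation; Bonferroni post-hoc two-sample
   t-tests (α = 0.05/3 = 0.017).
4. **Age trajectories** — per-group quadratic fits
   `alff ~ b0 + b1·age + b2·age²` with overall-model F tests on (2, n−3) df.
5. **Symptom prediction** — linear ε-insensitive support-vector regression
   on the voxelwise ALFF of all significant clusters, leave-one-out
   cross-validation with fold-internal feature scaling, and a permutation
   null (p = proportion of shuffles with R_perm > R).
6. **A synthetic-cohort generator** — seeded 4D volumes, motion traces,
   masks and phenotype tables with planted regional effects, so the whole
   chain runs and can be validated without any imaging data.

## Worked example

```r
library(alffdev)

cfg <- run_config(seed = 1, n_perm = 200)  # default 128-subject cohort
run <- run_all(cfg)
print(run)
#> <alffdev_run>
#>   128 subjects, 4512 in-mask voxels
#>   voxel Z > 2.326, extent >= 27 voxels (FWHM 2.13x2.11x2.13 vox)
#>   diagnosis: 1 significant cluster(s)
#>   interaction: 2 significant cluster(s)
#>   trajectory p: TC 9.334e-09, ASD 0.5457
#>   prediction ados_comm: R = -0.256, p_perm = 0.94
#>   prediction ados_social: R = 0.687, p_perm = 0
#>   prediction ados_stereo: R = -0.065, p_perm = 0.61
```

Reading the output: the voxelwise ANCOVA on standardized ALFF maps found
one diagnosis cluster (covering the planted precuneus and middle-occipital
regions, where ASD amplitude is lower at every age) and two
diagnosis-by-age interaction clusters, the largest being the planted
medial-prefrontal region. ALFF in the interaction region follows a
quadratic age trajectory in the TC group (overall F test p ≈ 9e-09) but
not in ASD (p ≈ 0.55), and the voxel pattern across all significant
clusters predicts the ADOS social subscore in the ASD group (LOOCV
R = 0.69, permutation p < 1/200, surviving the 0.017 Bonferroni gate)
while the two uncoupled subscales do not. Cluster tables, fits and per-map statistics
sit in `run$clusters`, `run$trajectory`, `run$prediction`, `run$stats`;
`summary(run)` returns the same as a JSON-ready list, and setting
`out_dir` in `run_config()` writes NIfTI maps, TSV cluster tables and a
summary JSON.

Individual stages are plain functions on plain objects — e.g.
`compute_alff_voxel(ts, tr_s = 2)`, `fit_quadratic(ages, alff)`,
`permutation_test(X, y, n_perm = 1000, seed = 1)` — and a thin CLI over
them lives at `inst/cli/alffdev.R` (subcommands `simulate`, `preprocess`,
`alff`, `run-all`).

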