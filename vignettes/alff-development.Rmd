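---
title: "Modelling developmental change in spontaneous brain activity with ALFF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling developmental change in spontaneous brain activity with ALFF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alffdev)
```

# The scientific problem

Resting-state fMRI measures spontaneous low-frequency fluctuations (LFF) of
the BOLD signal. The amplitude of these fluctuations (ALFF) — the mean
square-root power of a voxel's time series inside a low-frequency band,
conventionally 0.01–0.08 Hz — indexes the intensity of local spontaneous
neural activity. In neurodevelopmental conditions such as autism spectrum
disorder (ASD), the question is not only *whether* ALFF differs between
cases and controls but *how the difference changes with age*: a
cross-sectional 2 (diagnosis) × 3 (age cohort: child < 11 y, adolescent
11–< 18 y, adult ≥ 18 y) factorial design separates stable diagnosis effects
from diagnosis-by-age interactions, and a quadratic model of ALFF against
age within each group characterizes the developmental trajectory itself.

`alffdev` implements that complete analysis chain as reusable, tested
functions, together with a seeded synthetic-cohort generator so every stage
can be exercised end to end without access to imaging data.

# Pipeline stages and their models

## Temporal preprocessing

`preprocess_subject()` applies, in a fixed and logged order:

1. **Volume discarding** — the first 10 volumes are dropped (magnetization
   equilibration), synchronously from the image and the motion trace.
2. **Spatial smoothing** — separable isotropic Gaussian kernel,
   FWHM 8 mm, σ = FWHM/(2√(2 ln 2)) per axis converted to voxels.
   Zero-padding outside the grid; no masked renormalization.
3. **Linear detrending** — least-squares removal of intercept + ramp.
4. **Nuisance regression** — 26 regressors: the Friston-24 expansion of the
   six rigid-body parameters (R, R², R(t−1), R(t−1)², lag row zero-filled)
   plus mean white-matter and CSF signals, extracted from the smoothed,
   detrended data. Rank-deficient nuisance sets (e.g. an all-zero motion
   trace) drop dependent columns with a warning rather than failing.
5. **Band-pass filtering** — an ideal (brick-wall) frequency-domain filter
   on 0.01–0.08 Hz. The ideal filter makes a useful cross-module identity
   exact: ALFF over the band is invariant to prior filtering over the same
   band, which the test suite asserts to 1e−10.

Registration steps (slice timing, realignment, normalization) are out of
scope: inputs are assumed to share a grid, with motion supplied as
parameter files. Whether smoothing preceded the temporal steps in the
original toolbox chain is not recoverable from the usual method
descriptions; the order above is a documented, fixed choice.

Motion quality control: a run is excluded when any translation exceeds
3 mm or any rotation 3°. Framewise displacement is the sum of absolute
backward differences of the translations plus 50 mm times the rotations
(the standard sphere-arc convention); FD of the first frame is 0 and the
mean is taken over all frames. Mean FD enters the group model as a
covariate; no frame censoring is performed.

## ALFF

`compute_alff_voxel()` transforms each series with an FFT and averages the
square root of the one-sided power spectrum over bins with
0.01 ≤ f ≤ 0.08 Hz (band edges inclusive). The power convention is
|X<sub>k</sub>|²/N with doubling of non-DC, non-Nyquist bins, chosen so
Parseval's identity Σ power = Σ x² holds exactly — any fixed convention
works because `standardize_global_mean()` divides each map by its in-mask
mean (the "whole-brain" mean is taken over the brain mask, not the grid:
out-of-brain zeros would bias it). No windowing is applied. A brute-force
O(N²) DFT oracle in the test suite pins the implementation to 1e−10.

## Group inference

`build_design()` codes the factors sum-to-zero (effects coding) — the
factorial convention of statistical parametric mapping — with mean-centered
gender, FIQ and mean-FD covariates: 9 columns, error df n − 9 (119 for the
128-subject default cohort). `voxelwise_ancova()` computes partial
(Type-III) F tests per effect from reduced-model comparisons,
F = ((SSE<sub>r</sub> − SSE<sub>f</sub>)/df₁)/(SSE<sub>f</sub>/df₂), with
partial η² = SS<sub>eff</sub>/(SS<sub>eff</sub> + SSE<sub>f</sub>); the
identity partial η² = F·df₁/(F·df₁ + df₂) is asserted numerically. In
balanced designs without covariates Type-III and sequential tests coincide
(tested). F maps are converted to one-tailed Z equivalents (F is
one-sided); Z > 2.33 corresponds to voxel p < 0.01.

Cluster-level correction follows Gaussian random-field theory:

* smoothness is estimated from the per-voxel-standardized model residuals,
  FWHM = √(4 ln 2 / var(∂e/∂axis)) per axis from first differences —
  residual-based estimation is the random-field standard;
* the expected cluster count E[m] is the expected Euler characteristic,
  summed over resel dimensions 0–3 with Worsley lattice resel counts
  (the lower-dimensional boundary terms matter on small masks);
* cluster size follows the stationary-field approximation
  P(n ≥ k) = exp(−βk^{2/3}), β = (Γ(5/2)/E[n])^{2/3} with
  E[n] = S·Φ̄(z)/E[m];
* the extent threshold is the smallest k with familywise probability
  1 − exp(−E[m]·P(n ≥ k)) ≤ 0.05.

A Monte-Carlo experiment in the test suite (500 simulated smooth null
fields on the default mask) checks that this machinery delivers an
empirical familywise cluster error of 0.05 ± 0.02. Connected components
use face (6) connectivity by default, configurable to 26 — the choice is
rarely stated in publications and is documented here instead.

Post-hoc comparisons are pooled-variance two-sample t-tests per age cohort
with Bonferroni control over the three cohorts (per-comparison α = 0.05/3
≈ 0.017, strict inequality), plus a pooled all-ages comparison at α = 0.05.

## Age trajectories

`fit_quadratic()` regresses ROI ALFF (the mean standardized ALFF over the
cluster's voxels; mean rather than peak is a documented choice) on
[1, age, age²] within each diagnosis group. Ages are mean-centered before
squaring to control collinearity; coefficients are reported in the raw-age
basis. Significance is the overall model F against the intercept-only
model with (2, n−3) df — the published wording ("significance level of the
models") points at the overall test rather than the quadratic coefficient
alone, and that is what is implemented.

## Symptom prediction

`build_feature_matrix()` pools the voxelwise standardized ALFF values of
all significant diagnosis and interaction clusters (one pooled matrix;
modelling per region is possible by passing cluster subsets) for the ASD
subjects. `loocv_svr()` runs leave-one-out cross-validation of a linear
ε-insensitive support-vector regression: per fold, features are z-scored
with training-fold statistics only and the target is centered with the
training-fold mean — the held-out subject contributes nothing to either,
and a constructed counterexample in the tests shows predictions change
when global (leaky) scaling is used instead.

The solver is an L2-regularized L1-loss SVR trained by dual coordinate
descent in the LIBLINEAR style (shrinking, shuffled deterministic sweeps),
with C = 1 and ε = 0.1 fixed as defaults of the era's toolboxes. Warm
starts across folds and an exact row-space projection of p > n folds (the
Gram matrix, hence the solution, is unchanged) keep the permutation test
affordable; the stopping tolerance is 1e−3 for single fits and 1e−2 inside
permutation loops, both at least an order of magnitude tighter than the
0.1 shipped as that solver family's default. An independent
interior-point QP solution of the same dual pins the solver to 1e−4 in the
tests.

`permutation_test()` shuffles the target, reruns the *entire* LOOCV
procedure per draw, and reports p = #(R<sub>perm</sub> > R)/n<sub>perm</sub>
with a strict inequality, following the published definition verbatim (the
+1/(n+1) estimator is available via `add_one = TRUE`). Bonferroni control
over the three ADOS subscales uses α = 0.05/3. Because clusters are
selected on the same subjects used for prediction, the analysis inherits
the circularity of the published design; it is reproduced deliberately and
flagged here as a caveat.

# The synthetic cohort

`simulation_config()` + `generate_dataset()` emulate the study conditions:
TR 2 s, 180 volumes, a 22 × 26 × 22 grid of 3 mm voxels with an
ellipsoidal brain mask (~4500 voxels; a desk-scale stand-in for the MNI
grid — voxelwise cost is linear in voxels and nothing in the method
depends on absolute brain size), cell sizes 18/20, 28/26, 18/18
(128 subjects), gender proportions and FIQ distributions per cell matching
the published sample table, and ages uniform within cohort intervals with
the 3-SD restriction enforced by resampling.

Signals are built, not imaged: in-brain voxels receive white noise
(SD 1), and each planted region adds a spatially coherent sum of K = 5
equal-amplitude sinusoids on random in-band DFT bins (of the post-discard
series length) with random phases. On-bin sinusoids give the planted
amplitude a closed-form relation to ALFF — ALFF = A·√(K·N)/n_band — which
the tests verify exactly at zero noise. Three regions carry the effects:

* **mPFC** (81 voxels): TC amplitude 0.58 + 0.00105·(age − 27)² — higher
  in children than in adolescents and adults — against a flat ASD
  amplitude of 0.76: a diagnosis-by-age interaction and a TC-specific
  quadratic trajectory;
* **precuneus** (33 voxels) and **MOG** (33 voxels): TC 0.90 vs ASD 0.78
  at all ages: a stable diagnosis main effect (ASD lower).

Per subject, each region's amplitude is jittered multiplicatively
(SD 0.18, truncated at ±0.5). ADOS social scores for ASD subjects are a
linear combination of the subject's three regional amplitudes plus
Gaussian noise, rounded and clipped to 0–14 (resulting mean ≈ 7.8,
SD ≈ 2.6); communication and stereotyped scores are drawn independently,
so only the social subscale carries planted brain-behaviour coupling.
Motion traces are Gaussian random walks (step SDs 0.03 mm / 3·10⁻⁴ rad,
mean FD ≈ 0.11 mm, matching the published sample); they exist to exercise
the Friston-24 expansion, FD computation and the exclusion rule, not to
corrupt the images. `generate_roster()` additionally plants exactly 7
gross-motion subjects (a deterministic 4 mm drift) and 49
covariate-unmatched extras, so `cohort_filter()` recovers 128 of 184
candidates by rule.

**Calibration of the planted effect sizes.** The generator's contract
includes recoverability: with default settings the interaction cluster
must overlap the planted mPFC set (Dice > 0.5) in the large majority of
seeds, and the social-score coupling must survive the Bonferroni gate
while the uncoupled subscales do not. Two properties of the pipeline
drive the calibration. First, smoothing spreads a region's oscillation
into a halo, and the F-statistic's own sampling noise moves the realized
in-region Z by roughly ±1 between seeds: too weak a contrast and some
realizations produce no suprathreshold cluster at all; much above Z ≈ 5
and the halo itself crosses the Z > 2.33 cluster-forming threshold so the
cluster balloons (Dice falls even though detection is perfect). The
contrasts therefore target in-region Z ≈ 4–4.5, the middle of that
window; the small 33-voxel diagnosis regions additionally need
near-complete voxel coverage to clear the ~27-voxel extent threshold.
Second, voxelwise LOOCV SVR at the fixed C = 1 retains only part of the
latent brain-behaviour correlation, so the coupling is set near latent
R ≈ 0.9 to yield observed LOOCV R ≈ 0.5–0.8. Both choices were fixed
from pilot runs of the generator before the acceptance checks were
frozen. One caveat is inherent rather than tunable: the permutation test
is calibrated, so each *uncoupled* subscale still has the nominal ~2%
chance per dataset of a Bonferroni-significant p by chance (the null
LOOCV-R distribution on low-effective-dimension cluster features is wide,
SD ≈ 0.2), and repeated-seed recovery checks must budget for it.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: hemodynamic response shapes, physiological
(cardiac/respiratory) noise, motion artifacts *in the images* (traces are
supplied but do not corrupt voxels), anatomical geometry, spatial
normalization error, multi-site effects, and non-Gaussian between-subject
heterogeneity. Recovery results demonstrate the *pipeline's* correctness
and calibration, not field-strength claims about ASD.

A further property worth knowing: global-mean standardization couples
every voxel to the planted regions (a subject with strong regional
amplitudes has a larger global mean, depressing all other standardized
values). This imprints a weak anti-correlated group pattern outside the
planted regions that can occasionally reach cluster significance. It is a
real property of the published standardization, not a simulation bug;
recovery checks therefore compare the largest cluster against the planted
set.

# Numerical choices and degenerate inputs

* Band-edge bins are included (low ≤ f ≤ high); a series too short to
  contain an in-band bin raises an error naming the minimum length.
* `f_to_z()` computes the F tail on the log scale, so Z stays finite for
  F in the thousands.
* Flat residual maps make the smoothness estimator error out ("infinite
  FWHM") rather than return a degenerate threshold.
* All-zero motion traces survive preprocessing: the rank-deficient
  Friston-24 block is dropped with a warning.
* Every randomized operation takes an explicit seed; per-stage seeds are
  derived deterministically from one master seed, and generators restore
  the caller's RNG state.
* The SVR coordinate order is shuffled with a fixed xorshift stream:
  randomized enough to converge fast, deterministic across runs and
  platforms.

# Problem sizes used in the checks

The test suite and the acceptance script run the full default conditions —
128 subjects, 180 volumes, the 22 × 26 × 22 grid — for the end-to-end
recovery checks (10 seeds, permutation tests at 200 draws per subscale),
and reduced grids (e.g. 14 × 16 × 14, 80 volumes) for per-operation unit
tests. Null calibrations use 2000 independent voxels for the F-distribution
check and 500 simulated smooth fields for the cluster-level familywise
error check. The acceptance script's single-seed headline run uses the
full 1000 permutations.

# Known limitations

* GRF cluster inference assumes a stationary, reasonably smooth Gaussian
  field; on masks only a few FWHM across the approximation degrades. The
  Monte-Carlo calibration check covers exactly the default geometry.
* The quadratic trajectory model is descriptive; no spline or piecewise
  growth model, and no formal between-group test on trajectory
  coefficients (groups are fit separately, as published).
* Prediction reuses the cluster-selection subjects (circular, as
  published); out-of-sample claims would need an independent cohort.
* fALFF, ReHo, frequency sub-bands, scrubbing and TFCE-style permutation
  cluster inference are out of scope.
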