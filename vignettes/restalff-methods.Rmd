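---
title: "Methods: ALFF, cluster inference and seed connectivity in restalff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ALFF, cluster inference and seed connectivity in restalff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`restalff` implements the classical resting-state fMRI analysis chain
built around the amplitude of low-frequency fluctuation (ALFF): temporal
and spatial preprocessing of 4D BOLD volumes, voxel-wise standardized
ALFF, two-sample group maps with Monte-Carlo cluster-extent correction,
seed-based functional connectivity with Fisher z-transformation, and
partial correlation of regional ALFF with clinical covariates. A
synthetic two-group cohort simulator with planted, known effects provides
the calibration and recovery evidence for the whole chain. This vignette
documents the statistical model, the conventions and defaults, the
numerical choices, and what the synthetic studies do and do not
establish.

## Preprocessing

The pipeline assumes volumes already aligned on a common grid (spatial
normalisation is outside this package's scope; the simulator emits data
in a common space by construction). Stages run in this order:

1. **Dummy-frame removal.** The first `n_discard = 5` frames are dropped
   to let magnetisation reach equilibrium; with the default 155 acquired
   frames (a 5 min 10 s scan at TR = 2 s), 150 frames remain.
2. **Motion screening.** Subjects whose six-parameter rigid-body trace
   exceeds 1 mm translation or 1° rotation on *any* axis at *any* frame
   are excluded. The rule is strictly "greater than": a peak of exactly
   1 mm passes. Screening excludes subjects; it never censors frames.
3. **Spatial smoothing.** Isotropic Gaussian, FWHM 8 mm
   (σ = FWHM / (2√(2 ln 2))), applied separably per axis with
   replicate-nearest boundary handling so a constant image is exactly
   preserved and there is no rim darkening inside small masks. The
   boundary mode matters for the small synthetic grids used here;
   zero-padding would darken the mask edge.
4. **Linear detrending.** Per-voxel least-squares removal of intercept
   and slope; residuals are orthogonal to both regressors.
5. **Band-pass filtering** to 0.01–0.08 Hz. The filter is an *ideal*
   (brick-wall) frequency-domain filter: DFT coefficients whose
   frequency lies in the closed band are kept, everything else including
   DC is zeroed. An ideal filter rather than (say) a Butterworth design
   keeps the band edges exact, which makes the ALFF band average and the
   filter mutually consistent: filtering before ALFF is provably a no-op
   (asserted in the test suite), so ALFF may be computed on the
   detrended series directly.

Band-limited operations (filtering, ALFF, and the simulator's signal
synthesis) are evaluated through a cached real-DFT basis restricted to
the in-band bins rather than full FFTs. The two formulations are
mathematically identical (the tests compare against `stats::fft`
directly); the restricted basis is simply much faster at the awkward
series length of 150 and a few thousand voxels.

## ALFF and its standardization

For a series of length T sampled at TR, the single-sided amplitude at
DFT bin k (0 < k < T/2) is defined as (2/T)·|X_k|, so that a
unit-amplitude sinusoid sitting exactly on a bin has amplitude 1. ALFF
is the mean amplitude over the bins whose frequency k/(T·TR) lies in the
closed band [0.01, 0.08] Hz. At T = 150, TR = 2 s the frequency
resolution is 1/300 Hz and the band covers bins 3–24, i.e. 22 bins; a
unit sinusoid on one of them yields ALFF = 1/22.

The normalisation constant of "the square root of the power spectrum" is
a convention; any fixed choice cancels when each subject's map is
divided by its global (in-mask) mean. We fix the convention above
because it makes unit tests directly interpretable. The identity
`sum(amp²)·T/2 = Σ(x − x̄)²` (DC and Nyquist handled separately)
validates it against Parseval's theorem in the suite.

Standardized ALFF (mALFF) divides every in-mask voxel by the in-mask
mean, making each subject's map average exactly 1 and removing global
amplitude scale differences between subjects.

## Group statistics and cluster-extent correction

Voxel-wise group comparison uses the pooled-variance (Student) two-sample
t statistic with df = nA + nB − 2, the convention of the classical SPM /
REST pipelines; the sign is group B − group A, so with controls as A,
negative t means reduced in patients. At α = 0.01 two-tailed and
df = 28 the critical value is 2.7633 (df = 30 gives 2.750); the package
always derives df from its own inputs.

Cluster-extent correction is Monte-Carlo ("AlphaSim-style"): each
iteration fills the volume with unit Gaussian noise, smooths it with the
*same* FWHM as the analysis (the paper-style protocol takes the applied
smoothing as the smoothness; residual-based smoothness estimation is a
non-goal), re-standardises the in-mask values, thresholds two-tailed at
the voxel p, and records the largest connected cluster. The minimum
extent k_min is the smallest k whose null exceedance probability is at
most the family-wise α (0.05). Clusters of size ≥ k_min survive — the
printed convention "cluster > 16" corresponds to k_min = 17. Default
connectivity is 6 (faces), configurable to 18 or 26; Monte-Carlo
dialects differ on this point and face connectivity is the conservative
choice. Positive and negative suprathreshold voxels are labelled
separately so adjacent clusters of opposite sign never merge. Peak
reporting breaks exact |t| ties by the smallest voxel index, making
reports deterministic. A Bonferroni voxel-level option
(α / n-mask-voxels) stands in for family-wise-error voxel correction;
random-field theory is out of scope.

Because the ALFF maps inherit their spatial correlation from smoothed
series through a nonlinear (amplitude) transform, they are slightly
*rougher* than the Gaussian null used for calibration; the Monte-Carlo
threshold is therefore mildly conservative for ALFF maps, which the null
calibration study confirms empirically (family-wise false-positive rate
below the nominal 5%).

## Seed-based connectivity

Seeds are spheres of diameter 6 mm (read literally as diameter, radius
3 mm, configurable) centred either on planted ground-truth regions or on
the peak group-difference voxel of the ALFF map. A sphere resolves to
every in-mask voxel whose centre lies within the radius (inclusive); on
a 3 mm grid a 6 mm sphere centred on a voxel centre is 7 voxels.

Per subject, the seed mean series is extracted from the fully
preprocessed data, the six motion parameters (plus intercept) are
regressed out of the seed and of every voxel series, and the Pearson
correlation map is Fisher z-transformed. Averaging the seed before
regressing is equivalent to averaging residuals (regression is linear;
asserted in tests). Only motion is regressed — no global-signal or
tissue regressors, matching the modelled protocol. Within-group maps use
a one-sample t against zero; the between-group map reuses the two-sample
machinery and correction above. Seed-sphere voxels are excluded from
between-group cluster reports to avoid trivial self-connectivity
findings. Correlations of exactly ±1 (the seed's own voxels) are clipped
to |r| = 1 − 1e−7 before the z-transform, with a warning.

## Clinical association

Regional mean standardized ALFF in the dependent group is related to
drug-use duration (months) and daily dose (g/day) by partial
correlation: both variables are residualised on an intercept plus the
covariates (age, education, nicotine), the residuals are correlated, and
p comes from t = r·√((n−2−k)/(1−r²)) on n−2−k df (n = 17, k = 3 gives
df = 12). Residualisation is numerically equivalent to the
precision-matrix formulation; the single-covariate recursive identity is
the independent oracle in the tests. Multiple drug-use variables are
reported without multiplicity correction by default (a Bonferroni flag
exists). Demographic group tests use the pooled-variance t from either
raw values or printed mean/SD/n summaries — the two agree exactly when
the summaries come from the raw data; pooled rather than Welch variance
is the default because it reproduces the published demographic p-values
from their rounded summaries more closely (Welch remains available).
From summaries rounded to one decimal, age and nicotine p-values
reproduce to ±0.01; the education row only to ±0.03, which is an input
rounding limit, not a formula discrepancy.

## The synthetic cohort generator

Each voxel's series is

    x(t) = s·a_v · f_v(t) + AR1_v(t) + slope_v · t

where `f_v` is band-limited unit-variance Gaussian noise (independent
complex-Gaussian DFT coefficients on the in-band bins — the same
distribution as ideally filtered white noise, and exactly matched to the
analysis band), `a_v` is the region amplitude factor, the AR(1) noise
has marginal SD `noise_sd` and lag-1 coefficient `ar1_coef` with a
stationary start, and the drift slope is N(0, `drift_slope_sd`) per
voxel. Planted amplitude effects multiply `a_v` by `amplitude_ratio`
inside a spherical region for group B only; with all ratios 1 and equal
connectivity weights the two groups are exchangeable by construction.
Planted connectivity mixes a shared band-limited latent signal into seed
and target voxels as `√(1−w²)·own + w·shared` with group-specific weight
w, so w = 1 gives exactly unit correlation and the per-voxel variance is
unchanged.

Defaults mirror the modelled study: TR 2 s, 155 acquired frames, groups
of 15 and 17, 3 mm isotropic voxels, 0.01–0.08 Hz fluctuations. Values
the protocol does not fix were chosen once on field-realism grounds and
not revisited: fluctuation SD 1 and noise SD 1 (in-band SNR of order
one, typical of resting-state data); AR(1) coefficient 0.3 (moderate
scanner-noise autocorrelation at TR 2 s); drift slope SD 0.005 signal
units per frame (a few-percent variance contribution, comparable to
slow scanner drift after trend removal); motion random-walk step 0.02 mm
and 0.02° per frame, which keeps essentially all subjects below the 1 mm
screen (a flag injects a violator to exercise the exclusion rule). The
planted test points are an amplitude ratio of 1.5, connectivity weights
0.8 vs 0.2, and an amplitude–duration latent correlation of 0.8 with a
between-subject amplitude CV of 0.30. The CV is sized so that
between-subject amplitude spread dominates spectral-estimation noise
and smoothing dilution, making the *realized* correlation between
measured regional mALFF and duration match the documented |r| ≈ 0.8
condition (the latent correlation is its ceiling; a much smaller CV
would attenuate the measured association well below the condition it
is meant to plant). Group-B duration is drawn as 81.5 ± 33.9 months and
dose as 0.71 ± 0.35 g/day, truncated at zero, both coupled negatively
to the amplitude latent. Because the subject-level spread that creates
the coupling also inflates group-B variance in the group contrast, the
pure-ratio condition (`"amplitude"` preset) and the coupled condition
(`"clinical"` preset) are deliberately separate: each validation study
plants exactly the effect it measures. The brain mask is a
centred ellipsoid with semi-axes 0.45 of each grid dimension; the grid
centre sits at the world origin of an axis-aligned RAS affine (NIfTI
convention, 0-based voxel indices).

What the simulator does *not* emulate: scanner artifacts (spikes,
ghosting), physiological noise, susceptibility distortion, anatomical
tissue structure, or realistic spatial autocorrelation beyond what the
analysis smoothing induces. Passing recovery tests therefore show the
chain is correct and calibrated *under its own assumptions*, not that it
would behave identically on real scans.

## Study problem sizes

The calibration and recovery studies are sized to be informative yet
quick on a single CPU:

- **Null calibration**: 20 replicate no-effect cohorts on the reference
  24×24×18 grid (3 mm voxels, 15 + 17 subjects), Monte-Carlo extent from
  1000 iterations. Reported: fraction of empty corrected reports
  (expected ≥ 95% at family-wise α = 0.05).
- **Amplitude recovery**: 25 replicates on a 16×16×12 grid with the
  pure 1.5× region planted; detection = a surviving cluster of the
  correct sign peaking inside the planted radius.
- **Connectivity recovery**: 25 replicates, weights 0.8 vs 0.2, target
  region detection in the between-group z map.
- **Association power**: 50 replicates of the 17-subject dependent
  group; significance of the duration partial correlation at p < 0.05
  with the correct (negative) sign. Only the dependent group is
  simulated at full size here since controls do not enter the statistic.

The smaller recovery grid scales the planted-region coordinates
proportionally and keeps every region inside the mask; ALFF, correction
and connectivity machinery are identical across grids.

```{r studies}
library(restalff)
null_res  <- study_alff_null(n_replicates = 20, n_iter = 1000, seed = 1)
mean(null_res$empty)           # fraction of silent null cohorts
alff_res  <- study_alff_recovery(n_replicates = 25, seed = 2)
mean(alff_res$detected)        # planted-region detection rate
```

## Numerical choices and degenerate inputs

- Band-edge inclusion is closed ([low, high]) with a 1e−9 Hz tolerance
  absorbing floating-point edges; no interpolation between bins.
- Zero pooled variance in a two-sample map gives t = 0 with a warning;
  zero variance in a one-sample map masks the voxel (NA) with a warning;
  zero-variance voxels in a correlation map give r = 0 with a warning.
- Rank-deficient nuisance or covariate designs drop dependent columns
  (QR pivoting) with a warning rather than failing.
- Degenerate grids (< 8 voxels per axis), scans shorter than one cycle
  of the lowest band frequency, empty spheres, empty ROIs, and groups
  of fewer than 2 subjects are rejected with informative errors.
- All stochastic components (simulator, Monte-Carlo null) are driven by
  explicit integer seeds; rerunning any configuration reproduces every
  numeric output bit-identically.

## Known limitations

- The Monte-Carlo null assumes the analysis FWHM describes the map
  smoothness; for ALFF maps this is mildly conservative (see above), and
  for heavily autocorrelated real data it may not be.
- Bonferroni is the only voxel-level family-wise option; random-field
  theory and permutation inference are out of scope.
- The MNI→Talairach conversion is the conventional piecewise-linear
  mapping and inherits its known approximations.
- fALFF, frequency sub-bands, frame censoring, global-signal regression
  and slice-timing correction are deliberately not implemented.
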