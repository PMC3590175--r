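# restalff

Resting-state fMRI analysis around the **amplitude of low-frequency
fluctuation (ALFF)**, for researchers who want the classical
ALFF/seed-connectivity group pipeline as tested, scriptable R functions:

- temporal/spatial preprocessing of 4D BOLD volumes (dummy-frame
  removal, 1 mm/1° motion screening, 8 mm FWHM Gaussian smoothing,
  linear detrending, ideal 0.01–0.08 Hz band-pass);
- voxel-wise ALFF with global-mean standardization (mALFF);
- two-sample voxel-wise group maps with Monte-Carlo (AlphaSim-style)
  cluster-extent correction and TSV cluster reports;
- seed-based functional connectivity from 6 mm spheres with head-motion
  nuisance regression, Fisher z-transformation, and within-/between-group
  statistics;
- partial correlation of regional ALFF with clinical covariates
  (e.g. drug-use duration and dose, controlling age, education,
  nicotine);
- a synthetic two-group BOLD cohort simulator with *planted* amplitude
  and connectivity effects, used to calibrate and validate the whole
  chain.

## The statistics in brief

For a voxel series of length T at repetition time TR, with DFT
coefficients X_k, the single-sided amplitude at bin k is (2/T)·|X_k|,
and

> ALFF = mean of (2/T)·|X_k| over bins with k/(T·TR) ∈ [0.01, 0.08] Hz.

mALFF divides each subject's map by its within-mask mean. Group
comparison is the pooled-variance two-sample t (df = n₁ + n₂ − 2) at
every voxel, thresholded two-tailed at p < 0.01 and filtered by the
Monte-Carlo minimum cluster extent k_min that holds the family-wise
false-positive rate at 0.05. Seed connectivity is the Pearson
correlation of a sphere's mean series with every voxel after regressing
out the six motion parameters, mapped through z = atanh(r). Clinical
association is the partial correlation of regional mALFF with a use
variable after residualising both on the covariates, with
t = r·√((n−2−k)/(1−r²)) on n−2−k df.

## Worked example

Simulate a 15 + 17 cohort with one planted region whose band amplitude
is 1.5× larger in group B and couples to drug-use duration, run the
full pipeline, and look at the corrected group-difference report:

```r
library(restalff)

cfg <- pipeline_config(
  sim = simulation_preset("clinical", seed = 7),  # 24x24x18 grid, 3 mm
  n_iter = 1000, rng_seed = 7)
res <- run_pipeline(cfg)

res$k_min
#> [1] 26
res$t_crit
#> [1] 2.749996
res$alff_report
#>   seed x_mm y_mm z_mm   peak_t cluster_size sign
#> 1 <NA>  7.5 13.5  1.5 5.555563           52    1
res$association
#>   variable  r_partial          p df  n significant
#> 1 duration -0.7070856 0.00468340 12 17        TRUE
#> 2     dose -0.5702385 0.03323601 12 17        TRUE
```

The Monte-Carlo null (1000 iterations on this mask at 8 mm FWHM) demands
clusters of at least 26 voxels; the voxel threshold is the two-tailed
t critical value at p = 0.01 with df = 30. Exactly one cluster survives,
positive (group B > group A), 52 voxels, peaking at (7.5, 13.5, 1.5) mm —
one voxel off the planted centre (9, 12, 3). The association table shows
the planted negative coupling between regional mALFF and drug-use
duration recovered at n = 17 with df = 12 after controlling age,
education and nicotine. On a null preset (`"null"`) the same cluster
report is empty in ≥ 95% of replicates.

Per-seed connectivity reports (`res$fc_report`) come from the same run.
A shell entry point with the same options lives at
`inst/scripts/run_pipeline.R`.

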