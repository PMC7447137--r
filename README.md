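# daysgained

Days Gained (DG) response scoring and survival analysis for longitudinal
volumetric tumor measurements.

## The problem

Glioblastoma growth kinetics differ enormously between patients, so a fixed
size-change criterion treats a fast and a slow tumor as if the same imaging
change meant the same thing. Under bevacizumab the problem compounds:
contrast enhancement can fade because the blood–brain barrier normalises
(pseudo-response), not because tumor burden fell. DG scores each patient
against their *own* projected growth instead: from two pre-treatment scans a
patient-specific **untreated virtual control** (UVC) is extrapolated, and
response is the number of days of untreated growth the therapy "bought".

Segmented volumes are reduced to spherically equivalent radii,
`r = (3V / 4π)^(1/3)`, the scale on which untreated glioma growth is
approximately linear. With pre-treatment velocity `v = (r₂ − r₁)/(t₂ − t₁)`
and the UVC line `r̂(t) = r₂ + v (t − t₂)`, the score at the first
post-treatment scan `(tₚ, rₚ)` is

```
DG = (tₚ − t₂) − (rₚ − r₂)/v  =  (r̂(tₚ) − rₚ)/v      [days]
```

DG = 0 means the tumor tracked its prediction; DG equal to the whole
inter-scan interval means no net growth; negative DG means growth outpaced
the prediction. Cases with non-positive pre-treatment velocity are excluded
(the score divides by `v`), with explicit bookkeeping.

The package is aimed at quantitative imaging / neuro-oncology statisticians:
it ingests longitudinal volume tables, scores DG per patient and modality
(T1Gd and FLAIR), and runs the standard survival analysis set — Kaplan–Meier
dichotomization at fixed (78 DG for OS, 93 DG for PFS) and cohort-median
cutoffs with log-rank tests, an iterative cutoff sweep, and Cox
proportional-hazards models with DG scaled per 25 days — plus a seeded
synthetic cohort generator with ground truth for validation.

## Worked example

Score a single case by hand:

```r
library(daysgained)
r1 <- volume_to_radius(9202.77)    # 13.0 mm, scan at day -80
r2 <- volume_to_radius(14137.17)   # 15.0 mm, scan at day -30
rp <- volume_to_radius(15600)      # 15.5 mm, scan at day +30
v  <- estimate_velocity(r1, r2, -80, -30)       # 0.04 mm/day
predict_uvc_radius(v, r2, -30, 30)              # 17.4 mm expected untreated
compute_days_gained(v, r2, -30, rp, 30)         # 47.5 days gained
```

The tumor was predicted to reach 17.4 mm but only reached 15.5 mm, so
treatment deflected about 47.5 of the 60 elapsed days of growth.

Full pipeline on a seeded synthetic cohort:

```r
sim <- tempfile()
generate_cohort(synthetic_config(seed = 7), dir = sim)
res <- run_pipeline(file.path(sim, "longitudinal.csv"),
                    file.path(sim, "patients.csv"),
                    out = file.path(sim, "analysis"))
res$accounting$FLAIR
#>             n_input            n_scored n_excluded_velocity        n_ineligible
#>                  62                  53                   9                   0
subset(res$cox_table, variable == "dg_per25" & group == "BevCyto" &
                      modality == "T1Gd" & endpoint == "OS")
#>   modality endpoint   group        model variable    coef     hr ci_low ci_high   p_value  n events
#>       T1Gd       OS BevCyto   univariate dg_per25 -0.1683 0.8451 0.7806  0.9149 3.217e-05 39     33
#>       T1Gd       OS BevCyto multivariate dg_per25 -0.1617 0.8507 0.7848  0.9221 8.499e-05 39     33
hazard_reduction_percent(0.8507)
#> [1] 14.9
```

Read: in this synthetic BevCyto arm each additional 25 days gained
multiplies the OS hazard by 0.85 after adjusting for age and sex — a 14.9%
reduction in the chance of death per 25 DG. The run directory contains
`dg_scores.csv`, `km_table.csv`, `cox_table.csv`, `sweep.csv`, KM/sweep
figures, and `run.log` with the cutoffs, the High/Low boundary rule, and the
exclusion accounting. A command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/daysgained.R", package = "daysgained"))')" \
    demo --out dg_demo --seed 7
```

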