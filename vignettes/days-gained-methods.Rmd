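---
title: "Days Gained: model, assumptions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Days Gained: model, assumptions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daysgained)
```

## The response metric

Imaging response assessment in glioblastoma is confounded by patient-to-patient
heterogeneity in growth kinetics, and — under anti-angiogenic therapy such as
bevacizumab — by pseudo-response, where contrast enhancement fades because the
blood–brain barrier normalises rather than because tumor burden falls. Days
Gained (DG) addresses the first problem by scoring each patient against their
own projected growth, and this package implements the full analysis chain
around it.

Each segmented tumor-abnormality volume $V$ (necrosis included, since the
model describes the whole abnormality) is reduced to its spherically
equivalent radius

$$ r = \left( \frac{3V}{4\pi} \right)^{1/3}, $$

the scale on which untreated glioma growth is well approximated as linear in
time. From the two pre-treatment scans (times $t_1 < t_2$, radii $r_1, r_2$,
both strictly before the start of therapy) the patient's growth velocity is

$$ v = \frac{r_2 - r_1}{t_2 - t_1} \quad \text{(mm/day)}, $$

and the *untreated virtual control* (UVC) extrapolates

$$ \hat r(t) = r_2 + v\,(t - t_2), \qquad t \ge t_2. $$

At the first post-treatment scan $(t_p, r_p)$ the DG score is the horizontal
gap between the observation and the UVC line, measured in days of untreated
growth:

$$ \mathrm{DG} = (t_p - t_2) - \frac{r_p - r_2}{v}
             = \frac{\hat r(t_p) - r_p}{v}. $$

DG is 0 when the tumor tracked its prediction, equals the full inter-scan
interval when it did not grow at all, exceeds it when the tumor shrank, and is
negative when growth outpaced the prediction. Scores are deliberately uncapped
in both directions; deep responses (post radius below the *first*
pre-treatment radius) are flagged `extreme_response` in the output but not
truncated, since extreme values carry real information about response and
real cohorts show them.

Assumptions worth keeping in view: radial growth is linear over the
evaluation window (the two-point UVC cannot detect curvature); the two
selected pre-treatment scans represent untreated kinetics; and a single
post-treatment scan summarises response. The UVC uses exactly the two most
recent pre-treatment scans even when more exist — the linear method is
defined on two points, and mixing older scans into a regression would change
the metric.

### Eligibility, exclusions, and groups

Scan selection takes the two scan dates strictly before the treatment start
and the first on or after it (a same-day scan counts as post-treatment; the
boundary had to fall somewhere and a scan on the infusion date has not yet
seen sustained therapy). Cases with fewer scans are ineligible, with the
missing-scan reason recorded. Eligibility is per modality: a patient with a
complete T1Gd series but no FLAIR remains a T1Gd case.

DG requires $v > 0$. Velocities at or below $10^{-12}$ mm/day are excluded as
`excluded_nonpositive_velocity` rather than scored, because the score divides
by $v$: a zero slope has no finite "days of growth" unit, and a negative
slope would invert the sign convention. Shrinking pre-treatment FLAIR
abnormality is common enough that this exclusion is a first-class status with
its own bookkeeping, and every cohort satisfies the identity
`n_input = n_scored + n_excluded + n_ineligible` per modality.

A case is `BevCyto` when a concurrent cytotoxic dose falls in the half-open
window (pre2, post1]: a dose given on the post-scan day still acted during
the interval being scored, while a dose on the pre2 day precedes the window.

## Survival layer

DG scores are related to overall and progression-free survival three ways,
mirroring the standard analysis set for this metric:

* **Fixed-cutoff Kaplan–Meier.** Scores are dichotomized into High/Low at 78
  DG for OS and 93 DG for PFS — thresholds carried over from the newly
  diagnosed setting precisely to avoid re-optimising on the cohort under
  analysis — and at per-group cohort medians. A score exactly at the cutoff
  is High; "above the cutoff" needs a tie rule to be reproducible, and the
  package logs the rule with every run. Groups are compared with the
  unweighted two-sample log-rank test against $\chi^2_1$.
* **Iterative cutoff sweep.** The same dichotomize-and-test step is repeated
  over a grid of cutoffs (default: the 5th–95th percentile of observed DG in
  steps of 5 days, a resolution fine enough to show contiguous significance
  bands without testing every distinct value). Cutoffs leaving fewer than 3
  subjects in either arm are flagged not-evaluable instead of tested.
  P-values are raw per-cutoff values with no multiplicity correction — the
  sweep describes where discrimination lives, it does not select a cutoff —
  and the output says so.
* **Cox proportional hazards.** DG enters as $\mathrm{DG}/25$, so the hazard
  ratio reads "per 25 days gained"; the univariate model has DG alone and the
  multivariate model adds age at treatment start and sex (M = 1). Ties use
  the Efron approximation and intervals are Wald on the log-hazard scale,
  the conventions of the survival ecosystem this analysis comes from. A
  hazard ratio is reported alongside its percent hazard reduction
  $(1 - \mathrm{HR}) \times 100$, rounded to one decimal.

Estimation is delegated to the `survival` package; the test suite checks the
delegated results against independent brute-force oracles (hand-rolled
product-limit curves, hypergeometric log-rank tables, and a grid-maximized
partial likelihood).

## The synthetic cohort generator

No patient data ship with the package; cohorts with the assumed statistical
structure are generated with a seed, and every generated cohort carries its
ground truth. The generative model works backwards from the DG definition:

1. Draw a latent radial velocity $v$ per modality from a log-normal, and
   place three shared scan sessions: pre1→pre2 gap uniform on 30–120 days,
   pre2→post1 interval uniform on 30–90 days, with the treatment start
   inside the second interval.
2. Draw a latent *deflection* $d$ — the patient's true DG — and set the
   latent post radius to $r_2 + v\,(\Delta t - d)$. By construction, a
   noiseless pipeline recovers $\mathrm{DG} = d$ exactly; this identity is a
   test, not a coincidence.
3. Perturb every measured radius with i.i.d. Gaussian noise (default 0.2 mm,
   about a 3–4% volume error at typical lesion size), convert to volumes,
   and write the cohort file formats.
4. Draw OS and PFS from exponential proportional-hazards models with
   log-hazard linear in $d/25$, then censor at the earlier of a 3-year
   administrative horizon and a uniform dropout time. An optional shared
   log-normal frailty couples OS and PFS; it defaults to off so that
   recovery experiments stay interpretable.
5. Flip the FLAIR velocity sign for a configured fraction of patients
   (default 9/62), reproducing the negative-velocity exclusions real FLAIR
   series show, and give BevCyto patients (default fraction 38/62) a
   cytotoxic dose inside the evaluation window. Some BevAlone patients get a
   decoy dose *before* the window so the window rule is actually exercised.

Defaults were chosen to emulate a recurrent-glioblastoma bevacizumab cohort
and are worth stating because they carry the scientific weight. The velocity
log-normal has median 0.08 mm/day (sdlog 0.5): at a 17 mm radius that is a
volume-doubling time near 50 days, the textbook pace of recurrent GBM, and
it keeps the 0.2 mm measurement noise a small relative error on the velocity
(slower scales, e.g. 0.04 mm/day, make DG estimates so noisy that no
survival model could recover effects cleanly — a real phenomenon, but one
that would dominate every simulation). The deflection is normal with mean
100 and sd 200 days, wide enough to reproduce the extreme DG values
(several hundred days in both directions) that real cohorts print. True
hazard ratios default to 0.875 (OS) and 0.877 (PFS) per 25 DG with baseline
medians of 180 and 90 days at $d = 0$. Latent draws that would imply a
non-positive radius are resampled with a warning and a bounded retry budget.

What the generator does *not* emulate: segmentation bias (noise is zero-mean
and homoscedastic), scanner or institution effects, non-linear growth,
correlation between velocity and deflection, and informative censoring.
Passing tests on this cohort therefore validate the *pipeline arithmetic and
statistical machinery*, not the clinical claims: they show the method
recovers known truth when its assumptions hold, which is the most a
synthetic study can show.

## Validation design

The test suite is organised around independent oracles and known-truth
recovery, at sizes chosen to keep the default run under a minute:

* **Closed form vs. numeric inversion.** DG has a closed form; the oracle
  solves $\hat r(t^\ast) = r_p$ by bisection and takes $t_p - t^\ast$.
  Agreement is required to $10^{-6}$ days over 1000 randomized cases.
* **Construction identities.** Noiseless cohorts (n = 200) must score DG
  equal to the planted deflection to $10^{-6}$ days for every
  positive-velocity patient, through the full file-writing and loading path.
* **Small-table oracles.** On cohorts of at most 20 subjects, product-limit
  curves and log-rank statistics must match brute-force risk-set enumeration
  to $10^{-9}$; the Cox HR must match direct maximization of the written
  partial likelihood on a tie-free 6-subject example.
* **Parameter recovery.** Fifty seeded 400-patient cohorts at true HR 0.875
  per 25 DG: the Wald 95% CI must cover truth in at least 90% of replicates
  and the mean HR must sit within 0.03 of truth. The same 400-patient scale
  is used for the null (HR = 1) coverage check, because that is the regime
  in which a Wald interval's nominal level is meaningful; at a few dozen
  events the finite-sample spread of a Cox estimate is known to exceed its
  model-based standard error, an undercoverage that belongs to Wald
  intervals generally, not to any particular implementation.
* **Null calibration.** Across 20 null cohorts at the default 62-patient
  size, at most 10% of evaluable sweep cutoffs may reach p ≤ 0.05. The
  pooled fraction is a high-variance statistic — cutoffs within one cohort
  are strongly correlated — so this is a coarse sanity bound, not an exact
  size computation.
* **Bookkeeping.** A 62-patient cohort with 9 planted negative-velocity
  FLAIR cases must report exactly 53 FLAIR-scored and 9 excluded patients,
  and T1Gd scoring must be unaffected.

## Numerical and edge-case choices

* Dates are ISO-8601 in files and numeric day offsets internally; bare
  integer offsets are accepted on input. All intervals are whole days, the
  metric's natural unit.
* Two pre-treatment scans on the same date make the velocity undefined and
  are a hard error rather than an exclusion — the data are malformed, not
  merely unscoreable.
* Volumes default to mm³ with a `units = "cm3"` switch (×1000) for tables
  recorded in cm³.
* `dichotomize` refuses non-finite scores; `km_logrank` returns a
  not-evaluable result (rather than an error) for single-group inputs, so
  sweeps degrade gracefully at extreme cutoffs.
* The generator restores the caller's RNG state, and a fixed seed yields
  byte-identical output files (R's default Mersenne–Twister; the RNG kind
  is whatever the R version defaults to, recorded in the run log via the R
  version string).

## A worked run

```{r demo, eval = FALSE}
sim <- tempfile()
generate_cohort(synthetic_config(seed = 7), dir = sim)
res <- run_pipeline(file.path(sim, "longitudinal.csv"),
                    file.path(sim, "patients.csv"),
                    out = file.path(sim, "analysis"))
res$accounting
subset(res$km_table, modality == "T1Gd" & group == "BevCyto")
subset(res$cox_table, variable == "dg_per25")
```

The run directory contains `dg_scores.csv`, `km_table.csv` (one row per
modality × endpoint × group × cutoff source), `cox_table.csv` (one row per
covariate per model), `sweep.csv`, KM and sweep-map figures, and `run.log`
with the exact cutoffs, boundary rule, and exclusion accounting used.

## Known limitations

DG inherits the linear UVC's blind spots: it cannot separate pseudo-response
from cytoreduction (that contrast is exactly what comparing T1Gd against
FLAIR series probes), it is sensitive to velocity estimation error when
pre-treatment scans are close together or the tumor is slow, and a single
post-treatment scan cannot distinguish transient from durable deflection.
The survival layer deliberately omits time-varying covariates, competing
risks, and cutoff-selection bias correction; and the uncertainty of an
individual DG score (segmentation and timing error propagation) is not
quantified here — scores are point estimates.
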