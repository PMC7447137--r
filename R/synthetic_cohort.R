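# Synthetic cohort generator: seeded cohorts with the data structure the DG
# analysis assumes, plus a ground-truth sidecar for recovery tests.

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every generator parameter. Defaults emulate a
#' recurrent-glioblastoma bevacizumab cohort: 62 patients with a 38/62
#' BevCyto fraction, log-normal radial growth velocities around 0.08 mm/day
#' (a volume-doubling time near 50 days at typical lesion sizes),
#' a 9/62 fraction of FLAIR cases with negative pre-treatment velocity,
#' shared scan sessions with a 30-120 day pre-treatment gap and a 30-90 day
#' pre2-to-post1 interval, a latent treatment deflection (the true DG) of
#' about 100 +/- 200 days, 0.2 mm radial measurement noise, and exponential
#' OS/PFS with log-hazard linear in true DG per 25 days plus administrative
#' and uniform-dropout censoring.
#'
#' @param n_patients Cohort size.
#' @param p_bevcyto Probability a patient is BevCyto (concurrent cytotoxic
#'   dose inside the DG evaluation window).
#' @param v_meanlog,v_sdlog Log-normal parameters of the radial growth
#'   velocity in mm/day (drawn independently per modality).
#' @param p_negative_flair Fraction of patients whose FLAIR velocity has its
#'   sign flipped (shrinking pre-treatment FLAIR abnormality; these cases
#'   are excluded from FLAIR DG scoring downstream).
#' @param pre_gap_range Days between the two pre-treatment scans (uniform).
#' @param post_gap_range Days between the second pre-treatment and first
#'   post-treatment scan (uniform).
#' @param r_pre2_mean,r_pre2_sd,r_pre2_range Normal (truncated) distribution
#'   of the T1Gd radius at the second pre-treatment scan, mm.
#' @param flair_radius_offset Added to the T1Gd radius location for FLAIR
#'   (the FLAIR abnormality envelops the enhancing lesion).
#' @param deflection_mean,deflection_sd Normal distribution of the latent
#'   treatment deflection in days; this is the true DG of each patient.
#' @param noise_sd Radial measurement noise sd, mm, applied independently to
#'   every measured radius.
#' @param hr_os_per25,hr_pfs_per25 True hazard ratios per 25 true-DG days.
#' @param base_hazard_os,base_hazard_pfs Baseline (true DG = 0) exponential
#'   hazards per day.
#' @param frailty_sd Sd of a shared log-normal patient frailty multiplying
#'   both hazards (0 = independent OS and PFS, the default).
#' @param censor_horizon Administrative censoring horizon, days.
#' @param dropout_max Uniform dropout upper bound, days.
#' @param p_male Probability of male sex.
#' @param age_mean,age_sd,age_range Truncated-normal age distribution, years.
#' @param seed Integer seed; fully determines the cohort.
#' @return A validated list of class `dg_synth_config`.
#' @export
synthetic_config <- function(n_patients = 62,
                             p_bevcyto = 38 / 62,
                             v_meanlog = log(0.08),
                             v_sdlog = 0.5,
                             p_negative_flair = 9 / 62,
                             pre_gap_range = c(30, 120),
                             post_gap_range = c(30, 90),
                             r_pre2_mean = 17, r_pre2_sd = 4,
                             r_pre2_range = c(5, 35),
                             flair_radius_offset = 5,
                             deflection_mean = 100, deflection_sd = 200,
                             noise_sd = 0.2,
                             hr_os_per25 = 0.875,
                             hr_pfs_per25 = 0.877,
                             base_hazard_os = log(2) / 180,
                             base_hazard_pfs = log(2) / 90,
                             frailty_sd = 0,
                             censor_horizon = 1095,
                             dropout_max = 3000,
                             p_male = 42 / 62,
                             age_mean = 57, age_sd = 12, age_range = c(20, 80),
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_patients >= 1,
    p_bevcyto >= 0, p_bevcyto <= 1,
    p_negative_flair >= 0, p_negative_flair <= 1,
    p_male >= 0, p_male <= 1,
    all(pre_gap_range >= 1), diff(pre_gap_range) >= 0,
    all(post_gap_range >= 1), diff(post_gap_range) >= 0,
    noise_sd >= 0, frailty_sd >= 0,
    hr_os_per25 > 0, hr_pfs_per25 > 0,
    base_hazard_os > 0, base_hazard_pfs > 0,
    censor_horizon > 0, dropout_max > 0,
    is.numeric(seed), length(seed) == 1
  )
  cfg$seed <- as.integer(seed)
  class(cfg) <- "dg_synth_config"
  cfg
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) > 0L && tries < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    tries <- tries + 1L
  }
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a cohort from the generative model the DG analysis assumes. Per
#' patient: a latent radial growth velocity per modality, three shared scan
#' dates (two pre-treatment, one post-treatment), pre-treatment radii on the
#' latent linear trajectory, and a post-treatment radius deflected back by
#' the patient's latent deflection `d` —
#' `r_post = r_pre2 + v * (interval - d)` — so that in the noiseless limit
#' the pipeline-computed DG equals `d` exactly. Radii are perturbed with
#' i.i.d. Gaussian measurement noise, converted to volumes via the sphere
#' formula, and written in the cohort file schema. OS and PFS are drawn from
#' exponential proportional-hazards models whose log-hazard is linear in
#' true DG per 25 days, then right-censored by the earlier of an
#' administrative horizon and a uniform dropout time. BevCyto patients
#' receive a cytotoxic dosing date inside the evaluation window
#' (pre2, post1]; a fraction of BevAlone patients get a decoy dose before
#' pre2 to exercise the window rule. A configured fraction of patients have
#' their FLAIR velocity sign flipped, yielding the negative-velocity
#' exclusions seen in real FLAIR series.
#'
#' @param config A `dg_synth_config` from [synthetic_config()].
#' @param dir Optional directory; when given, `longitudinal.csv`,
#'   `patients.csv` and `ground_truth.csv` are written there.
#' @return A list with `cohort` (a `dg_cohort`: observations + patients,
#'   dates in numeric days) and `truth` (per-patient latent values:
#'   velocities, deflection = true DG, group, event-time draws before
#'   censoring), plus the `config`.
#' @export
generate_cohort <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "dg_synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_patients
  pid <- sprintf("P%03d", seq_len(n))
  start <- as.numeric(as.Date("2006-01-01")) + floor(stats::runif(n, 0, 3652))

  gap1 <- round(stats::runif(n, config$pre_gap_range[1], config$pre_gap_range[2]))
  gap2 <- round(stats::runif(n, config$post_gap_range[1], config$post_gap_range[2]))
  frac <- stats::runif(n, 0.15, 0.6)
  pre2_off <- -pmax(1, round(frac * gap2))
  post1_off <- pre2_off + gap2
  pre1_off <- pre2_off - gap1

  group <- ifelse(stats::runif(n) < config$p_bevcyto, "BevCyto", "BevAlone")
  n_neg <- round(config$p_negative_flair * n)
  neg_flair <- rep(FALSE, n)
  if (n_neg > 0) neg_flair[sample.int(n, n_neg)] <- TRUE

  v_t1gd <- stats::rlnorm(n, config$v_meanlog, config$v_sdlog)
  v_flair <- stats::rlnorm(n, config$v_meanlog, config$v_sdlog)
  v_flair[neg_flair] <- -v_flair[neg_flair]

  r2_t1gd <- rnorm_trunc(n, config$r_pre2_mean, config$r_pre2_sd,
                         config$r_pre2_range[1], config$r_pre2_range[2])
  r2_flair <- rnorm_trunc(n, config$r_pre2_mean + config$flair_radius_offset,
                          config$r_pre2_sd,
                          config$r_pre2_range[1] + config$flair_radius_offset,
                          config$r_pre2_range[2] + config$flair_radius_offset)
  deflection <- stats::rnorm(n, config$deflection_mean, config$deflection_sd)

  # Latent radial trajectories must stay non-negative; resample the draws
  # that break that (fast tumor + long gap, or extreme deflection) a bounded
  # number of times, then give up with a hard error.
  n_resampled <- 0L
  resample_until <- function(x, ok, draw, what) {
    tries <- 0L
    while (!ok(x)) {
      if (tries >= 100L) stop("could not generate a positive ", what,
                              " radius; check config", call. = FALSE)
      x <- draw()
      tries <- tries + 1L
    }
    if (tries > 0L) n_resampled <<- n_resampled + 1L
    x
  }
  for (i in seq_len(n)) {
    v_t1gd[i] <- resample_until(v_t1gd[i],
      function(v) r2_t1gd[i] - v * gap1[i] > 0,
      function() stats::rlnorm(1, config$v_meanlog, config$v_sdlog), "T1Gd pre1")
    s <- sign(v_flair[i])
    v_flair[i] <- resample_until(v_flair[i],
      function(v) abs(v) * gap1[i] < r2_flair[i],
      function() s * stats::rlnorm(1, config$v_meanlog, config$v_sdlog), "FLAIR pre1")
    deflection[i] <- resample_until(deflection[i],
      function(d) r2_t1gd[i] + v_t1gd[i] * (gap2[i] - d) > 0,
      function() stats::rnorm(1, config$deflection_mean, config$deflection_sd),
      "T1Gd post")
  }
  if (n_resampled > 0L) {
    warning("resampled latent draws for ", n_resampled,
            " patient(s) to keep radii positive", call. = FALSE)
  }

  noise <- function() stats::rnorm(n, 0, config$noise_sd)
  meas <- function(r) pmax(r, 0)

  r1m_t1gd <- meas(r2_t1gd - v_t1gd * gap1 + noise())
  r2m_t1gd <- meas(r2_t1gd + noise())
  rpm_t1gd <- meas(r2_t1gd + v_t1gd * (gap2 - deflection) + noise())
  r1m_flair <- meas(r2_flair - v_flair * gap1 + noise())
  r2m_flair <- meas(r2_flair + noise())
  rp_flair_lat <- ifelse(neg_flair, pmax(r2_flair + v_flair * gap2, 0.1),
                         r2_flair + v_flair * (gap2 - deflection))
  rpm_flair <- meas(rp_flair_lat + noise())

  observations <- data.frame(
    patient_id = rep(pid, 6),
    scan_date = c(start + pre1_off, start + pre2_off, start + post1_off,
                  start + pre1_off, start + pre2_off, start + post1_off),
    modality = rep(c("T1Gd", "FLAIR"), each = 3 * n),
    volume_mm3 = radius_to_volume(c(r1m_t1gd, r2m_t1gd, rpm_t1gd,
                                    r1m_flair, r2m_flair, rpm_flair)),
    stringsAsFactors = FALSE
  )

  # Cytotoxic dosing: inside (pre2, post1] for BevCyto; a decoy dose before
  # pre2 for ~30% of BevAlone patients.
  cyto <- vector("list", n)
  decoy <- stats::runif(n) < 0.3
  dose_off <- pre2_off + ceiling(stats::runif(n) * (post1_off - pre2_off))
  decoy_off <- pre2_off - round(stats::runif(n, 10, 60))
  for (i in seq_len(n)) {
    cyto[[i]] <- if (group[i] == "BevCyto") start[i] + dose_off[i]
    else if (decoy[i]) start[i] + decoy_off[i] else numeric(0)
  }

  beta_os <- log(config$hr_os_per25)
  beta_pfs <- log(config$hr_pfs_per25)
  frail <- if (config$frailty_sd > 0)
    stats::rlnorm(n, -config$frailty_sd^2 / 2, config$frailty_sd) else rep(1, n)
  rate_os <- config$base_hazard_os * exp(beta_os * deflection / 25) * frail
  rate_pfs <- config$base_hazard_pfs * exp(beta_pfs * deflection / 25) * frail
  t_os <- stats::rexp(n, rate_os)
  t_pfs <- stats::rexp(n, rate_pfs)
  cens <- pmin(config$censor_horizon, stats::runif(n, 0, config$dropout_max))
  os_time <- round(pmin(t_os, cens), 1)
  os_event <- as.integer(t_os <= cens)
  pfs_time <- round(pmin(t_pfs, cens), 1)
  pfs_event <- as.integer(t_pfs <= cens)

  sex <- ifelse(stats::runif(n) < config$p_male, "M", "F")
  age <- round(rnorm_trunc(n, config$age_mean, config$age_sd,
                           config$age_range[1], config$age_range[2]))

  patients <- data.frame(patient_id = pid, treatment_start = start,
                         age_at_start = age, sex = sex,
                         os_time_days = os_time, os_event = os_event,
                         pfs_time_days = pfs_time, pfs_event = pfs_event,
                         stringsAsFactors = FALSE)
  patients$cytotoxic_dates <- cyto

  truth <- data.frame(patient_id = pid, group = group,
                      v_t1gd = v_t1gd, v_flair = v_flair,
                      negative_flair = neg_flair,
                      true_dg = deflection,
                      interval_days = gap2,
                      t_os_uncensored = t_os, t_pfs_uncensored = t_pfs,
                      censor_time = cens,
                      stringsAsFactors = FALSE)
  attr(truth, "beta_os_per25") <- beta_os
  attr(truth, "beta_pfs_per25") <- beta_pfs

  cohort <- structure(list(observations = observations, patients = patients),
                      class = "dg_cohort")
  out <- list(cohort = cohort, truth = truth, config = config)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_cohort(cohort, file.path(dir, "longitudinal.csv"),
                 file.path(dir, "patients.csv"))
    tr <- truth
    utils::write.table(tr, file.path(dir, "ground_truth.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
  }
  out
}

#' Generate a null cohort: survival independent of DG
#'
#' Identical to [generate_cohort()] but with both true hazard ratios forced
#' to 1 (zero log-hazard per 25 DG), so any association between DG and
#' OS/PFS in the output is spurious. Used for type-I-error calibration of
#' the sweep and coverage checks of the Cox stage.
#'
#' @param config A `dg_synth_config`; its `hr_os_per25` and `hr_pfs_per25`
#'   are overridden with 1.
#' @param dir Optional output directory, as in [generate_cohort()].
#' @return As [generate_cohort()].
#' @export
generate_null_cohort <- function(config = synthetic_config(), dir = NULL) {
  config$hr_os_per25 <- 1
  config$hr_pfs_per25 <- 1
  generate_cohort(config, dir = dir)
}
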