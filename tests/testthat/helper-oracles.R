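# Independent oracles, kept deliberately naive and separate from the
# package's computation paths.

# Invert the linear UVC r(t) = r_pre2 + v (t - t_pre2) for the time t* at
# which the untreated control reaches the observed post radius, by bisection;
# the Days Gained score is t_post - t*.
oracle_dg_bisection <- function(v, r_pre2, t_pre2, r_post, t_post,
                                tol = 1e-9) {
  f <- function(t) r_pre2 + v * (t - t_pre2) - r_post
  lo <- t_pre2 - 1e7
  hi <- t_pre2 + 1e7
  stopifnot(f(lo) < 0, f(hi) > 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  t_star <- (lo + hi) / 2
  t_post - t_star
}

# Brute-force product-limit estimator: walk distinct event times and
# multiply the at-risk survival fractions.
oracle_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  surv <- numeric(length(et))
  s <- 1
  for (k in seq_along(et)) {
    n_risk <- sum(time >= et[k])
    d <- sum(time == et[k] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = et, survival = surv)
}

# Two-sample log-rank test from first principles: at each distinct event
# time form the 2x2 risk-set table; observed-minus-expected events in group
# 1 and the hypergeometric variance give the chi-square statistic.
oracle_logrank <- function(time, event, group) {
  group <- as.character(group)
  g1 <- sort(unique(group))[1]
  et <- sort(unique(time[event == 1]))
  OmE <- 0
  V <- 0
  for (tk in et) {
    at <- time >= tk
    nj <- sum(at)
    n1j <- sum(at & group == g1)
    dj <- sum(time == tk & event == 1)
    d1j <- sum(time == tk & event == 1 & group == g1)
    OmE <- OmE + d1j - dj * n1j / nj
    if (nj > 1) {
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  chisq <- OmE^2 / V
  list(chisq = chisq, p_value = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Exact Cox partial log-likelihood for a single covariate with no tied event
# times, maximized numerically; independent of survival::coxph.
oracle_cox_hr <- function(x, time, event) {
  stopifnot(!anyDuplicated(time[event == 1]))
  loglik <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  opt <- stats::optimize(loglik, c(-50, 50), maximum = TRUE, tol = 1e-10)
  exp(opt$maximum)
}

# Random valid DG inputs for property checks.
random_dg_cases <- function(n, seed) {
  set.seed(seed)
  data.frame(
    v = stats::runif(n, 1e-3, 0.5),
    r_pre2 = stats::runif(n, 1, 40),
    t_pre2 = stats::runif(n, -500, 500),
    dt = stats::runif(n, 1, 400),
    r_post = stats::runif(n, 0, 60)
  )
}

# Minimal in-memory cohort for plumbing tests: one patient, three scan days
# per modality, volumes derived from the radii supplied.
tiny_cohort <- function(radii_t1gd = c(10, 12, 13.2),
                        scan_days = c(-100, -30, 45),
                        os_time = 300, os_event = 1,
                        pfs_time = 150, pfs_event = 1,
                        cytotoxic = numeric(0)) {
  obs <- data.frame(
    patient_id = "P001",
    scan_date = rep(scan_days, 2),
    modality = rep(c("T1Gd", "FLAIR"), each = length(scan_days)),
    volume_mm3 = radius_to_volume(rep(radii_t1gd, 2)),
    stringsAsFactors = FALSE
  )
  pat <- data.frame(patient_id = "P001", treatment_start = 0,
                    age_at_start = 60, sex = "M",
                    os_time_days = os_time, os_event = os_event,
                    pfs_time_days = pfs_time, pfs_event = pfs_event,
                    stringsAsFactors = FALSE)
  pat$cytotoxic_dates <- list(cytotoxic)
  structure(list(observations = obs, patients = pat), class = "dg_cohort")
}
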