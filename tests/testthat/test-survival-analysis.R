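test_that("dichotomization uses the DG >= cutoff boundary rule", {
  lab <- dichotomize(c(-10, 78, 200), 78)
  expect_equal(as.character(lab), c("Low", "High", "High"))
  expect_true(attr(lab, "evaluable"))

  all_high <- dichotomize(c(10, 20, 30), 5)
  expect_false(attr(all_high, "evaluable"))
  expect_equal(attr(all_high, "n_high"), 3L)

  med <- stats::median(c(10, 20, 30))
  expect_equal(med, 20)
  expect_equal(as.character(dichotomize(c(10, 20, 30), med)),
               c("Low", "High", "High"))

  expect_error(dichotomize(c(1, Inf), 5), "finite")
})

test_that("KM estimates match the brute-force product-limit estimator", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:20, 1)
    time <- round(rexp(n, 1 / 100), 1)
    event <- rbinom(n, 1, 0.8)
    group <- factor(sample(c("Low", "High"), n, replace = TRUE))
    if (length(unique(group)) < 2 || sum(event) == 0) next
    km <- km_logrank(time, event, group)
    for (g in levels(group)) {
      ora <- oracle_km(time[group == g], event[group == g])
      cur <- km$curves[km$curves$group == g & km$curves$n_event > 0, ]
      got <- cur$survival[match(ora$time, cur$time)]
      expect_equal(got, ora$survival, tolerance = 1e-9)
    }
    # survival curves start at 1 and are non-increasing
    for (g in unique(km$curves$group)) {
      sg <- km$curves$survival[km$curves$group == g]
      expect_true(all(diff(sg) <= 1e-12))
      expect_true(all(sg <= 1 + 1e-12))
    }
  }
})

test_that("log-rank statistic matches the hypergeometric risk-set oracle", {
  # hand-enumerable 8-subject table: all events, clearly separated groups
  time <- c(1, 2, 3, 4, 10, 20, 30, 40)
  event <- rep(1, 8)
  group <- rep(c("A", "B"), each = 4)
  km <- km_logrank(time, event, group)
  ora <- oracle_logrank(time, event, group)
  expect_equal(km$chisq, ora$chisq, tolerance = 1e-9)
  expect_equal(km$p_value, ora$p_value, tolerance = 1e-9)

  # single subject per group, both events
  km1 <- km_logrank(c(5, 9), c(1, 1), c("A", "B"))
  ora1 <- oracle_logrank(c(5, 9), c(1, 1), c("A", "B"))
  expect_equal(km1$chisq, ora1$chisq, tolerance = 1e-9)

  # randomized small tables with censoring and ties
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(6:20, 1)
    time <- sample(1:15, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    group <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(group)) < 2 || sum(event) == 0) next
    km <- km_logrank(time, event, group)
    ora <- oracle_logrank(time, event, group)
    expect_equal(km$chisq, ora$chisq, tolerance = 1e-9)
    # label-swap invariance
    swapped <- km_logrank(time, event, ifelse(group == "A", "B", "A"))
    expect_equal(swapped$chisq, km$chisq, tolerance = 1e-12)
  }

  # identical event histories in the two groups: no separation
  km0 <- km_logrank(rep(c(3, 7, 12), 2), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_lt(km0$chisq, 1e-12)
  expect_gt(km0$p_value, 1 - 1e-6)

  # one empty group is not evaluable
  kme <- km_logrank(c(1, 2), c(1, 1), factor(c("A", "A"), levels = c("A", "B")))
  expect_false(kme$evaluable)
})

test_that("Cox fit matches direct partial-likelihood maximization and its invariances", {
  # n = 6, binary covariate, no ties, no censoring
  time <- c(2, 5, 7, 11, 16, 23)
  event <- rep(1, 6)
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- cox_fit(x * 25, time, event, model = "univariate")  # dg/25 == x
  expect_equal(fit$hr, oracle_cox_hr(x, time, event), tolerance = 1e-6)

  # per-25 coding: HR_per25 = HR_per1^25
  dg <- c(10, 150, -40, 220, 95, 130, 60, 180)
  t2 <- c(30, 200, 15, 340, 120, 210, 90, 260)
  e2 <- rep(1, 8)
  f25 <- cox_fit(dg, t2, e2, model = "univariate")
  f1 <- survival::coxph(survival::Surv(t2, e2) ~ dg, ties = "efron")
  expect_equal(f25$hr, exp(coef(f1))^25, tolerance = 1e-6,
               ignore_attr = TRUE)

  # multivariate: DG hazard ratio invariant to an affine shift of age
  set.seed(51)
  n <- 60
  dg3 <- rnorm(n, 100, 70); age <- rnorm(n, 60, 10)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  t3 <- rexp(n, 0.01 * exp(-0.1 * dg3 / 25)); e3 <- rbinom(n, 1, 0.9)
  m1 <- cox_fit(dg3, t3, e3, age = age, sex = sex, model = "multivariate")
  m2 <- cox_fit(dg3, t3, e3, age = age + 17.3, sex = sex, model = "multivariate")
  expect_equal(m1$hr[m1$variable == "dg_per25"],
               m2$hr[m2$variable == "dg_per25"], tolerance = 1e-8)
  expect_equal(m1$variable, c("dg_per25", "age", "sex_M"))
  expect_true(all(m1$ci_low <= m1$hr & m1$hr <= m1$ci_high))

  expect_error(cox_fit(rep(50, 10), rexp(10), rep(1, 10), model = "univariate"),
               "constant")
  expect_error(cox_fit(1:5, 1:5, c(1, 0, 0, 0, 0), model = "univariate"),
               "2 observed events")
})

test_that("hazard ratio to percent reduction conversion", {
  expect_equal(hazard_reduction_percent(0.875), 12.5)
  expect_equal(hazard_reduction_percent(1.0), 0.0)
  expect_equal(hazard_reduction_percent(0.956), 4.4)
  expect_equal(hazard_reduction_percent(1.2), -20.0)
  expect_error(hazard_reduction_percent(0), "positive")
  expect_error(hazard_reduction_percent(-1), "positive")
})

test_that("cutoff sweep composes dichotomization and log-rank over the grid", {
  set.seed(61)
  n <- 40
  dg <- rnorm(n, 100, 60)
  time <- rexp(n, 0.005 * exp(-0.15 * dg / 25))
  event <- rbinom(n, 1, 0.85)

  # one-cutoff grid equals the standalone analysis
  sw1 <- iterative_km_sweep(dg, time, event, grid = 100)
  expect_equal(nrow(sw1), 1L)
  km <- km_logrank(time, event, dichotomize(dg, 100))
  expect_identical(sw1$chisq, km$chisq)
  expect_identical(sw1$p_value, km$p_value)

  # sweep row at the cohort median reproduces the median-cutoff analysis
  med <- stats::median(dg)
  sw <- iterative_km_sweep(dg, time, event, grid = sort(c(med, 50, 150)))
  kmed <- km_logrank(time, event, dichotomize(dg, med))
  expect_identical(sw$p_value[sw$cutoff == med], kmed$p_value)

  # minimum-group-size rule flags extreme cutoffs as not evaluable
  sw2 <- iterative_km_sweep(dg, time, event,
                            grid = c(min(dg) - 10, med, max(dg) + 10),
                            min_group_size = 3)
  expect_equal(sw2$evaluable, c(FALSE, TRUE, FALSE))
  expect_true(all(is.na(sw2$p_value[!sw2$evaluable])))

  expect_error(iterative_km_sweep(dg, time, event, grid = numeric(0)), "empty")
  expect_error(iterative_km_sweep(dg, time, event, grid = c(2, 1)),
               "strictly increasing")
})

test_that("a strong DG effect yields a contiguous significant cutoff band", {
  cfg <- synthetic_config(n_patients = 200, seed = 71, hr_os_per25 = 0.80)
  g <- generate_cohort(cfg)
  s <- score_cohort(g$cohort, "T1Gd")
  sc <- s[s$status == "scored", ]
  idx <- match(sc$patient_id, g$cohort$patients$patient_id)
  sw <- iterative_km_sweep(sc$dg_days, g$cohort$patients$os_time_days[idx],
                           g$cohort$patients$os_event[idx])
  ev <- sw[sw$evaluable, ]
  med <- stats::median(sc$dg_days)
  near <- ev[abs(ev$cutoff - med) <= 40, ]
  expect_gt(nrow(near), 3)
  expect_true(all(near$p_value <= 0.05))
})
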