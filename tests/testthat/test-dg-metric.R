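test_that("spherically equivalent radius matches the sphere formula", {
  expect_equal(volume_to_radius(4 * pi / 3), 1.0)
  expect_equal(volume_to_radius(0), 0)
  # forward oracle: the volume of a 20 mm sphere maps back to 20 mm
  expect_equal(volume_to_radius(radius_to_volume(20)), 20, tolerance = 1e-12)
  expect_equal(volume_to_radius(33510.32), 20, tolerance = 1e-5)
  # cm^3 switch
  expect_equal(volume_to_radius(radius_to_volume(20) / 1000, units = "cm3"), 20)
  expect_error(volume_to_radius(-1), "non-negative")
  expect_error(radius_to_volume(-1), "non-negative")

  # round-trip identity over a range of radii
  r <- seq(0.1, 60, length.out = 200)
  expect_equal(volume_to_radius(radius_to_volume(r)), r, tolerance = 1e-9)
})

test_that("velocity is the radial slope between the pre-treatment scans", {
  expect_equal(estimate_velocity(10, 12, 0, 50), 0.04)
  expect_equal(estimate_velocity(12, 12, 0, 50), 0)
  expect_equal(estimate_velocity(14, 12, 0, 40), -0.05)
  expect_error(estimate_velocity(10, 12, 50, 50), "strictly increasing")
})

test_that("the UVC is a straight line anchored at the second pre scan", {
  expect_equal(predict_uvc_radius(0.04, 12, 0, 60), 14.4)
  expect_equal(predict_uvc_radius(0.04, 12, 10, 10), 12)
  expect_equal(predict_uvc_radius(0, 12, 0, c(0, 100, 1000)), rep(12, 3))
  expect_error(predict_uvc_radius(0.04, 12, 0, -1), "precede")
})

test_that("DG closed form matches hand cases and flags non-positive velocity", {
  expect_equal(compute_days_gained(0.04, 12, 0, 14.4, 60), 0)
  expect_equal(compute_days_gained(0.04, 12, 0, 12, 60), 60)
  expect_equal(compute_days_gained(0.04, 12, 0, 13.2, 60), 30)
  expect_warning(dg <- compute_days_gained(0, 12, 0, 13, 60), "non-positive")
  expect_true(is.na(dg))
  expect_warning(dg2 <- compute_days_gained(-0.02, 12, 0, 13, 60))
  expect_true(is.na(dg2))
  expect_error(compute_days_gained(0.04, 12, 50, 13, 40), "must follow")
})

test_that("closed-form DG agrees with bisection inversion of the UVC line", {
  cases <- random_dg_cases(250, seed = 11)
  for (i in seq_len(nrow(cases))) {
    cc <- cases[i, ]
    dg <- compute_days_gained(cc$v, cc$r_pre2, cc$t_pre2, cc$r_post,
                              cc$t_pre2 + cc$dt)
    dg_oracle <- oracle_dg_bisection(cc$v, cc$r_pre2, cc$t_pre2, cc$r_post,
                                     cc$t_pre2 + cc$dt)
    expect_lt(abs(dg - dg_oracle), 1e-6)
  }
})

test_that("DG is monotone in post radius, shift-invariant in time, scale-equivariant", {
  set.seed(21)
  for (rep in 1:50) {
    v <- runif(1, 0.005, 0.3); r2 <- runif(1, 5, 30)
    t2 <- runif(1, -100, 100); dt <- runif(1, 10, 300)
    rp <- sort(runif(2, 0, 50))
    dg_lo <- compute_days_gained(v, r2, t2, rp[1], t2 + dt)
    dg_hi <- compute_days_gained(v, r2, t2, rp[2], t2 + dt)
    expect_gt(dg_lo, dg_hi)  # strictly decreasing in post radius

    shift <- runif(1, -1000, 1000)
    expect_equal(compute_days_gained(v, r2, t2 + shift, rp[1], t2 + dt + shift),
                 dg_lo, tolerance = 1e-9)

    c_scale <- runif(1, 0.1, 10)
    expect_equal(compute_days_gained(v * c_scale, r2 * c_scale, t2,
                                     rp[1] * c_scale, t2 + dt),
                 dg_lo, tolerance = 1e-8)
  }
})

test_that("score_cohort composes selection, conversion, velocity, and DG", {
  co <- tiny_cohort(radii_t1gd = c(10, 12, 13.2), scan_days = c(-80, -30, 30))
  s <- score_cohort(co, "T1Gd")
  expect_equal(nrow(s), 1L)
  expect_equal(s$status, "scored")
  v <- (12 - 10) / 50
  expect_equal(s$velocity_mm_per_day, v, tolerance = 1e-10)
  expect_equal(s$interval_days, 60)
  expect_equal(s$dg_days, compute_days_gained(v, 12, -30, 13.2, 30),
               tolerance = 1e-10)
  expect_equal(s$group, "BevAlone")

  # missing post scan -> ineligible with the scan-selection reason
  co2 <- tiny_cohort(scan_days = c(-80, -30, -10))
  s2 <- score_cohort(co2, "T1Gd")
  expect_equal(s2$status, "ineligible")
  expect_equal(s2$reason, "missing_posttreatment_scan")
  expect_true(is.na(s2$dg_days))

  # shrinking pre-treatment tumor -> excluded, not scored, no crash
  co3 <- tiny_cohort(radii_t1gd = c(14, 12, 11), scan_days = c(-80, -30, 30))
  s3 <- score_cohort(co3, "T1Gd")
  expect_equal(s3$status, "excluded_nonpositive_velocity")
  expect_true(is.na(s3$dg_days))
  expect_lt(s3$velocity_mm_per_day, 0)

  # deep response (post radius below first pre radius) is flagged, not capped
  co4 <- tiny_cohort(radii_t1gd = c(10, 12, 8), scan_days = c(-80, -30, 30))
  s4 <- score_cohort(co4, "T1Gd")
  expect_true(s4$extreme_response)
  expect_gt(s4$dg_days, s4$interval_days)
})

test_that("cohort scoring partitions every patient into exactly one status", {
  g <- generate_cohort(synthetic_config(seed = 5, n_patients = 40))
  for (mod in DG_MODALITIES) {
    s <- score_cohort(g$cohort, mod)
    expect_equal(nrow(s), 40L)
    expect_true(all(s$status %in% c("scored", "excluded_nonpositive_velocity",
                                    "ineligible")))
    expect_equal(sum(is.na(s$dg_days)), sum(s$status != "scored"))
    cts <- summarize_dg(s)$counts
    expect_equal(cts[["n_input"]],
                 cts[["n_scored"]] + cts[["n_excluded_velocity"]] +
                   cts[["n_ineligible"]])
  }
})
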