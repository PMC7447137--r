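# Days Gained metric: spherically equivalent radii, linear growth velocity,
# untreated virtual control, DG score, cohort scoring.

#' Spherically equivalent radius of a tumor volume
#'
#' Converts a segmented tumor-abnormality volume to the radius of the sphere
#' of equal volume, r = (3V / 4 pi)^(1/3). All downstream growth modelling is
#' done on this radial scale, where untreated glioma growth is well
#' approximated as linear in time.
#'
#' @param volume Non-negative volume(s).
#' @param units `"mm3"` (default) or `"cm3"`; cm^3 inputs are converted to
#'   mm^3 before the radius (mm) is computed.
#' @return Radius in mm, same length as `volume`.
#' @seealso [radius_to_volume()] for the inverse.
#' @export
volume_to_radius <- function(volume, units = c("mm3", "cm3")) {
  units <- match.arg(units)
  if (any(is.na(volume)) || any(volume < 0)) {
    stop("volume must be non-negative", call. = FALSE)
  }
  if (units == "cm3") volume <- volume * 1000
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Volume of a sphere of given radius
#'
#' Forward companion of [volume_to_radius()]; used by the synthetic generator
#' to emit volumes from latent radial trajectories.
#'
#' @param radius Non-negative radius in mm.
#' @return Volume in mm^3.
#' @export
radius_to_volume <- function(radius) {
  if (any(is.na(radius)) || any(radius < 0)) {
    stop("radius must be non-negative", call. = FALSE)
  }
  4 / 3 * pi * radius^3
}

#' Pre-treatment radial growth velocity
#'
#' The patient-specific tumor growth velocity is the slope of the
#' spherically equivalent radius between the two pre-treatment scans:
#' v = (r2 - r1) / (t2 - t1), in mm/day. The value may be negative or zero
#' (shrinking or static pre-treatment abnormality); such cases are excluded
#' from DG scoring downstream, not here.
#'
#' @param r_pre1,r_pre2 Radii (mm) at the first and second pre-treatment scan.
#' @param t_pre1,t_pre2 Scan times in days; `t_pre2` must exceed `t_pre1`.
#' @return Velocity in mm/day (vectorised).
#' @export
estimate_velocity <- function(r_pre1, r_pre2, t_pre1, t_pre2) {
  if (any(t_pre2 <= t_pre1)) {
    stop("pre-treatment scans must have strictly increasing times", call. = FALSE)
  }
  (r_pre2 - r_pre1) / (t_pre2 - t_pre1)
}

#' Untreated virtual control radius prediction
#'
#' Linear UVC: from the second pre-treatment scan the tumor radius is
#' extrapolated at the pre-treatment velocity,
#' r(t) = r_pre2 + v (t - t_pre2). This is the patient-specific prediction
#' of tumor size had no treatment been given.
#'
#' @param v Velocity in mm/day.
#' @param r_pre2 Radius (mm) at the second pre-treatment scan.
#' @param t_pre2 Time (days) of the second pre-treatment scan.
#' @param t Prediction time(s), `t >= t_pre2`.
#' @return Predicted radius in mm.
#' @export
predict_uvc_radius <- function(v, r_pre2, t_pre2, t) {
  if (any(t < t_pre2)) {
    stop("UVC prediction time must not precede the second pre-treatment scan",
         call. = FALSE)
  }
  r_pre2 + v * (t - t_pre2)
}

# Velocities at or below this (mm/day) are treated as non-positive: DG
# divides by v, so exact and near-zero slopes are excluded rather than
# producing unbounded scores.
VELOCITY_TOL <- 1e-12

#' Days Gained score
#'
#' DG compares the observed post-treatment radius with the untreated virtual
#' control over the interval from the second pre-treatment scan to the first
#' post-treatment scan:
#' \deqn{DG = (t_{post} - t_{pre2}) - (r_{post} - r_{pre2})/v
#'          = (r_{UVC}(t_{post}) - r_{post}) / v.}
#' It is the number of days of untreated growth the treatment "bought": 0
#' when the tumor tracked the prediction exactly, the full interval when it
#' did not grow at all, and negative when it outgrew the prediction. Scores
#' are not capped in either direction.
#'
#' Requires a positive pre-treatment velocity; with `v <= 0` the score is
#' undefined (the case should be excluded, see [score_cohort()]) and `NA` is
#' returned with a warning rather than an error.
#'
#' @param v Pre-treatment velocity (mm/day).
#' @param r_pre2,t_pre2 Radius (mm) and time (days) at the second
#'   pre-treatment scan.
#' @param r_post,t_post Radius and time at the first post-treatment scan;
#'   `t_post` must exceed `t_pre2`.
#' @return DG in days (vectorised); `NA` where `v` is not positive.
#' @export
compute_days_gained <- function(v, r_pre2, t_pre2, r_post, t_post) {
  if (any(t_post <= t_pre2)) {
    stop("post-treatment scan must follow the second pre-treatment scan",
         call. = FALSE)
  }
  dg <- (t_post - t_pre2) - (r_post - r_pre2) / v
  bad <- v <= VELOCITY_TOL
  if (any(bad)) {
    warning("DG undefined for non-positive growth velocity; returning NA",
            call. = FALSE)
    dg[bad] <- NA_real_
  }
  dg
}

#' Score a cohort: one DG result per patient and modality
#'
#' Runs the full DG pipeline for one modality: per patient, select the scan
#' triplet (two most recent pre-treatment dates, first post-treatment date),
#' convert volumes to spherically equivalent radii, estimate the growth
#' velocity, and compute DG against the linear UVC. Every patient in the
#' patient table receives exactly one row with status
#' `"scored"`, `"excluded_nonpositive_velocity"` (eligible scans but
#' non-positive pre-treatment velocity, for which DG is undefined), or
#' `"ineligible"` (missing required scan dates, reason recorded). The
#' treatment group is assigned from the cytotoxic dosing window (pre2, post1].
#'
#' @param cohort A `dg_cohort` from [load_cohort()] or
#'   [generate_cohort()]`$cohort`.
#' @param modality `"T1Gd"` or `"FLAIR"`.
#' @param units Volume units passed to [volume_to_radius()].
#' @return A data frame of class `dg_scores`: `patient_id`, `modality`,
#'   `status`, `reason`, `group`, `velocity_mm_per_day`, `interval_days`,
#'   `r_pre2_mm`, `r_post_mm`, `r_predicted_mm`, `dg_days`,
#'   `extreme_response` (post radius below the first pre-treatment radius —
#'   deep response flagged, not capped).
#' @export
score_cohort <- function(cohort, modality = c("T1Gd", "FLAIR"), units = "mm3") {
  modality <- match.arg(modality)
  obs <- cohort$observations
  pats <- cohort$patients
  obs <- obs[obs$modality == modality, , drop = FALSE]

  n <- nrow(pats)
  res <- data.frame(
    patient_id = pats$patient_id,
    modality = rep(modality, n),
    status = rep(NA_character_, n),
    reason = rep("ok", n),
    group = rep(NA_character_, n),
    velocity_mm_per_day = rep(NA_real_, n),
    interval_days = rep(NA_real_, n),
    r_pre2_mm = rep(NA_real_, n),
    r_post_mm = rep(NA_real_, n),
    r_predicted_mm = rep(NA_real_, n),
    dg_days = rep(NA_real_, n),
    extreme_response = rep(FALSE, n),
    stringsAsFactors = FALSE
  )

  for (i in seq_len(n)) {
    pid <- pats$patient_id[i]
    start <- pats$treatment_start[i]
    po <- obs[obs$patient_id == pid, , drop = FALSE]
    sel <- select_dg_scans(po, start)
    if (!sel$eligible) {
      res$status[i] <- "ineligible"
      res$reason[i] <- sel$reason
      next
    }
    r1 <- volume_to_radius(sel$pre1$volume_mm3, units)
    r2 <- volume_to_radius(sel$pre2$volume_mm3, units)
    rp <- volume_to_radius(sel$post1$volume_mm3, units)
    v <- estimate_velocity(r1, r2, sel$pre1$scan_date, sel$pre2$scan_date)
    res$group[i] <- assign_treatment_group(pats$cytotoxic_dates[[i]],
                                           sel$pre2$scan_date, sel$post1$scan_date)
    res$velocity_mm_per_day[i] <- v
    res$interval_days[i] <- sel$post1$scan_date - sel$pre2$scan_date
    res$r_pre2_mm[i] <- r2
    res$r_post_mm[i] <- rp
    if (v <= VELOCITY_TOL) {
      res$status[i] <- "excluded_nonpositive_velocity"
      next
    }
    res$r_predicted_mm[i] <- predict_uvc_radius(v, r2, sel$pre2$scan_date,
                                                sel$post1$scan_date)
    res$dg_days[i] <- compute_days_gained(v, r2, sel$pre2$scan_date,
                                          rp, sel$post1$scan_date)
    res$extreme_response[i] <- rp < r1
    res$status[i] <- "scored"
  }
  class(res) <- c("dg_scores", "data.frame")
  res
}

#' Summarise DG scores per treatment group
#'
#' Status bookkeeping (scored / excluded / ineligible counts) and the
#' median and range of DG per treatment group, in the shape of a cohort
#' demographics table.
#'
#' @param scores A `dg_scores` data frame from [score_cohort()].
#' @return A list with `counts` (per-status totals) and `by_group`
#'   (N, median DG, min, max per treatment group).
#' @export
summarize_dg <- function(scores) {
  counts <- c(
    n_input = nrow(scores),
    n_scored = sum(scores$status == "scored"),
    n_excluded_velocity = sum(scores$status == "excluded_nonpositive_velocity"),
    n_ineligible = sum(scores$status == "ineligible")
  )
  sc <- scores[scores$status == "scored", , drop = FALSE]
  groups <- sort(unique(sc$group))
  by_group <- do.call(rbind, lapply(groups, function(g) {
    d <- sc$dg_days[sc$group == g]
    data.frame(group = g, n = length(d), dg_median = stats::median(d),
               dg_min = min(d), dg_max = max(d), stringsAsFactors = FALSE)
  }))
  list(counts = counts, by_group = by_group)
}

#' Write DG scores as delimited text
#'
#' @param scores A `dg_scores` data frame.
#' @param path Output path.
#' @param sep Field separator.
#' @return Invisibly, `path`.
#' @export
write_dg_scores <- function(scores, path, sep = ",") {
  cols <- c("patient_id", "modality", "status", "reason", "group",
            "velocity_mm_per_day", "interval_days", "dg_days", "extreme_response")
  utils::write.table(scores[, cols], path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
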