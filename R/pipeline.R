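# End-to-end orchestration: validate -> score DG -> KM / sweep / Cox ->
# tables and figures in a deterministic run directory.

km_row <- function(scores, pats, modality, group, endpoint, cutoff, cutoff_source) {
  sc <- scores[scores$status == "scored", , drop = FALSE]
  if (group != "All") sc <- sc[sc$group == group, , drop = FALSE]
  idx <- match(sc$patient_id, pats$patient_id)
  time <- if (endpoint == "OS") pats$os_time_days[idx] else pats$pfs_time_days[idx]
  event <- if (endpoint == "PFS") pats$pfs_event[idx] else pats$os_event[idx]
  if (nrow(sc) == 0L) {
    return(data.frame(modality = modality, endpoint = endpoint, group = group,
                      cutoff_source = cutoff_source, cutoff = NA_real_,
                      n_high = 0L, n_low = 0L, chisq = NA_real_,
                      p_value = NA_real_, evaluable = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (cutoff_source == "median") cutoff <- stats::median(sc$dg_days)
  lab <- dichotomize(sc$dg_days, cutoff)
  km <- if (attr(lab, "evaluable")) km_logrank(time, event, lab) else
    list(chisq = NA_real_, p_value = NA_real_, evaluable = FALSE)
  data.frame(modality = modality, endpoint = endpoint, group = group,
             cutoff_source = cutoff_source, cutoff = cutoff,
             n_high = attr(lab, "n_high"), n_low = attr(lab, "n_low"),
             chisq = km$chisq, p_value = km$p_value, evaluable = km$evaluable,
             stringsAsFactors = FALSE)
}

cox_rows <- function(scores, pats, modality, group, endpoint) {
  sc <- scores[scores$status == "scored", , drop = FALSE]
  if (group != "All") sc <- sc[sc$group == group, , drop = FALSE]
  idx <- match(sc$patient_id, pats$patient_id)
  time <- if (endpoint == "OS") pats$os_time_days[idx] else pats$pfs_time_days[idx]
  event <- if (endpoint == "PFS") pats$pfs_event[idx] else pats$os_event[idx]
  age <- pats$age_at_start[idx]; sex <- pats$sex[idx]
  out <- list()
  for (m in c("univariate", "multivariate")) {
    fit <- tryCatch(
      cox_fit(sc$dg_days, time, event,
              age = if (m == "multivariate") age else NULL,
              sex = if (m == "multivariate") sex else NULL, model = m),
      error = function(e) NULL)
    if (is.null(fit)) next
    fit_df <- as.data.frame(fit)
    fit_df$model <- m
    fit_df$modality <- modality; fit_df$endpoint <- endpoint; fit_df$group <- group
    fit_df$n <- attr(fit, "n"); fit_df$events <- attr(fit, "events")
    out[[m]] <- fit_df
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Run the full DG analysis pipeline
#'
#' Validates and loads a cohort, scores DG per modality, then reproduces
#' the standard analysis set: Kaplan-Meier log-rank tests at the prior OS/PFS
#' cutoffs (78 and 93 DG) and at cohort-median cutoffs, per treatment group
#' (All, BevAlone, BevCyto); an iterative cutoff sweep per group and
#' endpoint; and univariate/multivariate Cox models with DG per 25 days.
#' Outputs are written to a deterministic run directory:
#' `dg_scores.csv`, `km_table.csv`, `cox_table.csv`, `sweep.csv`,
#' `figures/` (KM curves and sweep significance maps when `plots = TRUE`),
#' and `run.log` with package version, configuration echo, the dichotomy
#' boundary rule, and the per-modality exclusion accounting.
#'
#' @param longitudinal,patients Input table paths (see [load_cohort()]).
#' @param out Output directory (created if absent).
#' @param modality `"T1Gd"`, `"FLAIR"`, or `"both"`.
#' @param cutoff_os,cutoff_pfs Fixed DG cutoffs for OS and PFS.
#' @param median_cutoffs Also analyse at per-group cohort-median cutoffs.
#' @param sweep_step Sweep grid step in DG days.
#' @param min_group_size Minimum per-arm size for sweep evaluability.
#' @param sep Input field separator.
#' @param plots Write PNG figures.
#' @return Invisibly, a list with `scores`, `km_table`, `cox_table`,
#'   `sweep`, `accounting`, and `out`.
#' @export
run_pipeline <- function(longitudinal, patients, out,
                         modality = c("both", "T1Gd", "FLAIR"),
                         cutoff_os = DG_PRIOR_CUTOFFS[["OS"]],
                         cutoff_pfs = DG_PRIOR_CUTOFFS[["PFS"]],
                         median_cutoffs = TRUE,
                         sweep_step = 5, min_group_size = 3,
                         sep = ",", plots = TRUE) {
  modality <- match.arg(modality)
  modalities <- if (modality == "both") DG_MODALITIES else modality

  cohort <- load_cohort(longitudinal, patients, sep = sep)
  for (mod in modalities) {
    if (!any(cohort$observations$modality == mod)) {
      stop("cohort has no ", mod, " observations", call. = FALSE)
    }
  }
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  if (plots && !dir.exists(file.path(out, "figures"))) {
    dir.create(file.path(out, "figures"))
  }

  scores_all <- list(); km_all <- list(); cox_all <- list(); sweep_all <- list()
  accounting <- list()
  pats <- cohort$patients

  for (mod in modalities) {
    scores <- score_cohort(cohort, mod)
    scores_all[[mod]] <- scores
    accounting[[mod]] <- summarize_dg(scores)$counts

    for (ep in c("OS", "PFS")) {
      fixed <- if (ep == "OS") cutoff_os else cutoff_pfs
      for (grp in c("All", "BevAlone", "BevCyto")) {
        km_all[[paste(mod, ep, grp, "prior")]] <-
          km_row(scores, pats, mod, grp, ep, fixed, "prior")
        if (median_cutoffs) {
          km_all[[paste(mod, ep, grp, "median")]] <-
            km_row(scores, pats, mod, grp, ep, NA, "median")
        }
        cox_all[[paste(mod, ep, grp)]] <- cox_rows(scores, pats, mod, grp, ep)

        sc <- scores[scores$status == "scored", , drop = FALSE]
        if (grp != "All") sc <- sc[sc$group == grp, , drop = FALSE]
        if (nrow(sc) >= 2 * min_group_size) {
          idx <- match(sc$patient_id, pats$patient_id)
          time <- if (ep == "OS") pats$os_time_days[idx] else pats$pfs_time_days[idx]
          event <- if (ep == "PFS") pats$pfs_event[idx] else pats$os_event[idx]
          sw <- iterative_km_sweep(sc$dg_days, time, event, step = sweep_step,
                                   min_group_size = min_group_size)
          sw$modality <- mod; sw$endpoint <- ep; sw$group <- grp
          sweep_all[[paste(mod, ep, grp)]] <- as.data.frame(sw)
        }
      }
    }
  }

  scores_df <- do.call(rbind, lapply(scores_all, as.data.frame))
  km_df <- do.call(rbind, km_all)
  cox_df <- if (length(cox_all)) do.call(rbind, Filter(Negate(is.null), cox_all)) else NULL
  sweep_df <- if (length(sweep_all)) do.call(rbind, sweep_all) else NULL
  rownames(scores_df) <- rownames(km_df) <- NULL
  if (!is.null(cox_df)) {
    rownames(cox_df) <- NULL
    cox_df <- cox_df[, c("modality", "endpoint", "group", "model", "variable",
                         "coef", "hr", "ci_low", "ci_high", "p_value",
                         "n", "events")]
  }
  if (!is.null(sweep_df)) rownames(sweep_df) <- NULL

  wt <- function(d, f) if (!is.null(d)) {
    utils::write.table(d, file.path(out, f), sep = ",", row.names = FALSE,
                       quote = FALSE)
  }
  write_dg_scores(scores_df, file.path(out, "dg_scores.csv"))
  wt(km_df, "km_table.csv")
  wt(cox_df, "cox_table.csv")
  wt(sweep_df, "sweep.csv")

  if (plots) {
    for (mod in modalities) {
      plot_km_pipeline(scores_all[[mod]], pats, mod, out)
    }
    if (!is.null(sweep_df)) plot_sweep_map(sweep_df, out)
  }

  log_lines <- c(
    sprintf("daysgained version: %s",
            as.character(utils::packageVersion("daysgained"))),
    sprintf("R version: %s", R.version.string),
    sprintf("survival version: %s",
            as.character(utils::packageVersion("survival"))),
    sprintf("inputs: longitudinal=%s patients=%s", longitudinal, patients),
    sprintf("modality: %s", paste(modalities, collapse = ",")),
    sprintf("cutoffs: OS=%g PFS=%g; median cutoffs: %s", cutoff_os, cutoff_pfs,
            median_cutoffs),
    "boundary rule: DG >= cutoff is High",
    sprintf("sweep: step=%g, min group size=%d, grid 5th-95th percentile",
            sweep_step, as.integer(min_group_size)),
    "sweep p-values are raw per-cutoff log-rank values (no multiplicity correction)",
    unlist(lapply(names(accounting), function(mod) {
      a <- accounting[[mod]]
      sprintf("accounting %s: input=%d scored=%d excluded_nonpositive_velocity=%d ineligible=%d",
              mod, a[["n_input"]], a[["n_scored"]],
              a[["n_excluded_velocity"]], a[["n_ineligible"]])
    }))
  )
  writeLines(log_lines, file.path(out, "run.log"))

  invisible(list(scores = scores_df, km_table = km_df, cox_table = cox_df,
                 sweep = sweep_df, accounting = accounting, out = out))
}

plot_km_pipeline <- function(scores, pats, modality, out) {
  sc <- scores[scores$status == "scored", , drop = FALSE]
  if (nrow(sc) < 4L) return(invisible(NULL))
  idx <- match(sc$patient_id, pats$patient_id)
  grDevices::png(file.path(out, "figures", sprintf("km_%s.png", modality)),
                 width = 900, height = 450)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  for (ep in c("OS", "PFS")) {
    cutoff <- DG_PRIOR_CUTOFFS[[ep]]
    time <- if (ep == "OS") pats$os_time_days[idx] else pats$pfs_time_days[idx]
    event <- if (ep == "PFS") pats$pfs_event[idx] else pats$os_event[idx]
    lab <- dichotomize(sc$dg_days, cutoff)
    if (!attr(lab, "evaluable")) next
    fit <- survival::survfit(survival::Surv(time, event) ~ lab)
    graphics::plot(fit, col = c("firebrick", "navy"), lwd = 2,
                   xlab = "Days from treatment start", ylab = "Survival",
                   main = sprintf("%s %s, cutoff %g DG", modality, ep, cutoff))
    graphics::legend("topright", c("Low DG", "High DG"),
                     col = c("firebrick", "navy"), lwd = 2, bty = "n")
  }
  invisible(NULL)
}

plot_sweep_map <- function(sweep_df, out) {
  grDevices::png(file.path(out, "figures", "sweep_significance.png"),
                 width = 900, height = 600)
  on.exit(grDevices::dev.off())
  combos <- unique(sweep_df[, c("modality", "endpoint", "group")])
  graphics::par(mfrow = c(length(unique(combos$modality)) *
                            length(unique(combos$endpoint)), 1),
                mar = c(2, 8, 1, 1))
  for (mod in unique(combos$modality)) for (ep in unique(combos$endpoint)) {
    d <- sweep_df[sweep_df$modality == mod & sweep_df$endpoint == ep, ]
    graphics::plot(NA, xlim = range(d$cutoff), ylim = c(0, length(unique(d$group))),
                   yaxt = "n", xlab = "DG cutoff", ylab = "",
                   main = sprintf("%s %s", mod, ep))
    grps <- unique(d$group)
    graphics::axis(2, at = seq_along(grps) - 0.5, labels = grps, las = 1)
    for (k in seq_along(grps)) {
      dd <- d[d$group == grps[k], ]
      sig <- dd$evaluable & !is.na(dd$p_value) & dd$p_value <= 0.05
      graphics::rect(dd$cutoff - 2, k - 1, dd$cutoff + 2, k,
                     col = ifelse(!dd$evaluable, "grey80",
                                  ifelse(sig, "white", "grey40")),
                     border = NA)
    }
  }
  invisible(NULL)
}
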