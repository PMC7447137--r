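# Survival layer: cutoff dichotomization, Kaplan-Meier + log-rank,
# iterative threshold sweep, Cox proportional hazards with DG per 25 days.

#' Prior DG cutoffs from the newly diagnosed setting
#'
#' Optimal T1Gd DG thresholds identified in newly diagnosed glioblastoma
#' under first-line therapy: 78 DG for overall survival and 93 DG for
#' progression-free survival. Reusing them avoids re-optimising a cutoff on
#' the cohort under analysis.
#'
#' @format Named numeric vector with elements `OS = 78` and `PFS = 93`.
#' @export
DG_PRIOR_CUTOFFS <- c(OS = 78, PFS = 93)

#' Dichotomize DG scores at a cutoff
#'
#' Splits scores into High and Low response groups. The boundary rule is
#' fixed for reproducibility: a score exactly equal to the cutoff is High
#' (High iff `dg >= cutoff`).
#'
#' @param dg Numeric DG scores (finite).
#' @param cutoff Cutoff in DG days.
#' @return Factor with levels `c("Low", "High")` and attributes `cutoff`,
#'   `n_high`, `n_low`, and `evaluable` (`FALSE` when one side is empty, in
#'   which case a log-rank comparison is impossible).
#' @export
dichotomize <- function(dg, cutoff) {
  if (any(!is.finite(dg))) stop("DG scores must be finite", call. = FALSE)
  lab <- factor(ifelse(dg >= cutoff, "High", "Low"), levels = c("Low", "High"))
  structure(lab, cutoff = cutoff,
            n_high = sum(lab == "High"), n_low = sum(lab == "Low"),
            evaluable = all(table(lab) > 0L))
}

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' Product-limit survival estimates per response group and the standard
#' (unweighted) two-sample log-rank test, with the p-value from the
#' chi-square reference with one degree of freedom. Delegates estimation to
#' the survival package.
#'
#' @param time Follow-up times in days (>= 0).
#' @param event Event indicator, 1 = event observed, 0 = censored.
#' @param group Two-level factor or character vector (e.g. output of
#'   [dichotomize()]).
#' @return A list of class `dg_km`: `curves` (data frame of per-group step
#'   functions: group, time, n_risk, n_event, survival), `chisq`, `p_value`,
#'   `n` (per-group sizes), `evaluable`.
#' @export
km_logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time < 0)) stop("survival times must be non-negative", call. = FALSE)
  group <- factor(group)
  tab <- table(group)
  if (length(tab) != 2L || any(tab == 0L)) {
    return(structure(list(curves = NULL, chisq = NA_real_, p_value = NA_real_,
                          n = as.vector(tab), evaluable = FALSE),
                     class = "dg_km"))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  sm <- summary(fit, censored = TRUE)
  curves <- data.frame(group = sub("^group=", "", as.character(sm$strata)),
                       time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
                       survival = sm$surv, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  chisq <- sd$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  structure(list(curves = curves, chisq = chisq, p_value = p,
                 n = as.vector(tab), evaluable = TRUE),
            class = "dg_km")
}

#' Iterative Kaplan-Meier cutoff sweep
#'
#' Scans a grid of DG cutoffs; at each one the cohort is dichotomized and
#' the log-rank test run, producing the data behind a threshold-significance
#' map. Cutoffs leaving fewer than `min_group_size` subjects in either arm
#' are flagged not-evaluable rather than tested. P-values are raw per-cutoff
#' log-rank values; no multiple-testing correction is applied, and the sweep
#' is descriptive, not a cutoff-selection procedure.
#'
#' @param dg DG scores.
#' @param time,event Survival follow-up as in [km_logrank()].
#' @param grid Numeric vector of cutoffs (strictly increasing). If `NULL`,
#'   a default grid is built from the 5th to the 95th percentile of `dg` in
#'   steps of `step`.
#' @param step Grid step in DG days (used only when `grid` is `NULL`).
#' @param min_group_size Minimum subjects per arm for a cutoff to be
#'   evaluable.
#' @return Data frame of class `dg_sweep`: `cutoff`, `n_high`, `n_low`,
#'   `chisq`, `p_value`, `evaluable`, with attributes `step` and
#'   `min_group_size`.
#' @export
iterative_km_sweep <- function(dg, time, event, grid = NULL, step = 5,
                               min_group_size = 3) {
  if (is.null(grid)) {
    q <- stats::quantile(dg, c(0.05, 0.95), names = FALSE)
    grid <- seq(from = ceiling(q[1] / step) * step, to = q[2], by = step)
  }
  if (length(grid) == 0L) stop("sweep grid is empty", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("sweep grid must be strictly increasing", call. = FALSE)
  }
  rows <- lapply(grid, function(ct) {
    lab <- dichotomize(dg, ct)
    n_high <- attr(lab, "n_high"); n_low <- attr(lab, "n_low")
    if (min(n_high, n_low) < min_group_size) {
      return(data.frame(cutoff = ct, n_high = n_high, n_low = n_low,
                        chisq = NA_real_, p_value = NA_real_, evaluable = FALSE))
    }
    km <- km_logrank(time, event, lab)
    data.frame(cutoff = ct, n_high = n_high, n_low = n_low,
               chisq = km$chisq, p_value = km$p_value, evaluable = km$evaluable)
  })
  out <- do.call(rbind, rows)
  attr(out, "step") <- step
  attr(out, "min_group_size") <- min_group_size
  class(out) <- c("dg_sweep", "data.frame")
  out
}

#' Cox proportional-hazards model with DG per 25 days
#'
#' Fits the partial-likelihood Cox model used for continuous DG analysis.
#' DG enters as `dg / 25`, so the reported hazard ratio is per 25 DG. The
#' univariate model has DG alone; the multivariate model adds age at
#' treatment start and sex (coded M = 1 vs F = 0). Ties are handled with the
#' Efron approximation; confidence intervals and p-values are Wald on the
#' log-hazard scale.
#'
#' @param dg DG scores in days.
#' @param time,event Survival follow-up (>= 2 observed events required).
#' @param age Age at treatment start in years (multivariate only).
#' @param sex `"M"`/`"F"` (multivariate only).
#' @param model `"univariate"` or `"multivariate"`.
#' @return A data frame of class `dg_cox`: one row per covariate with
#'   `variable` (`dg_per25`, `age`, `sex_M`), `coef`, `hr`, `ci_low`,
#'   `ci_high`, `p_value`, plus attributes `model`, `n`, `events`.
#' @export
cox_fit <- function(dg, time, event, age = NULL, sex = NULL,
                    model = c("univariate", "multivariate")) {
  model <- match.arg(model)
  if (sum(event) < 2L) stop("at least 2 observed events are required", call. = FALSE)
  df <- data.frame(time = time, event = event, dg_per25 = dg / 25)
  if (model == "multivariate") {
    if (is.null(age) || is.null(sex)) {
      stop("multivariate model requires age and sex", call. = FALSE)
    }
    df$age <- age
    df$sex_M <- as.numeric(sex == "M")
    form <- survival::Surv(time, event) ~ dg_per25 + age + sex_M
  } else {
    form <- survival::Surv(time, event) ~ dg_per25
  }
  covars <- all.vars(form)[-(1:2)]
  const <- vapply(covars, function(v) stats::var(df[[v]]) == 0, TRUE)
  if (any(const)) {
    stop("covariate(s) constant across patients: ",
         paste(covars[const], collapse = ", "), call. = FALSE)
  }
  fit <- survival::coxph(form, data = df, ties = "efron")
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info))) {
    stop("Cox model did not converge", call. = FALSE)
  }
  s <- summary(fit)
  out <- data.frame(
    variable = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    ci_low = s$conf.int[, "lower .95"],
    ci_high = s$conf.int[, "upper .95"],
    p_value = s$coefficients[, "Pr(>|z|)"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "model") <- model
  attr(out, "n") <- s$n
  attr(out, "events") <- s$nevent
  class(out) <- c("dg_cox", "data.frame")
  out
}

#' Convert a hazard ratio to a percent hazard reduction
#'
#' For a hazard ratio per 25 DG, `(1 - hr) * 100` is the percent reduction
#' in hazard per 25-day gain; reported rounded to one decimal. Negative when
#' the hazard ratio exceeds 1.
#'
#' @param hr Hazard ratio(s), strictly positive.
#' @return Percent reduction rounded to one decimal.
#' @export
hazard_reduction_percent <- function(hr) {
  if (any(!is.finite(hr)) || any(hr <= 0)) {
    stop("hazard ratio must be positive and finite", call. = FALSE)
  }
  round((1 - hr) * 100, 1)
}
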