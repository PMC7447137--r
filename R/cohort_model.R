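# Cohort data model: longitudinal imaging table, patient table, eligibility
# and treatment-group rules.

#' Imaging modalities recognised by the cohort model
#'
#' Tumor abnormality is segmented on T1-weighted gadolinium-enhanced MRI
#' (contrast-enhancing lesion) and on FLAIR MRI (non-enhancing/edematous
#' abnormality); every volumetric observation carries one of these labels.
#'
#' @format Character vector of length two: `c("T1Gd", "FLAIR")`.
#' @export
DG_MODALITIES <- c("T1Gd", "FLAIR")

# Parse a vector of scan dates. Accepts ISO-8601 calendar dates or plain
# integer day offsets; returns numeric days (Date is converted to days since
# epoch, so differences are whole days either way). NA marks unparseable
# entries.
parse_days <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  is_int <- grepl("^-?[0-9]+$", x)
  out[is_int] <- as.numeric(x[is_int])
  if (any(!is_int)) {
    d <- as.Date(x[!is_int], format = "%Y-%m-%d")
    out[!is_int] <- as.numeric(d)
  }
  out
}

required_longitudinal_cols <- c("patient_id", "scan_date", "modality", "volume_mm3")
required_patient_cols <- c(
  "patient_id", "treatment_start", "age_at_start", "sex", "cytotoxic_dates",
  "os_time_days", "os_event", "pfs_time_days", "pfs_event"
)

stop_missing_cols <- function(have, need, what) {
  miss <- setdiff(need, have)
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
}

report_bad_rows <- function(bad, table_name, problem) {
  if (length(bad) == 0L) return(invisible(NULL))
  stop(sprintf("%s: %s in row(s) %s", table_name, problem,
               paste(bad, collapse = ", ")), call. = FALSE)
}

#' Read and validate a longitudinal + patient cohort
#'
#' Reads the two delimited text tables that define a cohort: a longitudinal
#' table with one row per (patient, scan date, modality) volumetric
#' measurement, and a patient table with treatment start, demographics,
#' concurrent cytotoxic dosing dates, and OS/PFS follow-up. All rows are
#' validated; any unparseable or invariant-violating row aborts the load with
#' a message naming the offending rows — nothing is silently dropped.
#'
#' @param longitudinal Path to the longitudinal table. Required columns:
#'   `patient_id`, `scan_date` (ISO-8601 date or integer day offset),
#'   `modality` (`"T1Gd"` or `"FLAIR"`), `volume_mm3` (non-negative).
#' @param patients Path to the patient table. Required columns:
#'   `patient_id`, `treatment_start`, `age_at_start`, `sex` (`"M"`/`"F"`),
#'   `cytotoxic_dates` (semicolon-separated dates, possibly empty),
#'   `os_time_days`, `os_event`, `pfs_time_days`, `pfs_event`
#'   (event indicators: 1 = observed, 0 = censored).
#' @param sep Field separator; comma by default, tab accepted.
#' @return A list of class `dg_cohort` with elements `observations` and
#'   `patients` (data frames with parsed date columns in numeric days).
#' @export
load_cohort <- function(longitudinal, patients, sep = ",") {
  if (!file.exists(longitudinal)) stop("longitudinal table not found: ", longitudinal)
  if (!file.exists(patients)) stop("patient table not found: ", patients)

  obs <- utils::read.table(longitudinal, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character")
  pat <- utils::read.table(patients, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character")
  stop_missing_cols(names(obs), required_longitudinal_cols, "longitudinal table")
  stop_missing_cols(names(pat), required_patient_cols, "patient table")

  if (nrow(obs) == 0L) {
    warning("longitudinal table has a header but no rows", call. = FALSE)
    observations <- data.frame(patient_id = character(), scan_date = numeric(),
                               modality = character(), volume_mm3 = numeric(),
                               stringsAsFactors = FALSE)
  } else {
    scan_days <- parse_days(obs$scan_date)
    report_bad_rows(which(is.na(scan_days)), "longitudinal table",
                    "unparseable scan_date")
    report_bad_rows(which(!obs$modality %in% DG_MODALITIES), "longitudinal table",
                    sprintf("modality not in {%s}", paste(DG_MODALITIES, collapse = ", ")))
    vol <- suppressWarnings(as.numeric(obs$volume_mm3))
    report_bad_rows(which(is.na(vol)), "longitudinal table", "unparseable volume_mm3")
    report_bad_rows(which(vol < 0), "longitudinal table", "negative volume_mm3")
    key <- paste(obs$patient_id, scan_days, obs$modality, sep = "\r")
    report_bad_rows(which(duplicated(key)), "longitudinal table",
                    "duplicate (patient_id, scan_date, modality)")
    observations <- data.frame(patient_id = obs$patient_id, scan_date = scan_days,
                               modality = obs$modality, volume_mm3 = vol,
                               stringsAsFactors = FALSE)
  }

  start_days <- parse_days(pat$treatment_start)
  report_bad_rows(which(is.na(start_days)), "patient table",
                  "unparseable treatment_start")
  age <- suppressWarnings(as.numeric(pat$age_at_start))
  report_bad_rows(which(is.na(age) | age <= 0), "patient table",
                  "age_at_start must be a positive number")
  report_bad_rows(which(!pat$sex %in% c("M", "F")), "patient table",
                  "sex must be M or F")
  num_cols <- c("os_time_days", "pfs_time_days")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(pat[[cc]]))
    report_bad_rows(which(is.na(v) | v < 0), "patient table",
                    sprintf("%s must be a non-negative number", cc))
    pat[[cc]] <- v
  }
  for (cc in c("os_event", "pfs_event")) {
    v <- suppressWarnings(as.integer(pat[[cc]]))
    report_bad_rows(which(is.na(v) | !v %in% c(0L, 1L)), "patient table",
                    sprintf("%s must be 0 or 1", cc))
    pat[[cc]] <- v
  }
  report_bad_rows(which(duplicated(pat$patient_id)), "patient table",
                  "duplicate patient_id")

  cyto <- lapply(pat$cytotoxic_dates, function(s) {
    s <- trimws(s)
    if (is.na(s) || s == "") return(numeric(0))
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    parts <- parts[parts != ""]
    d <- parse_days(parts)
    if (anyNA(d)) stop("patient table: unparseable cytotoxic_dates entry '", s, "'",
                       call. = FALSE)
    d
  })

  patients_df <- data.frame(patient_id = pat$patient_id,
                            treatment_start = start_days,
                            age_at_start = age, sex = pat$sex,
                            os_time_days = pat$os_time_days,
                            os_event = pat$os_event,
                            pfs_time_days = pat$pfs_time_days,
                            pfs_event = pat$pfs_event,
                            stringsAsFactors = FALSE)
  patients_df$cytotoxic_dates <- cyto

  structure(list(observations = observations, patients = patients_df),
            class = "dg_cohort")
}

#' Write a cohort back to delimited text
#'
#' Inverse of [load_cohort()]: writes the longitudinal and patient tables in
#' the package's file format. Numeric day values are written as ISO dates
#' when `origin` is supplied, otherwise as plain integer day offsets.
#'
#' @param cohort A `dg_cohort` list (or any list with `observations` and
#'   `patients` in the loader's parsed form).
#' @param longitudinal,patients Output file paths.
#' @param sep Field separator.
#' @param as_date Write day values as ISO-8601 dates (`TRUE`, default) or as
#'   bare integer offsets.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, longitudinal, patients, sep = ",", as_date = TRUE) {
  fmt <- function(d) {
    if (as_date) format(as.Date(d, origin = "1970-01-01"), "%Y-%m-%d")
    else format(d, scientific = FALSE, trim = TRUE)
  }
  obs <- cohort$observations
  obs_out <- data.frame(patient_id = obs$patient_id, scan_date = fmt(obs$scan_date),
                        modality = obs$modality, volume_mm3 = obs$volume_mm3,
                        stringsAsFactors = FALSE)
  pat <- cohort$patients
  cyto_str <- vapply(pat$cytotoxic_dates, function(d) paste(fmt(d), collapse = ";"), "")
  pat_out <- data.frame(patient_id = pat$patient_id,
                        treatment_start = fmt(pat$treatment_start),
                        age_at_start = pat$age_at_start, sex = pat$sex,
                        cytotoxic_dates = cyto_str,
                        os_time_days = pat$os_time_days, os_event = pat$os_event,
                        pfs_time_days = pat$pfs_time_days, pfs_event = pat$pfs_event,
                        stringsAsFactors = FALSE)
  utils::write.table(obs_out, longitudinal, sep = sep, row.names = FALSE, quote = FALSE)
  utils::write.table(pat_out, patients, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(c(longitudinal = longitudinal, patients = patients))
}

#' Select the DG scan triplet for one patient and modality
#'
#' The DG method uses exactly three scans: the two scan dates strictly before
#' the start of bevacizumab (`pre1` earlier, `pre2` later — the two most
#' recent pre-treatment dates) and the first scan on or after the start
#' (`post1`). A scan on the treatment-start date itself counts as
#' post-treatment. With fewer than two pre-treatment or no post-treatment
#' scan the case is ineligible and the reason is returned instead.
#'
#' @param observations Data frame with columns `scan_date` (numeric days) and
#'   `volume_mm3`, for a single patient and modality; row order is irrelevant.
#' @param treatment_start Treatment start in the same day units.
#' @return A list with `eligible = TRUE` and rows `pre1`, `pre2`, `post1`
#'   (each a one-row data frame), or `eligible = FALSE` with `reason` one of
#'   `"missing_pretreatment_scan"`, `"missing_posttreatment_scan"`.
#' @export
select_dg_scans <- function(observations, treatment_start) {
  o <- observations[order(observations$scan_date), , drop = FALSE]
  pre <- o[o$scan_date < treatment_start, , drop = FALSE]
  post <- o[o$scan_date >= treatment_start, , drop = FALSE]
  if (nrow(pre) < 2L) {
    return(list(eligible = FALSE, reason = "missing_pretreatment_scan"))
  }
  if (nrow(post) < 1L) {
    return(list(eligible = FALSE, reason = "missing_posttreatment_scan"))
  }
  pre1 <- pre[nrow(pre) - 1L, , drop = FALSE]
  pre2 <- pre[nrow(pre), , drop = FALSE]
  if (pre1$scan_date == pre2$scan_date) {
    stop("two pre-treatment scans share the same date; growth velocity undefined",
         call. = FALSE)
  }
  list(eligible = TRUE, pre1 = pre1, pre2 = pre2, post1 = post[1L, , drop = FALSE])
}

#' Assign the treatment group from the cytotoxic dosing window
#'
#' A case is `BevCyto` (bevacizumab plus concurrent cytotoxic agent) when any
#' cytotoxic dose falls in the DG evaluation window — after the second
#' pre-treatment scan and up to and including the first post-treatment scan,
#' i.e. the half-open interval (pre2, post1]. Otherwise the case is
#' `BevAlone`.
#'
#' @param cytotoxic_dates Numeric vector of dosing days (possibly empty).
#' @param pre2_date,post1_date Window endpoints in days; `pre2_date` must
#'   precede `post1_date`.
#' @return `"BevCyto"` or `"BevAlone"`.
#' @export
assign_treatment_group <- function(cytotoxic_dates, pre2_date, post1_date) {
  stopifnot(pre2_date < post1_date)
  if (length(cytotoxic_dates) > 0 &&
      any(cytotoxic_dates > pre2_date & cytotoxic_dates <= post1_date)) {
    "BevCyto"
  } else {
    "BevAlone"
  }
}
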