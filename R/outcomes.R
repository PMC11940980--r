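# First-line outcomes: censored treatment duration, Kaplan-Meier product-limit
# estimate (through survival::survfit, with the median extracted under the
# "smallest t with S(t) <= 0.5" convention), time to next treatment, and the
# SACT period used as the costing window.

#' Compute censored first-line treatment durations
#'
#' Duration runs from the index date (line-1 start) to the earliest of: the
#' maximum runout date over all line-1 therapies, the day before the next line
#' starts, the study end date, or the end of follow-up — as an inclusive day
#' count. The record is censored when the end was imposed by study end or
#' follow-up end (not death) before any of the treatment-defined ends.
#'
#' @param lots Line segments from [derive_lots()].
#' @param ds A `claims_dataset` (for death dates).
#' @param config An [analysis_config()].
#' @return data.table: `patient_id`, `category`, `duration_days`, `censored`.
#' @export
compute_durations <- function(lots, ds, config = default_config()) {
  l1 <- lots[lot_number == 1L]
  if (nrow(l1) == 0L) {
    return(data.table(patient_id = character(), category = character(),
                      duration_days = integer(), censored = logical()))
  }
  l2 <- lots[lot_number == 2L, .(patient_id, next_start = start_date)]
  l1 <- merge(l1, l2, by = "patient_id", all.x = TRUE)
  l1 <- merge(l1, ds$patients[, .(patient_id, death_date)], by = "patient_id")

  far <- as.Date("9999-12-31")
  l1[, nat_end := pmin_date(max_runout,
                            fifelse(is.na(next_start), far, next_start - 1L),
                            fifelse(is.na(death_date), far, death_date))]
  l1[, adm_end := pmin_date(rep(config$study_end, .N), followup_end)]
  l1[, dur_end := pmin_date(nat_end, adm_end)]
  l1[, duration_days := days_between(start_date, dur_end) + 1L]
  # censored iff the administrative end bites strictly before a treatment-defined
  # end, and the administrative end is not the patient's death
  l1[, censored := adm_end < nat_end &
       !(!is.na(death_date) & adm_end == death_date)]
  if (any(l1$duration_days < 0L)) stopf("negative 1L duration: invariant breach upstream")
  l1[, .(patient_id, category, duration_days, censored)]
}

#' Kaplan-Meier product-limit fit of treatment duration
#'
#' Product-limit estimator over censored duration records: at each distinct
#' event time with `d` events among `n` at risk, survival multiplies by
#' `1 - d/n`. The median is the smallest time with S(t) <= 0.5 (no
#' interpolation) and is undefined when S never reaches 0.5.
#'
#' @param records Duration records from [compute_durations()] (needs
#'   `duration_days`, `censored`).
#' @param config An [analysis_config()] (month length for the median in months).
#' @return List of class `oncolot_km`: `time` (days), `surv`, `n_risk`,
#'   `n_event`, `median_days`, `median_months`, `n`.
#' @export
km_fit <- function(records, config = default_config()) {
  if (nrow(records) == 0L) stopf("km_fit needs at least one duration record")
  fit <- survival::survfit(
    survival::Surv(time = records$duration_days,
                   event = !records$censored) ~ 1)
  time <- fit$time; surv <- fit$surv
  med <- time[surv <= 0.5 + 1e-12]
  median_days <- if (length(med)) min(med) else NA_real_
  out <- list(time = time, surv = surv, n_risk = fit$n.risk,
              n_event = fit$n.event, median_days = median_days,
              median_months = median_days / config$month_length_days,
              n = nrow(records))
  class(out) <- "oncolot_km"
  out
}

#' @export
print.oncolot_km <- function(x, ...) {
  cat(sprintf("<Kaplan-Meier fit> n = %d, events = %d, median = %s days\n",
              x$n, sum(x$n_event),
              if (is.na(x$median_days)) "undefined" else format(x$median_days)))
  invisible(x)
}

#' Time to next treatment
#'
#' For patients with a second line, the number of days from the 1L start to the
#' day before the 2L start, counted inclusively (equal to `2L start - 1L start`
#' in days). Patients without a second line have no record.
#'
#' @param lots Line segments from [derive_lots()].
#' @return data.table: `patient_id`, `ttnt_days`.
#' @export
compute_ttnt <- function(lots) {
  l1 <- lots[lot_number == 1L, .(patient_id, l1_start = start_date)]
  l2 <- lots[lot_number == 2L, .(patient_id, l2_start = start_date)]
  t <- merge(l1, l2, by = "patient_id")
  t[, .(patient_id, ttnt_days = days_between(l1_start, l2_start))]
}

#' SACT-period costing windows
#'
#' The costing window runs from the index date to the earliest of: 30 days after
#' the maximum runout over all line-1 treatments, the day before the 2L start,
#' or the end of follow-up. Utilization and costs are attributed only inside
#' this window.
#'
#' @param lots Line segments from [derive_lots()].
#' @param config An [analysis_config()].
#' @return data.table: `patient_id`, `start_date`, `end_date`, `period_days`.
#' @export
compute_sact_periods <- function(lots, config = default_config()) {
  l1 <- lots[lot_number == 1L]
  l2 <- lots[lot_number == 2L, .(patient_id, next_start = start_date)]
  sp <- merge(l1, l2, by = "patient_id", all.x = TRUE)
  far <- as.Date("9999-12-31")
  sp[, end_date := pmin_date(max_runout + config$sact_period_tail_days,
                             fifelse(is.na(next_start), far, next_start - 1L),
                             pmin_date(followup_end, rep(config$study_end, .N)))]
  sp[, period_days := days_between(start_date, end_date) + 1L]
  if (any(sp$period_days < 1L)) {
    warnf("%d SACT period(s) of zero length excluded", sum(sp$period_days < 1L))
    sp <- sp[period_days >= 1L]
  }
  sp[, .(patient_id, category, start_date, end_date, period_days)]
}
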