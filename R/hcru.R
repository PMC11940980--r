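# HCRU and cost module: claim attribution (setting, SACT-period membership,
# NSCLC relatedness, CPI-adjusted cost), per-patient-per-month rates, and the
# summary table by treatment category x setting x scope.

HCRU_SETTINGS <- c("OUTPATIENT", "INPATIENT", "ED", "PHARMACY")

#' Flag a claim as NSCLC-related
#'
#' A claim is NSCLC-related if any diagnosis code in any position has a
#' lung-cancer prefix (default C34), or if its drug is a lung-cancer-related
#' medication (any systemic-anticancer class).
#'
#' @param dx_codes Character vector of pipe-delimited diagnosis code fields.
#' @param drug_code Character vector of drug codes (`NA`/empty for none).
#' @param dictionary Drug dictionary.
#' @param config An [analysis_config()].
#' @return Logical vector.
#' @export
flag_nsclc_related <- function(dx_codes, drug_code, dictionary,
                               config = default_config()) {
  pat <- paste0("(^|\\|)(", paste(gsub(".", "", config$lung_cancer_prefixes,
                                       fixed = TRUE), collapse = "|"), ")")
  dx_hit <- grepl(pat, gsub(".", "", dx_codes %||% "", fixed = TRUE))
  sact_codes <- dictionary[is_sact(drug_class), drug_code]
  drug_hit <- !is.na(drug_code) & drug_code %in% sact_codes
  dx_hit | drug_hit
}

#' Adjust a paid amount to reference-year dollars
#'
#' Multiplies by the ratio of the reference-year medical CPI to the service-year
#' medical CPI. A service year missing from the CPI table is fatal.
#'
#' @param paid_amount Numeric vector of paid amounts.
#' @param service_year Integer vector of service years.
#' @param config An [analysis_config()] carrying `cpi_table`/`reference_year`.
#' @return Numeric vector in reference-year dollars.
#' @export
adjust_cost <- function(paid_amount, service_year, config = default_config()) {
  cpi <- config$cpi_table
  miss <- setdiff(unique(service_year), as.integer(names(cpi)))
  if (length(miss)) stopf("CPI table lacks service year(s): %s",
                          paste(miss, collapse = ", "))
  ref <- cpi[[as.character(config$reference_year)]]
  paid_amount * ref / unname(cpi[as.character(service_year)])
}

#' Per-patient-per-month rate
#'
#' Divides a count or summed cost by the observed period length expressed in
#' months (`period_days / month_length_days`).
#'
#' @param value Numeric vector (count or cost within the period).
#' @param period_days Integer vector of period lengths (>= 1 day).
#' @param config An [analysis_config()].
#' @return Numeric PPPM values.
#' @export
compute_pppm <- function(value, period_days, config = default_config()) {
  if (any(period_days < 1L)) stopf("compute_pppm: zero-length period")
  value / (period_days / config$month_length_days)
}

# Attribute every claim: setting, in-period membership, NSCLC flag, adjusted
# cost. One row per claim (medical and pharmacy).
attribute_claims <- function(ds, periods, config = default_config()) {
  med <- ds$medical_claims[, .(claim_id, patient_id, date = service_date,
                               setting, dx_codes, drug_code, paid_amount,
                               service_year)]
  rx <- ds$pharmacy_claims[, .(claim_id, patient_id, date = fill_date,
                               setting = "PHARMACY", dx_codes = "", drug_code,
                               paid_amount)]
  rx[, service_year := as.integer(format(date, "%Y"))]
  att <- rbind(med, rx)
  att <- merge(att, periods[, .(patient_id, p_start = start_date, p_end = end_date)],
               by = "patient_id")
  att[, in_sact_period := date >= p_start & date <= p_end]
  att[, nsclc_related := flag_nsclc_related(dx_codes, drug_code,
                                            ds$drug_dictionary, config)]
  att[, adjusted_cost := adjust_cost(paid_amount, service_year, config)]
  att
}

# Collapse in-period inpatient claim dates into stays: consecutive dates abut
# into one admission.
count_admissions <- function(att) {
  inp <- unique(att[setting == "INPATIENT" & in_sact_period,
                    .(patient_id, date, nsclc_related)])
  if (nrow(inp) == 0L) {
    return(data.table(patient_id = character(), admissions = integer(),
                      admissions_nsclc = integer()))
  }
  days <- unique(inp[, .(patient_id, date)])
  setorder(days, patient_id, date)
  days[, new_stay := c(TRUE, diff(as.integer(date)) > 1L), by = patient_id]
  days[, stay_id := cumsum(new_stay), by = patient_id]
  inp <- merge(inp, days[, .(patient_id, date, stay_id)], by = c("patient_id", "date"))
  stays <- inp[, .(nsclc = any(nsclc_related)), by = .(patient_id, stay_id)]
  stays[, .(admissions = .N, admissions_nsclc = sum(nsclc)), by = patient_id]
}

#' Per-patient HCRU and cost table within the SACT period
#'
#' For every patient with a SACT period: outpatient visit count (outpatient
#' claims), inpatient admissions (consecutive inpatient claim dates collapsed
#' into stays), ED visits, pharmacy fills, and CPI-adjusted costs per setting,
#' each all-cause and NSCLC-related, plus the PPPM versions. Claims outside the
#' SACT period contribute nothing.
#'
#' @param ds A `claims_dataset`.
#' @param periods SACT periods from [compute_sact_periods()].
#' @param config An [analysis_config()].
#' @return data.table, one row per patient: counts `visits_<setting>`, costs
#'   `cost_<setting>`, `cost_total`, NSCLC-scoped twins with suffix `_nsclc`,
#'   and PPPM columns prefixed `pppm_`.
#' @export
patient_hcru <- function(ds, periods, config = default_config()) {
  att <- attribute_claims(ds, periods, config)
  inp <- count_admissions(att)
  inper <- att[in_sact_period == TRUE]

  counts <- inper[, .(
    visits_outpatient = sum(setting == "OUTPATIENT"),
    visits_ed = sum(setting == "ED"),
    fills_pharmacy = sum(setting == "PHARMACY"),
    visits_outpatient_nsclc = sum(setting == "OUTPATIENT" & nsclc_related),
    visits_ed_nsclc = sum(setting == "ED" & nsclc_related),
    fills_pharmacy_nsclc = sum(setting == "PHARMACY" & nsclc_related),
    cost_outpatient = sum(adjusted_cost[setting == "OUTPATIENT"]),
    cost_inpatient = sum(adjusted_cost[setting == "INPATIENT"]),
    cost_ed = sum(adjusted_cost[setting == "ED"]),
    cost_pharmacy = sum(adjusted_cost[setting == "PHARMACY"]),
    cost_outpatient_nsclc = sum(adjusted_cost[setting == "OUTPATIENT" & nsclc_related]),
    cost_inpatient_nsclc = sum(adjusted_cost[setting == "INPATIENT" & nsclc_related]),
    cost_ed_nsclc = sum(adjusted_cost[setting == "ED" & nsclc_related]),
    cost_pharmacy_nsclc = sum(adjusted_cost[setting == "PHARMACY" & nsclc_related])
  ), by = patient_id]

  out <- merge(periods, counts, by = "patient_id", all.x = TRUE)
  out <- merge(out, inp, by = "patient_id", all.x = TRUE)
  num_cols <- setdiff(names(out), c("patient_id", "category", "start_date",
                                    "end_date", "period_days"))
  for (cc in num_cols) data.table::set(out, which(is.na(out[[cc]])), cc, 0)
  out[, `:=`(cost_total = cost_outpatient + cost_inpatient + cost_ed + cost_pharmacy,
             cost_total_nsclc = cost_outpatient_nsclc + cost_inpatient_nsclc +
               cost_ed_nsclc + cost_pharmacy_nsclc)]
  measure_cols <- c("visits_outpatient", "admissions", "visits_ed", "fills_pharmacy",
                    "visits_outpatient_nsclc", "admissions_nsclc", "visits_ed_nsclc",
                    "fills_pharmacy_nsclc",
                    "cost_outpatient", "cost_inpatient", "cost_ed", "cost_pharmacy",
                    "cost_total", "cost_outpatient_nsclc", "cost_inpatient_nsclc",
                    "cost_ed_nsclc", "cost_pharmacy_nsclc", "cost_total_nsclc")
  for (cc in measure_cols) {
    out[, (paste0("pppm_", cc)) := compute_pppm(get(cc), period_days, config)]
  }
  out[]
}

#' Summarize PPPM utilization and costs by category, setting and scope
#'
#' Patient-level PPPM values are computed first (within the SACT period), then
#' summarized: mean, SD, median and IQR per treatment category x setting x
#' scope (all-cause vs NSCLC-related), with a pooled `ALL` category row. Total
#' cost is the per-patient sum across settings before averaging.
#'
#' @param ph Per-patient table from [patient_hcru()].
#' @return data.table: `category`, `scope`, `measure`, `setting`, `mean_pppm`,
#'   `sd_pppm`, `median_pppm`, `q1_pppm`, `q3_pppm`, `n`.
#' @export
summarize_hcru <- function(ph) {
  spec <- data.table(
    col = c("pppm_visits_outpatient", "pppm_admissions", "pppm_visits_ed",
            "pppm_fills_pharmacy", "pppm_cost_outpatient", "pppm_cost_inpatient",
            "pppm_cost_ed", "pppm_cost_pharmacy", "pppm_cost_total",
            "pppm_visits_outpatient_nsclc", "pppm_admissions_nsclc",
            "pppm_visits_ed_nsclc", "pppm_fills_pharmacy_nsclc",
            "pppm_cost_outpatient_nsclc", "pppm_cost_inpatient_nsclc",
            "pppm_cost_ed_nsclc", "pppm_cost_pharmacy_nsclc",
            "pppm_cost_total_nsclc"),
    measure = rep(c("visits", "admissions", "visits", "fills",
                    "cost", "cost", "cost", "cost", "cost"), 2),
    setting = rep(c("OUTPATIENT", "INPATIENT", "ED", "PHARMACY",
                    "OUTPATIENT", "INPATIENT", "ED", "PHARMACY", "TOTAL"), 2),
    scope = rep(c("ALL_CAUSE", "NSCLC_RELATED"), each = 9)
  )
  if (nrow(ph) == 0L) {
    return(data.table(category = character(), scope = character(),
                      measure = character(), setting = character(),
                      mean_pppm = numeric(), sd_pppm = numeric(),
                      median_pppm = numeric(), q1_pppm = numeric(),
                      q3_pppm = numeric(), n = integer()))
  }
  one <- function(dt, cat_label) {
    rbindlist(lapply(seq_len(nrow(spec)), function(i) {
      v <- dt[[spec$col[i]]]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      data.table(category = cat_label, scope = spec$scope[i],
                 measure = spec$measure[i], setting = spec$setting[i],
                 mean_pppm = mean(v),
                 sd_pppm = if (length(v) > 1L) stats::sd(v) else 0,
                 median_pppm = q[2], q1_pppm = q[1], q3_pppm = q[3],
                 n = length(v))
    }))
  }
  res <- list(one(ph, "ALL"))
  for (cat in sort(unique(ph$category))) {
    res[[length(res) + 1L]] <- one(ph[category == cat], cat)
  }
  rbindlist(res)
}
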