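# Cohort selection: key dates (lung-cancer diagnosis, secondary malignancy,
# 1L SACT start = index), the eligibility cascade with an attrition table, and
# baseline characteristics over the 180-day lookback.

ATTRITION_LABELS <- c(
  dx           = "Diagnosis of lung cancer (Dx date)",
  sm           = "Diagnosis of secondary malignancy on or after Dx date",
  sact         = "SACT for NSCLC on or after diagnosis of secondary malignancy",
  index_2020   = "≥1 LOT initiated on or after 1 January 2020 (index date)",
  enrollment   = "Continuously enrolled for ≥180 days before diagnosis to ≥30 days after index date",
  no_sclc      = "No medications typically administered for SCLC before the index date",
  no_targeted  = "No claims for targeted treatment during the study period",
  no_prior_sm  = "No diagnosis of secondary malignancy or use of SACT within 180 days prior to Dx date",
  age_18       = "Age ≥ 18 years on the index date",
  nsclc_sact   = "1L SACT for NSCLC"
)

#' Derive the lung-cancer diagnosis date per patient
#'
#' The Dx date is the earliest service date of any medical claim carrying a
#' lung-cancer diagnosis code (default prefix C34) in any position, within the
#' study period. Patients with no such claim are absent from the result.
#'
#' @param ds A `claims_dataset`.
#' @param config An [analysis_config()].
#' @return data.table with columns `patient_id`, `dx_date`.
#' @export
derive_dx_date <- function(ds, config = default_config()) {
  dx <- dx_long(ds$medical_claims)
  dx <- dx[has_prefix(code, config$lung_cancer_prefixes) &
             service_date >= config$study_start & service_date <= config$study_end]
  if (nrow(dx) == 0L) {
    return(data.table(patient_id = character(), dx_date = as.Date(character())))
  }
  dx[, .(dx_date = min(service_date)), by = patient_id]
}

#' Derive the secondary-malignancy date per patient
#'
#' Earliest claim date bearing a metastasis diagnosis code (default prefixes
#' C77-C79) on or after the patient's Dx date.
#'
#' @param ds A `claims_dataset`.
#' @param dx_dates Output of [derive_dx_date()].
#' @param config An [analysis_config()].
#' @return data.table with columns `patient_id`, `sm_date`.
#' @export
derive_sm_date <- function(ds, dx_dates, config = default_config()) {
  sm <- dx_long(ds$medical_claims)
  sm <- sm[has_prefix(code, config$metastasis_prefixes)]
  sm <- merge(sm, dx_dates, by = "patient_id")
  sm <- sm[service_date >= dx_date]
  if (nrow(sm) == 0L) {
    return(data.table(patient_id = character(), sm_date = as.Date(character())))
  }
  sm[, .(sm_date = min(service_date)), by = patient_id]
}

# long table of all SACT drug claims: patient, date, drug_code, class, canonical
sact_claims <- function(ds) {
  dict <- ds$drug_dictionary
  med <- ds$medical_claims[!is.na(drug_code) & drug_code != "",
                           .(patient_id, date = service_date, drug_code, source = "medical")]
  rx <- ds$pharmacy_claims[, .(patient_id, date = fill_date, drug_code,
                               source = "pharmacy", days_supply)]
  med[, days_supply := NA_integer_]
  all <- rbind(med, rx, fill = TRUE)
  all <- merge(all, dict[, .(drug_code, drug_class, canonical_id,
                             maintenance_eligible, default_runout_days)],
               by = "drug_code")
  all[is_sact(drug_class)]
}

#' Derive the index date (1L SACT start) per patient
#'
#' Earliest service or fill date of a systemic-anticancer-therapy claim on or
#' after the secondary-malignancy date.
#'
#' @param ds A `claims_dataset`.
#' @param sm_dates Output of [derive_sm_date()].
#' @param config An [analysis_config()].
#' @return data.table with columns `patient_id`, `index_date`.
#' @export
derive_index_date <- function(ds, sm_dates, config = default_config()) {
  sact <- sact_claims(ds)
  sact <- merge(sact, sm_dates, by = "patient_id")
  sact <- sact[date >= sm_date]
  if (nrow(sact) == 0L) {
    return(data.table(patient_id = character(), index_date = as.Date(character())))
  }
  sact[, .(index_date = min(date)), by = patient_id]
}

#' Check continuous enrollment around diagnosis and index
#'
#' TRUE when merged spans with medical benefit and merged spans with pharmacy
#' benefit each cover every day of `[dx_date - lookback, index_date + post]`
#' (both endpoints inclusive).
#'
#' @param ds A `claims_dataset`.
#' @param rows data.table with `patient_id`, `dx_date`, `index_date`.
#' @param config An [analysis_config()].
#' @return Logical vector aligned with `rows`.
#' @export
check_enrollment <- function(ds, rows, config = default_config()) {
  win <- data.table(patient_id = rows$patient_id,
                    win_start = rows$dx_date - config$pre_dx_lookback_days,
                    win_end = rows$index_date + config$post_index_enroll_days)
  covered_by <- function(benefit) {
    spans <- ds$enrollment[get(benefit) == TRUE,
                           .(patient_id, start_date, end_date)]
    spans <- merge_enrollment_spans(spans[, .(patient_id, start_date, end_date,
                                              medical = TRUE, pharmacy = TRUE)],
                                    gap_tolerance = config$enrollment_gap_tolerance_days)
    hit <- merge(win, spans, by = "patient_id", allow.cartesian = TRUE)
    ok <- hit[start_date <= win_start & end_date >= win_end, unique(patient_id)]
    win$patient_id %in% ok
  }
  covered_by("medical") & covered_by("pharmacy")
}

#' Apply the eligibility cascade and build the attrition table
#'
#' Applies the selection criteria in cascade order: lung-cancer diagnosis;
#' metastasis on/after diagnosis; SACT on/after metastasis; 1L start on/after
#' the index floor; continuous enrollment; no SCLC-typical agent before the
#' index date; no targeted-therapy claim during the study period (ICIs and
#' anti-VEGF agents never count as targeted); no metastasis diagnosis or SACT in
#' the 180 days before the Dx date; age >= 18 at index; and a 1L regimen
#' containing at least one NSCLC-appropriate agent. Each patient is labeled with
#' the first criterion failed.
#'
#' @param ds A `claims_dataset`.
#' @param config An [analysis_config()].
#' @return List with `cohort` (one row per patient holding key dates,
#'   `index_age`, `eligible`, `failed_filter`) and `attrition` (criterion label,
#'   patients remaining; counts are nonincreasing).
#' @export
build_cohort <- function(ds, config = default_config()) {
  pat <- ds$patients[, .(patient_id, birth_year)]
  dxd <- derive_dx_date(ds, config)
  rows <- merge(pat, dxd, by = "patient_id", all.x = TRUE)
  smd <- derive_sm_date(ds, dxd, config)
  rows <- merge(rows, smd, by = "patient_id", all.x = TRUE)
  idx <- if (nrow(smd)) derive_index_date(ds, smd, config) else
    data.table(patient_id = character(), index_date = as.Date(character()))
  rows <- merge(rows, idx, by = "patient_id", all.x = TRUE)
  rows[, index_age := as.integer(format(index_date, "%Y")) - birth_year]

  sact <- sact_claims(ds)
  n <- nrow(rows)
  pass <- list()
  pass$dx <- !is.na(rows$dx_date)
  pass$sm <- pass$dx & !is.na(rows$sm_date)
  pass$sact <- pass$sm & !is.na(rows$index_date)
  pass$index_2020 <- pass$sact & rows$index_date >= config$index_floor

  enr_ok <- rep(FALSE, n)
  cand <- which(pass$index_2020)
  if (length(cand)) enr_ok[cand] <- check_enrollment(ds, rows[cand], config)
  pass$enrollment <- pass$index_2020 & enr_ok

  # SCLC-typical agent strictly before the index date
  sclc <- merge(sact[drug_class == "SCLC_TYPICAL"],
                rows[, .(patient_id, index_date)], by = "patient_id")
  sclc_pat <- sclc[date < index_date, unique(patient_id)]
  pass$no_sclc <- pass$enrollment & !rows$patient_id %in% sclc_pat

  # targeted therapy any time in the study period (ICI/VEGF never trigger this)
  targ_pat <- sact[drug_class == "TARGETED" &
                     date >= config$study_start & date <= config$study_end,
                   unique(patient_id)]
  pass$no_targeted <- pass$no_sclc & !rows$patient_id %in% targ_pat

  # metastasis dx or SACT use within the 180 days before the Dx date
  met_any <- dx_long(ds$medical_claims)
  met_any <- met_any[has_prefix(code, config$metastasis_prefixes),
                     .(patient_id, date = service_date)]
  pre_events <- rbind(met_any, sact[, .(patient_id, date)])
  pre_events <- merge(pre_events, rows[, .(patient_id, dx_date)], by = "patient_id")
  pre_pat <- pre_events[date >= dx_date - config$pre_dx_lookback_days & date < dx_date,
                        unique(patient_id)]
  pass$no_prior_sm <- pass$no_targeted & !rows$patient_id %in% pre_pat

  pass$age_18 <- pass$no_prior_sm & !is.na(rows$index_age) & rows$index_age >= 18L

  # the 1L regimen window must contain at least one NSCLC-appropriate agent
  reg <- merge(sact, rows[, .(patient_id, index_date)], by = "patient_id")
  reg <- reg[date >= index_date & date <= index_date + (config$regimen_window_days - 1L)]
  nsclc_pat <- reg[drug_class %in% c("ICI", "PLATINUM", "NONPLAT_CHEMO", "VEGF", "TARGETED"),
                   unique(patient_id)]
  pass$nsclc_sact <- pass$age_18 & rows$patient_id %in% nsclc_pat

  keys <- names(ATTRITION_LABELS)
  stopifnot(identical(keys, names(pass)))
  attrition <- data.table(criterion = unname(ATTRITION_LABELS),
                          patients_remaining = vapply(pass, sum, integer(1)))

  failed <- rep(NA_character_, n)
  still_in <- rep(TRUE, n)
  for (k in keys) {
    newly_failed <- still_in & !pass[[k]]
    failed[newly_failed] <- k
    still_in <- still_in & pass[[k]]
  }
  rows[, eligible := still_in]
  rows[, failed_filter := failed]
  setorder(rows, patient_id)
  list(cohort = rows[], attrition = attrition)
}

#' Baseline characteristics over the 180-day lookback
#'
#' Comorbidity flags, metastasis sites and smoking history are derived only from
#' claims dated in `[index - 180, index - 1]` (the index date itself excluded);
#' the comorbidity score is the weighted sum of flagged conditions, the index
#' lung cancer excluded. Smoking is ascertained from nicotine-dependence codes
#' and is known to be under-captured in claims.
#'
#' @param ds A `claims_dataset`.
#' @param cohort Cohort table from [build_cohort()]; only eligible rows are
#'   profiled.
#' @param config An [analysis_config()].
#' @return data.table, one row per eligible patient: logical flags per
#'   condition/site, `smoking_history`, and `nci_cci`.
#' @export
baseline_profiles <- function(ds, cohort, config = default_config()) {
  elig <- cohort[eligible == TRUE, .(patient_id, index_date)]
  flags <- names(config$dx_prefix_map)
  out <- data.table(patient_id = elig$patient_id)
  if (nrow(elig) == 0L) {
    for (f in flags) out[, (f) := logical(0)]
    out[, smoking_history := logical(0)]
    out[, nci_cci := numeric(0)]
    return(out)
  }
  dx <- dx_long(ds$medical_claims)
  dx <- merge(dx, elig, by = "patient_id")
  dx <- dx[service_date >= index_date - config$pre_dx_lookback_days &
             service_date <= index_date - 1L]
  for (f in flags) {
    hit <- dx[has_prefix(code, config$dx_prefix_map[[f]]), unique(patient_id)]
    out[, (f) := patient_id %in% hit]
  }
  # metastasis "other": any secondary-malignancy code not among the named sites
  named <- unlist(config$dx_prefix_map[c("met_bone", "met_brain_spinal", "met_liver")])
  met <- dx[has_prefix(code, config$metastasis_prefixes)]
  other_pat <- met[!has_prefix(code, named), unique(patient_id)]
  out[, met_other := patient_id %in% other_pat]
  data.table::setnames(out, "smoking", "smoking_history")
  w <- config$charlson_weights
  score <- rep(0, nrow(out))
  for (cond in names(w)) {
    if (cond %in% names(out)) score <- score + w[[cond]] * as.numeric(out[[cond]])
  }
  out[, nci_cci := score]
  out[]
}
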