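# Pipeline orchestration: cohort -> LOT -> outcomes -> HCRU/costs, with
# table rendering shaped like the study's deliverables (attrition, baseline,
# category distribution, duration/TTNT, PPPM utilization and costs).

#' Run the full analysis pipeline
#'
#' Executes cohort selection, baseline profiling, line-of-therapy derivation,
#' outcome computation (durations, Kaplan-Meier, TTNT, SACT periods) and PPPM
#' HCRU/cost summarization on a claims dataset, collecting per-stage row counts
#' in a run manifest.
#'
#' @param ds A `claims_dataset` (read with [read_claims_dataset()] or generated
#'   with [simulate_claims()]).
#' @param config An [analysis_config()].
#' @return List of class `oncolot_result`: `cohort`, `attrition`, `baseline`,
#'   `lots`, `durations`, `km`, `km_by_category`, `ttnt`, `sact_periods`,
#'   `patient_hcru`, `hcru_summary`, `category_distribution`, `manifest`.
#' @export
run_pipeline <- function(ds, config = default_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  manifest <- list(n_patients_in = nrow(ds$patients),
                   config_reference_year = config$reference_year)

  ch <- stage("cohort", build_cohort(ds, config))
  manifest$n_eligible <- sum(ch$cohort$eligible)
  baseline <- stage("baseline", baseline_profiles(ds, ch$cohort, config))
  lots <- stage("lot", derive_lots(ds, ch$cohort, config))
  manifest$n_lot_segments <- nrow(lots)
  durations <- stage("outcomes", compute_durations(lots, ds, config))
  km <- if (nrow(durations)) km_fit(durations, config) else NULL
  km_by_category <- if (nrow(durations)) {
    cats <- sort(unique(durations$category))
    stats::setNames(lapply(cats, function(cc)
      km_fit(durations[category == cc], config)), cats)
  } else list()
  ttnt <- stage("outcomes", compute_ttnt(lots))
  periods <- stage("outcomes", compute_sact_periods(lots, config))
  ph <- stage("hcru", patient_hcru(ds, periods, config))
  hs <- stage("hcru", summarize_hcru(ph))

  l1 <- lots[lot_number == 1L]
  catdist <- if (nrow(l1)) {
    l1[, .(n = .N), by = category][, pct := 100 * n / sum(n)][order(-n)]
  } else data.table(category = character(), n = integer(), pct = numeric())

  manifest$n_durations <- nrow(durations)
  manifest$n_ttnt <- nrow(ttnt)
  out <- list(cohort = ch$cohort, attrition = ch$attrition, baseline = baseline,
              lots = lots, durations = durations, km = km,
              km_by_category = km_by_category, ttnt = ttnt,
              sact_periods = periods, patient_hcru = ph, hcru_summary = hs,
              category_distribution = catdist, manifest = manifest)
  class(out) <- "oncolot_result"
  out
}

#' @export
print.oncolot_result <- function(x, ...) {
  cat("<oncolot pipeline result>\n")
  cat(sprintf("  eligible cohort : %d of %d patients\n",
              x$manifest$n_eligible, x$manifest$n_patients_in))
  if (!is.null(x$km)) {
    cat(sprintf("  KM median 1L duration: %.2f months (n = %d)\n",
                x$km$median_months, x$km$n))
  }
  if (nrow(x$ttnt)) {
    cat(sprintf("  mean TTNT       : %.2f months (n = %d with 2L)\n",
                mean(x$ttnt$ttnt_days) / 30.4375, nrow(x$ttnt)))
  }
  invisible(x)
}

#' Render the result bundle as fixed-layout tables
#'
#' Produces the report tables with fixed column order and labels: the attrition
#' cascade, baseline characteristics (percentages to one decimal), 1L category
#' distribution, duration/TTNT by category, and the PPPM utilization/cost
#' summary.
#'
#' @param result An `oncolot_result` from [run_pipeline()].
#' @return Named list of data.tables.
#' @export
render_tables <- function(result) {
  att <- copy(result$attrition)

  bl <- result$baseline
  pct <- function(v) round(100 * mean(v), 1)
  baseline_rows <- c("hypertension", "copd", "coronary_heart_disease", "anemia",
                     "diabetes", "chronic_kidney_disease",
                     "chronic_liver_disease", "dementia",
                     "cerebrovascular_disease")
  base_tab <- if (nrow(bl)) {
    elig <- result$cohort[eligible == TRUE]
    data.table(
      characteristic = c("Age, years, mean (SD)", "Sex, male, %",
                         "Medicare Advantage, %",
                         paste0("Comorbidity: ", baseline_rows, ", %"),
                         "Metastasis: bone, %", "Metastasis: brain/spinal cord, %",
                         "Metastasis: liver, %", "Metastasis: other, %",
                         "History of smoking, %", "NCI-CCI, mean (SD)"),
      value = c(sprintf("%.1f (%.1f)", mean(elig$index_age), stats::sd(elig$index_age)),
                NA, NA,
                vapply(baseline_rows, function(f) sprintf("%.1f", pct(bl[[f]])), character(1)),
                sprintf("%.1f", pct(bl$met_bone)), sprintf("%.1f", pct(bl$met_brain_spinal)),
                sprintf("%.1f", pct(bl$met_liver)), sprintf("%.1f", pct(bl$met_other)),
                sprintf("%.1f", pct(bl$smoking_history)),
                sprintf("%.1f (%.1f)", mean(bl$nci_cci), stats::sd(bl$nci_cci)))
    )
  } else data.table(characteristic = character(), value = character())

  catdist <- copy(result$category_distribution)
  if (nrow(catdist)) catdist[, pct := round(pct, 1)]

  dur <- if (nrow(result$durations)) {
    rbindlist(c(list(data.table(
      category = "ALL",
      km_median_months = round(result$km$median_months, 2),
      n = result$km$n)),
      lapply(names(result$km_by_category), function(cc) data.table(
        category = cc,
        km_median_months = round(result$km_by_category[[cc]]$median_months, 2),
        n = result$km_by_category[[cc]]$n))))
  } else data.table(category = character(), km_median_months = numeric(), n = integer())

  list(attrition = att, baseline = base_tab, category_distribution = catdist,
       duration = dur, hcru = copy(result$hcru_summary))
}

#' Write the rendered tables as delimited text
#'
#' @param result An `oncolot_result`.
#' @param out_dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- render_tables(result)
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    data.table::fwrite(tabs[[nm]], p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Generator self-check against calibration targets
#'
#' Runs the full pipeline on a generated dataset and compares every calibrated
#' quantity with its target: category share, mean age, share male / Medicare
#' Advantage, KM median duration, mean TTNT, PPPM visit rates per setting, PPPM
#' mean costs, and the NSCLC-related share of outpatient visits. Standardized
#' deviations use the empirical standard error; |z| > 4 is flagged. The KM
#' median is compared on a +/- 0.25 month band (cycle-quantization tolerance)
#' instead of a z-score.
#'
#' @param ds Generated `claims_dataset`.
#' @param truth Ground-truth table from [simulate_claims()].
#' @param calib The calibration used to generate.
#' @param config An [analysis_config()].
#' @param result Optional precomputed [run_pipeline()] result for `ds`.
#' @return data.table: `quantity`, `target`, `value`, `se`, `z`, `flag`.
#' @export
self_check <- function(ds, truth, calib, config = default_config(),
                       result = NULL) {
  res <- result %||% run_pipeline(ds, config)
  mlen <- config$month_length_days
  rows <- list()
  add <- function(quantity, target, value, se) {
    z <- if (is.na(se) || se == 0) NA_real_ else (value - target) / se
    rows[[length(rows) + 1L]] <<- data.table(
      quantity = quantity, target = target, value = value, se = se, z = z,
      flag = !is.na(z) & abs(z) > 4)
  }
  elig <- res$cohort[eligible == TRUE]
  n <- nrow(elig)

  add("mean_age", calib$age_mean, mean(elig$index_age),
      stats::sd(elig$index_age) / sqrt(n))
  pats <- ds$patients[patient_id %in% elig$patient_id]
  pm <- mean(pats$sex == "M")
  add("share_male", calib$p_male, pm, sqrt(pm * (1 - pm) / n))
  pmed <- mean(pats$payer == "MedicareAdvantage")
  add("share_medicare", calib$p_medicare, pmed, sqrt(pmed * (1 - pmed) / n))

  l1 <- res$lots[lot_number == 1L]
  sh <- mean(l1$category == "ICI_PBCT")
  add("share_ici_pbct", calib$category_shares[["ICI_PBCT"]], sh,
      sqrt(sh * (1 - sh) / nrow(l1)))

  if (nrow(res$ttnt)) {
    tt <- res$ttnt$ttnt_days / mlen
    add("mean_ttnt_months", calib$ttnt_mean_months, mean(tt),
        stats::sd(tt) / sqrt(length(tt)))
  }

  ph <- res$patient_hcru
  pooled <- function(col) {
    v <- ph[[col]]
    c(mean(v), stats::sd(v) / sqrt(length(v)))
  }
  m <- pooled("pppm_visits_outpatient")
  add("pppm_outpatient_visits", calib$visit_rates_pppm[["outpatient"]], m[1], m[2])
  m <- pooled("pppm_admissions")
  add("pppm_inpatient_admissions", calib$visit_rates_pppm[["inpatient"]], m[1], m[2])
  m <- pooled("pppm_visits_ed")
  add("pppm_ed_visits", calib$visit_rates_pppm[["ed"]], m[1], m[2])
  m <- pooled("pppm_cost_total")
  add("pppm_cost_total", calib$cost_mean_pppm[["total"]], m[1], m[2])
  m <- pooled("pppm_cost_outpatient")
  add("pppm_cost_outpatient", calib$cost_mean_pppm[["outpatient"]], m[1], m[2])
  m <- pooled("pppm_cost_inpatient")
  add("pppm_cost_inpatient", calib$cost_mean_pppm[["inpatient"]], m[1], m[2])

  vfrac <- sum(ph$visits_outpatient_nsclc) / max(1, sum(ph$visits_outpatient))
  add("nsclc_outpatient_visit_frac", calib$nsclc_related_outpatient_frac, vfrac,
      sqrt(vfrac * (1 - vfrac) / max(1, sum(ph$visits_outpatient))))

  out <- rbindlist(rows)
  if (!is.null(res$km)) {
    med_row <- data.table(quantity = "km_median_duration_months",
                          target = calib$duration_median_months,
                          value = res$km$median_months, se = NA_real_,
                          z = NA_real_,
                          flag = abs(res$km$median_months -
                                       calib$duration_median_months) > 0.25)
    out <- rbind(out, med_row)
  }
  out[]
}
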