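# Run configuration: study window, algorithm constants, CPI table, code maps.

#' Default medical-care CPI index table
#'
#' Annual average of the medical-care component of the US Consumer Price Index
#' (index values, 1982-84 = 100), used to express paid amounts in reference-year
#' dollars. Values are the published annual averages rounded to one decimal.
#'
#' @return Named numeric vector, names are calendar years.
#' @export
default_cpi_table <- function() {
  c(`2016` = 463.7, `2017` = 471.5, `2018` = 480.5, `2019` = 494.3,
    `2020` = 518.9, `2021` = 521.5, `2022` = 546.6, `2023` = 566.3)
}

#' Default comorbidity and metastasis-site ICD-10-CM prefix map
#'
#' Prefix sets used for the 180-day baseline lookback. A claim flags a condition
#' when any of its diagnosis codes starts with one of the listed prefixes
#' (dots ignored). The map is plain data and can be swapped wholesale.
#'
#' @return Named list of character vectors of ICD-10-CM prefixes.
#' @export
default_dx_prefix_map <- function() {
  list(
    hypertension            = c("I10", "I11", "I12", "I13", "I15", "I16"),
    copd                    = c("J44"),
    coronary_heart_disease  = c("I25"),
    anemia                  = c("D50", "D51", "D52", "D53", "D63", "D64"),
    diabetes                = c("E08", "E09", "E10", "E11", "E13"),
    chronic_kidney_disease  = c("N18"),
    chronic_liver_disease   = c("K70", "K71", "K72", "K73", "K74", "K75", "K76"),
    dementia                = c("F01", "F02", "F03", "G30"),
    cerebrovascular_disease = c("I60", "I61", "I62", "I63", "I65", "I66", "I67", "I69"),
    smoking                 = c("F17"),
    met_bone                = c("C795"),
    met_brain_spinal        = c("C793", "C794"),
    met_liver               = c("C787")
  )
}

#' Default comorbidity weights for the adapted Charlson score
#'
#' Weighted-sum comorbidity score over the baseline flags; the index lung cancer
#' itself contributes nothing. The table is editable configuration, not code:
#' any named numeric vector over baseline flag names is accepted.
#'
#' @return Named numeric vector of weights.
#' @export
default_charlson_weights <- function() {
  c(copd = 1, diabetes = 1, chronic_kidney_disease = 2,
    chronic_liver_disease = 1, dementia = 1, cerebrovascular_disease = 1,
    coronary_heart_disease = 1)
}

#' Default maintenance-absorption map
#'
#' Guideline-recommended continuation therapies that extend a line of therapy
#' without advancing it: the named drug (canonical id) is absorbed when the
#' current regimen contains the listed backbone canonical id.
#'
#' @return Named list: canonical id -> character vector of backbone canonical ids.
#' @export
default_maintenance_map <- function() {
  list(
    pemetrexed  = "platinum_agent",
    bevacizumab = "platinum_agent"
  )
}

#' Build an analysis configuration
#'
#' Bundles every tunable constant of the pipeline: study window, eligibility
#' windows, line-of-therapy algorithm constants, the month length used for
#' per-patient-per-month rates, the CPI table and reference year, diagnosis-code
#' prefix maps, and comorbidity weights.
#'
#' @param study_start,study_end Study period bounds (default 2016-01-01 to
#'   2023-03-31).
#' @param index_floor Earliest admissible 1L start date (default 2020-01-01).
#' @param pre_dx_lookback_days Continuous-enrollment requirement before the
#'   lung-cancer diagnosis date, and the baseline lookback length (180).
#' @param post_index_enroll_days Continuous-enrollment requirement after the
#'   index date (30).
#' @param regimen_window_days Window after a line start whose systemic
#'   anticancer therapies define the regimen (30; days 0..29 inclusive).
#' @param gap_days Treatment gap that advances the line of therapy (60; a gap of
#'   at least this many days from the latest runout triggers advancement).
#' @param sact_period_tail_days Days added after the 1L maximum runout when
#'   closing the costing window (30).
#' @param month_length_days Days per month for PPPM conversion (30.4375).
#' @param enrollment_gap_tolerance_days Gap between enrollment spans still
#'   treated as continuous (0 = strict).
#' @param cpi_table Named numeric vector, year -> medical CPI index value.
#' @param reference_year Year costs are adjusted to (2022).
#' @param metastasis_prefixes ICD-10-CM prefixes identifying secondary
#'   malignancy (default C77-C79).
#' @param lung_cancer_prefixes ICD-10-CM prefixes identifying lung cancer
#'   (default C34).
#' @param dx_prefix_map Baseline comorbidity prefix map
#'   (see [default_dx_prefix_map()]).
#' @param charlson_weights Named weights for the comorbidity score.
#' @param maintenance_map Maintenance absorption map
#'   (see [default_maintenance_map()]).
#' @param rng_seed Integer seed recorded with the configuration.
#' @return An object of class `oncolot_config` (a validated named list).
#' @export
analysis_config <- function(study_start = as.Date("2016-01-01"),
                            study_end = as.Date("2023-03-31"),
                            index_floor = as.Date("2020-01-01"),
                            pre_dx_lookback_days = 180L,
                            post_index_enroll_days = 30L,
                            regimen_window_days = 30L,
                            gap_days = 60L,
                            sact_period_tail_days = 30L,
                            month_length_days = 30.4375,
                            enrollment_gap_tolerance_days = 0L,
                            cpi_table = default_cpi_table(),
                            reference_year = 2022L,
                            metastasis_prefixes = c("C77", "C78", "C79"),
                            lung_cancer_prefixes = "C34",
                            dx_prefix_map = default_dx_prefix_map(),
                            charlson_weights = default_charlson_weights(),
                            maintenance_map = default_maintenance_map(),
                            rng_seed = 1L) {
  cfg <- list(
    study_start = as_date_safe(study_start),
    study_end = as_date_safe(study_end),
    index_floor = as_date_safe(index_floor),
    pre_dx_lookback_days = as.integer(pre_dx_lookback_days),
    post_index_enroll_days = as.integer(post_index_enroll_days),
    regimen_window_days = as.integer(regimen_window_days),
    gap_days = as.integer(gap_days),
    sact_period_tail_days = as.integer(sact_period_tail_days),
    month_length_days = as.numeric(month_length_days),
    enrollment_gap_tolerance_days = as.integer(enrollment_gap_tolerance_days),
    cpi_table = cpi_table,
    reference_year = as.integer(reference_year),
    metastasis_prefixes = metastasis_prefixes,
    lung_cancer_prefixes = lung_cancer_prefixes,
    dx_prefix_map = dx_prefix_map,
    charlson_weights = charlson_weights,
    maintenance_map = maintenance_map,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "oncolot_config"
  validate_config(cfg)
  cfg
}

#' @rdname analysis_config
#' @export
default_config <- function() analysis_config()

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "oncolot_config"))
  win <- c("pre_dx_lookback_days", "post_index_enroll_days",
           "regimen_window_days", "gap_days", "sact_period_tail_days")
  for (w in win) {
    if (is.na(cfg[[w]]) || cfg[[w]] <= 0L) stopf("config field '%s' must be > 0", w)
  }
  if (cfg$month_length_days <= 0) stopf("month_length_days must be > 0")
  if (cfg$study_start > cfg$study_end) stopf("study_start must be <= study_end")
  if (!as.character(cfg$reference_year) %in% names(cfg$cpi_table)) {
    stopf("cpi_table must contain the reference year %d", cfg$reference_year)
  }
  invisible(cfg)
}

#' Read an analysis configuration from a YAML file
#'
#' Scalar fields override the defaults of [analysis_config()]; `cpi_table`,
#' `charlson_weights` and `maintenance_map` replace the default maps wholesale
#' when present.
#'
#' @param path Path to a YAML file.
#' @return An `oncolot_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("study_start", "study_end", "index_floor")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- as_date_safe(raw[[nm]])
  }
  for (nm in c("pre_dx_lookback_days", "post_index_enroll_days",
               "regimen_window_days", "gap_days", "sact_period_tail_days",
               "enrollment_gap_tolerance_days", "reference_year", "rng_seed")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- as.integer(raw[[nm]])
  }
  if (!is.null(raw$month_length_days)) args$month_length_days <- as.numeric(raw$month_length_days)
  if (!is.null(raw$cpi_table)) args$cpi_table <- unlist(raw$cpi_table)
  if (!is.null(raw$charlson_weights)) args$charlson_weights <- unlist(raw$charlson_weights)
  if (!is.null(raw$maintenance_map)) args$maintenance_map <- raw$maintenance_map
  if (!is.null(raw$metastasis_prefixes)) args$metastasis_prefixes <- as.character(raw$metastasis_prefixes)
  do.call(analysis_config, args)
}

#' @export
print.oncolot_config <- function(x, ...) {
  cat("<oncolot analysis config>\n")
  cat(sprintf("  study period : %s .. %s (index floor %s)\n",
              x$study_start, x$study_end, x$index_floor))
  cat(sprintf("  windows      : lookback %dd, post-index %dd, regimen %dd, gap %dd, tail %dd\n",
              x$pre_dx_lookback_days, x$post_index_enroll_days,
              x$regimen_window_days, x$gap_days, x$sact_period_tail_days))
  cat(sprintf("  month length : %.4f days; costs in %d USD (CPI years %s..%s)\n",
              x$month_length_days, x$reference_year,
              min(names(x$cpi_table)), max(names(x$cpi_table))))
  invisible(x)
}
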