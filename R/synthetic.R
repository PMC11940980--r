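# Synthetic claims generator. Emits a complete claims dataset plus per-patient
# ground truth, calibrated so that the full pipeline (cohort -> LOT -> outcomes
# -> HCRU/costs) reproduces the published summary statistics of the 1L
# metastatic-NSCLC population it emulates. Eligible patients receive
# rule-consistent event streams (the LOT engine recovers their true line starts
# exactly); ineligible patients are injected so each violates exactly one
# selection criterion.

INELIGIBLE_FILTERS <- c("NO_METASTASIS", "NO_SACT_AFTER_SM", "INDEX_BEFORE_2020",
                        "ENROLLMENT_GAP", "SCLC_PRIOR", "TARGETED_ANYTIME",
                        "PRIOR_SM_OR_SACT_PREDX", "AGE_LT_18")

# map of injected filter label -> attrition cascade key it must trip
FILTER_TO_CASCADE <- c(NO_METASTASIS = "sm", NO_SACT_AFTER_SM = "sact",
                       INDEX_BEFORE_2020 = "index_2020", ENROLLMENT_GAP = "enrollment",
                       SCLC_PRIOR = "no_sclc", TARGETED_ANYTIME = "no_targeted",
                       PRIOR_SM_OR_SACT_PREDX = "no_prior_sm", AGE_LT_18 = "age_18")

# 1L regimen variants per category: drug codes (see bundled dictionary) and
# sampling weight. All drugs of a variant are given every cycle.
REGIMEN_VARIANTS <- list(
  ICI_PBCT = list(
    list(w = 0.60, codes = c("J9271", "J9045", "J9305")),
    list(w = 0.15, codes = c("J9271", "J9060", "J9305")),
    list(w = 0.15, codes = c("J9299", "J9045", "J9267")),
    list(w = 0.10, codes = c("J9022", "J9045", "J9264"))),
  PBCT_MONO_COMBO = list(
    list(w = 0.40, codes = c("J9045", "J9305")),
    list(w = 0.30, codes = "J9045"),
    list(w = 0.30, codes = c("J9060", "J9201"))),
  ICI_MONO_DUAL = list(
    list(w = 0.90, codes = "J9271"),
    list(w = 0.10, codes = c("J9299", "J9228"))),
  ICI_NONPBCT = list(
    list(w = 0.60, codes = c("J9022", "J9264")),
    list(w = 0.40, codes = c("J9271", "J9305"))),
  NONPBCT_MONO = list(
    list(w = 0.50, codes = "J9171"),
    list(w = 0.50, codes = "J9201")),
  NONPBCT_COMBO = list(
    list(w = 1.00, codes = c("J9201", "J9390"))),
  OTHER = list(
    list(w = 1.00, codes = "J9035"))
)

# second-line candidates, in preference order; the first whose canonical id is
# not in the 1L regimen is used (none is maintenance-eligible)
SECOND_LINE_CANDIDATES <- c("J9171", "J9201", "J9390")

#' Solve per-category rates against a pooled target
#'
#' Given category shares, a pooled mean target, per-category values fixed in
#' advance, and a relative profile for the remaining categories, scales the
#' profile so the share-weighted mean equals the pooled target exactly.
#'
#' @param shares Named category shares summing to 1.
#' @param pooled Pooled target (share-weighted mean of the result).
#' @param fixed Named numeric of categories with known values.
#' @param profile Named numeric relative profile for the remaining categories
#'   (defaults to flat).
#' @return Named numeric vector over all categories.
#' @export
calibrate_rates <- function(shares, pooled, fixed = numeric(0), profile = NULL) {
  free <- setdiff(names(shares), names(fixed))
  if (is.null(profile)) profile <- stats::setNames(rep(1, length(free)), free)
  resid <- pooled - sum(shares[names(fixed)] * fixed)
  denom <- sum(shares[free] * profile[free])
  if (length(free) == 0L) return(fixed[names(shares)])
  if (denom <= 0) {
    # all free categories carry zero share: the pooled constraint cannot bind
    # them; keep the profile values and warn if the target is unattainable
    if (abs(resid) > 1e-6) {
      warnf("calibrate_rates: pooled target unattainable under degenerate shares (residual %.3g)",
            resid)
    }
    return(c(fixed, profile[free])[names(shares)])
  }
  k <- resid / denom
  out <- c(fixed, profile[free] * k)[names(shares)]
  if (any(out < 0)) stopf("calibrate_rates: fixed values exceed the pooled target")
  out
}

#' Default calibration for the synthetic-claims generator
#'
#' Defaults encode the study conditions the generator emulates: the seven
#' 1L-regimen category shares, treatment-duration medians (overall 4.2 months,
#' category spread 2.7-6.5), mean time to next treatment 8.0 months among
#' 2L patients, per-patient-per-month visit rates (outpatient 6.6, inpatient
#' 0.12, ED 0.11) and costs (total $32,215, outpatient $28,045, inpatient
#' $3,412, in 2022 USD), demographic targets (mean age 71.7, SD 8.6; 51.8%
#' male; 85.5% Medicare Advantage), the NSCLC-related share of outpatient
#' visits (74%), and injected ineligible fractions for each selection filter.
#' Category values not published are apportioned so share-weighted means hit
#' the pooled targets exactly.
#'
#' @param n_patients Number of eligible patients to generate (ineligible
#'   patients are injected on top per `ineligible_fractions`).
#' @param seed Integer seed; every stochastic draw passes through one seeded
#'   generator.
#' @param category_shares Named shares over the seven categories (sum to 1).
#' @param duration_median_months Overall target KM median of 1L duration.
#' @param duration_category_medians Named per-category duration medians
#'   (months).
#' @param duration_log_sd Log-scale SD of the intended-duration distribution.
#' @param p_second_line Probability a (non-truncated) patient starts 2L.
#' @param ttnt_mean_months Target mean time-to-next-treatment (months).
#' @param censor_fraction Fraction of patients whose enrollment is truncated
#'   before the intended 1L end (Kaplan-Meier censored).
#' @param visit_rates_pppm Pooled visit-rate targets
#'   (`outpatient`, `inpatient`, `ed`).
#' @param cost_mean_pppm Pooled cost targets in reference-year USD
#'   (`total`, `outpatient`, `inpatient`, `ed`, `pharmacy`; total must equal the
#'   sum of the others).
#' @param cost_log_sd Log-scale SD of cost draws (mean-targeting
#'   parameterization, so mean is exact and SD exceeds the mean, as observed).
#' @param nsclc_related_outpatient_frac Target share of outpatient visits that
#'   are NSCLC-related.
#' @param age_mean,age_sd,p_male,p_medicare Demographic targets.
#' @param region_shares Census-region shares.
#' @param ineligible_fractions Named fractions (of `n_patients`) of injected
#'   ineligible patients per filter; see `INELIGIBLE_FILTERS`.
#' @param cycle_length_days Treatment cycle length (days between SACT
#'   administrations and the imputed infusion runout).
#' @param followup_mean_months,followup_sd_months Follow-up length targets.
#' @param dx_to_index_median_months Median time from lung-cancer diagnosis to
#'   1L start.
#' @param pharmacy_fill_rate_pppm Background pharmacy fill rate.
#' @param p_death Probability of a recorded death after treatment end.
#' @return Object of class `oncolot_calibration`.
#' @export
default_calibration <- function(n_patients = 15659L,
                                seed = 42L,
                                category_shares = c(
                                  ICI_PBCT = 0.470, PBCT_MONO_COMBO = 0.264,
                                  ICI_MONO_DUAL = 0.197, ICI_NONPBCT = 0.016,
                                  NONPBCT_MONO = 0.030, NONPBCT_COMBO = 0.008,
                                  OTHER = 0.015),
                                duration_median_months = 4.2,
                                duration_category_medians = c(
                                  ICI_PBCT = 4.6, PBCT_MONO_COMBO = 2.7,
                                  ICI_MONO_DUAL = 6.5, ICI_NONPBCT = 5.5,
                                  NONPBCT_MONO = 3.2, NONPBCT_COMBO = 2.7,
                                  OTHER = 4.0),
                                duration_log_sd = 0.6,
                                p_second_line = 0.40,
                                ttnt_mean_months = 8.0,
                                censor_fraction = 0.25,
                                visit_rates_pppm = c(outpatient = 6.6,
                                                     inpatient = 0.12, ed = 0.11),
                                cost_mean_pppm = c(total = 32215, outpatient = 28045,
                                                   inpatient = 3412, ed = 300,
                                                   pharmacy = 458),
                                cost_log_sd = 1.0,
                                nsclc_related_outpatient_frac = 0.74,
                                age_mean = 71.7, age_sd = 8.6,
                                p_male = 0.518, p_medicare = 0.855,
                                region_shares = c(Northeast = 0.141, Midwest = 0.261,
                                                  South = 0.434, West = 0.164),
                                ineligible_fractions = c(
                                  NO_METASTASIS = 0.030, NO_SACT_AFTER_SM = 0.020,
                                  INDEX_BEFORE_2020 = 0.020, ENROLLMENT_GAP = 0.015,
                                  SCLC_PRIOR = 0.010, TARGETED_ANYTIME = 0.008,
                                  PRIOR_SM_OR_SACT_PREDX = 0.005, AGE_LT_18 = 0.002),
                                cycle_length_days = 21L,
                                followup_mean_months = 11.2,
                                followup_sd_months = 9.2,
                                dx_to_index_median_months = 1.5,
                                pharmacy_fill_rate_pppm = 1.0,
                                p_death = 0.15) {
  shares <- category_shares / sum(category_shares)
  # category visit rates: published values fixed, the rest solved so the
  # share-weighted mean equals the pooled target exactly
  outpatient_rates <- calibrate_rates(
    shares, visit_rates_pppm[["outpatient"]],
    fixed = c(PBCT_MONO_COMBO = 10.5, NONPBCT_MONO = 6.6, ICI_MONO_DUAL = 1.6,
              ICI_NONPBCT = 6.0, NONPBCT_COMBO = 10.0, OTHER = 5.0))
  inpatient_rates <- calibrate_rates(
    shares, visit_rates_pppm[["inpatient"]],
    fixed = c(PBCT_MONO_COMBO = 0.16, NONPBCT_MONO = 0.16, NONPBCT_COMBO = 0.19,
              ICI_NONPBCT = 0.16, ICI_MONO_DUAL = 0.08, OTHER = 0.12))
  ed_rates <- calibrate_rates(
    shares, visit_rates_pppm[["ed"]],
    fixed = c(PBCT_MONO_COMBO = 0.16, NONPBCT_MONO = 0.14, NONPBCT_COMBO = 0.16,
              ICI_NONPBCT = 0.12, ICI_MONO_DUAL = 0.07, OTHER = 0.10))
  cost_out_rates <- calibrate_rates(
    shares, cost_mean_pppm[["outpatient"]],
    fixed = c(ICI_PBCT = 30888, ICI_NONPBCT = 32913),
    profile = c(PBCT_MONO_COMBO = 1.0, ICI_MONO_DUAL = 1.15, NONPBCT_MONO = 0.65,
                NONPBCT_COMBO = 0.75, OTHER = 0.85))
  cost_inp_rates <- calibrate_rates(
    shares, cost_mean_pppm[["inpatient"]],
    fixed = c(PBCT_MONO_COMBO = 4725, ICI_NONPBCT = 4648),
    profile = c(ICI_PBCT = 1.0, ICI_MONO_DUAL = 0.8, NONPBCT_MONO = 1.3,
                NONPBCT_COMBO = 1.5, OTHER = 1.0))
  cost_ed_rates <- calibrate_rates(shares, cost_mean_pppm[["ed"]])
  cost_rx_rates <- calibrate_rates(shares, cost_mean_pppm[["pharmacy"]])

  calib <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    category_shares = shares,
    duration_median_months = duration_median_months,
    duration_category_medians = duration_category_medians,
    duration_log_sd = duration_log_sd,
    p_second_line = p_second_line, ttnt_mean_months = ttnt_mean_months,
    censor_fraction = censor_fraction,
    visit_rates_pppm = visit_rates_pppm,
    outpatient_rates = outpatient_rates, inpatient_rates = inpatient_rates,
    ed_rates = ed_rates,
    cost_mean_pppm = cost_mean_pppm,
    cost_out_rates = cost_out_rates, cost_inp_rates = cost_inp_rates,
    cost_ed_rates = cost_ed_rates, cost_rx_rates = cost_rx_rates,
    cost_log_sd = cost_log_sd,
    nsclc_related_outpatient_frac = nsclc_related_outpatient_frac,
    nsclc_outpatient_cost_frac = 23388 / 28045,
    nsclc_inpatient_frac = 2709 / 3412,
    age_mean = age_mean, age_sd = age_sd, p_male = p_male,
    p_medicare = p_medicare,
    region_shares = region_shares / sum(region_shares),
    ineligible_fractions = ineligible_fractions,
    cycle_length_days = as.integer(cycle_length_days),
    followup_mean_months = followup_mean_months,
    followup_sd_months = followup_sd_months,
    dx_to_index_median_months = dx_to_index_median_months,
    pharmacy_fill_rate_pppm = pharmacy_fill_rate_pppm,
    p_death = p_death
  )
  class(calib) <- "oncolot_calibration"
  validate_calibration(calib)
  calib
}

validate_calibration <- function(calib) {
  if (abs(sum(calib$category_shares) - 1) > 1e-9) {
    stopf("category_shares must sum to 1")
  }
  rates <- c(calib$visit_rates_pppm, calib$cost_mean_pppm,
             calib$outpatient_rates, calib$inpatient_rates, calib$ed_rates,
             calib$cost_out_rates, calib$cost_inp_rates)
  if (any(rates < 0)) stopf("calibration rates and costs must be >= 0")
  probs <- c(calib$p_second_line, calib$censor_fraction, calib$p_male,
             calib$p_medicare, calib$p_death, calib$ineligible_fractions)
  if (any(probs < 0 | probs > 1)) stopf("calibration probabilities must lie in [0, 1]")
  for (nm in c("outpatient_rates", "inpatient_rates", "ed_rates")) {
    pooled <- switch(nm, outpatient_rates = "outpatient",
                     inpatient_rates = "inpatient", ed_rates = "ed")
    dev <- abs(sum(calib$category_shares * calib[[nm]][names(calib$category_shares)]) -
                 calib$visit_rates_pppm[[pooled]])
    if (dev > 1e-9) stopf("share-weighted %s must equal the pooled target", nm)
  }
  tot <- calib$cost_mean_pppm
  if (abs(tot[["total"]] - sum(tot[c("outpatient", "inpatient", "ed", "pharmacy")])) > 1e-6) {
    stopf("cost_mean_pppm total must equal the sum of its settings")
  }
  invisible(calib)
}

#' @export
print.oncolot_calibration <- function(x, ...) {
  cat(sprintf("<oncolot calibration> n = %d eligible (+%.1f%% ineligible), seed %d\n",
              x$n_patients, 100 * sum(x$ineligible_fractions), x$seed))
  cat(sprintf("  duration median %.1f mo | TTNT %.1f mo | censor %.0f%% | 2L %.0f%%\n",
              x$duration_median_months, x$ttnt_mean_months,
              100 * x$censor_fraction, 100 * x$p_second_line))
  invisible(x)
}

# deterministic calibration internals solved from the configuration:
# - intended-duration medians scaled so the cycle-quantized KM median lands on
#   the 21-day grid point nearest the target (durations are emitted as whole
#   cycles, so the achievable medians live on that grid)
# - the enrollment-truncation (censoring) time scale solved so
#   P(truncation < intended duration) equals the censor fraction
generator_internals <- function(calib, config) {
  shares <- calib$category_shares
  med_days <- calib$duration_category_medians[names(shares)] * config$month_length_days
  sdlog <- calib$duration_log_sd
  cyc <- calib$cycle_length_days
  grid_target <- max(cyc, round(calib$duration_median_months *
                                  config$month_length_days / cyc) * cyc)
  f <- function(s) {
    sum(shares * stats::plnorm(grid_target, meanlog = log(s * med_days),
                               sdlog = sdlog)) - 0.55
  }
  s <- stats::uniroot(f, c(0.2, 5), tol = 1e-10)$root
  dur_med_days <- s * med_days

  # censoring-time scale: single log-normal C, same sdlog, independent of the
  # duration draw; P(C < D) = censor_fraction over the category mixture
  g <- function(mc) {
    sum(shares * stats::pnorm((log(dur_med_days) - log(mc)) / (sdlog * sqrt(2)))) -
      calib$censor_fraction
  }
  cens_med <- stats::uniroot(g, c(1, 1e5), tol = 1e-8)$root

  fm <- calib$followup_mean_months * config$month_length_days
  fs <- calib$followup_sd_months * config$month_length_days
  fu_sdlog <- sqrt(log(1 + (fs / fm)^2))
  fu_meanlog <- log(fm) - fu_sdlog^2 / 2

  dxi_med <- calib$dx_to_index_median_months * config$month_length_days
  dxi_sdlog <- log(2.8 / 0.9) / (2 * stats::qnorm(0.75))

  list(dur_med_days = dur_med_days, cens_med = cens_med,
       grid_target = grid_target,
       fu_meanlog = fu_meanlog, fu_sdlog = fu_sdlog,
       dxi_med = dxi_med, dxi_sdlog = dxi_sdlog)
}

# truncated-exponential mean: E[X | X <= Tmax] for rate 1/mu
trunc_exp_mean <- function(mu, tmax) {
  p <- 1 - exp(-tmax / mu)
  ifelse(p <= 0, tmax / 2, mu - tmax * exp(-tmax / mu) / p)
}

# Solve the 2L-delay mean so the mean TTNT among *observed* 2L patients hits
# the target, accounting for truncation of the delay at each patient's
# remaining study time.
solve_delay_mean <- function(derived_days, budget_days, target_days) {
  ok <- budget_days >= 2
  if (!any(ok)) return(7)
  d <- derived_days[ok]; tmax <- budget_days[ok]
  f <- function(mu) {
    w <- 1 - exp(-tmax / mu)
    sum(w * (d + trunc_exp_mean(mu, tmax))) / sum(w) - target_days
  }
  if (f(7) >= 0) return(7)  # even the floor overshoots; spec floors at 7 days
  hi <- 5000
  if (f(hi) < 0) return(hi)
  stats::uniroot(f, c(7, hi), tol = 1e-6)$root
}

rlnorm_mean <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a calibrated synthetic claims dataset with ground truth
#'
#' Builds the full five-table dataset plus a per-patient ground-truth table.
#' Each eligible patient gets: a lung-cancer diagnosis claim, a metastasis
#' claim on/after it, baseline comorbidity claims in the 180-day lookback, SACT
#' claims every cycle from the 1L start until a sampled intended duration
#' (log-normal, medians calibrated per category), an optional second line
#' starting with a drug outside the 1L regimen, and visit/cost streams drawn to
#' match the per-patient-per-month calibration targets within the SACT period.
#' Ineligible patients are injected per `ineligible_fractions`, each violating
#' exactly one selection criterion.
#'
#' @param calib An [default_calibration()] object.
#' @param config An [analysis_config()].
#' @param seed Integer seed (defaults to `calib$seed`).
#' @return List with `dataset` (a `claims_dataset`) and `truth` (data.table:
#'   `patient_id`, `eligible`, `failed_filter`, `true_category`,
#'   `true_lot_starts` pipe-delimited, `true_1l_duration_days`,
#'   `true_censored`, `true_2l_start`).
#' @export
simulate_claims <- function(calib = default_calibration(),
                            config = default_config(), seed = calib$seed) {
  validate_calibration(calib)
  set.seed(seed)
  gi <- generator_internals(calib, config)
  cyc <- calib$cycle_length_days
  mlen <- config$month_length_days
  dict <- load_drug_dictionary()

  n_e <- calib$n_patients
  inel <- round(calib$ineligible_fractions * n_e)
  status <- c(rep("ELIGIBLE", n_e),
              rep(names(inel), inel))
  N <- length(status)
  if (N == 0L) return(empty_simulation(dict))

  pt <- data.table(patient_id = sprintf("P%07d", seq_len(N)), status = status)
  full_stream <- !pt$status %in% c("NO_METASTASIS", "NO_SACT_AFTER_SM")

  ## --- patient-level draws -------------------------------------------------
  cats <- names(calib$category_shares)
  pt[, category := sample(cats, N, replace = TRUE, prob = calib$category_shares)]

  idx_lo <- as.integer(config$index_floor)
  idx_hi <- as.integer(config$study_end)
  pt[, index_day := idx_lo + as.integer(floor(stats::runif(N) * (idx_hi - idx_lo + 1L)))]
  early <- pt$status == "INDEX_BEFORE_2020"
  if (any(early)) {
    e_lo <- as.integer(as.Date("2018-06-01")); e_hi <- as.integer(as.Date("2019-12-15"))
    pt[early, index_day := e_lo + as.integer(floor(stats::runif(sum(early)) * (e_hi - e_lo + 1L)))]
  }

  pt[, dx_delta := pmax(3L, pmin(1200L, as.integer(round(
    stats::rlnorm(N, log(gi$dxi_med), gi$dxi_sdlog)))))]
  pt[status == "SCLC_PRIOR", dx_delta := pmax(dx_delta, 40L)]
  # keep the Dx date inside the study period
  pt[, dx_delta := pmin(dx_delta, index_day - as.integer(config$study_start))]
  pt[, dx_day := index_day - dx_delta]
  pt[, sm_day := dx_day + pmin(dx_delta, pmax(0L, as.integer(round(
    stats::runif(N, 0.2, 0.9) * dx_delta))))]
  pt[status == "SCLC_PRIOR", sm_day := pmin(index_day, pmax(sm_day, dx_day + 10L))]

  pt[, age := pmax(19L, pmin(99L, as.integer(round(
    stats::rnorm(N, calib$age_mean, calib$age_sd)))))]
  u18 <- pt$status == "AGE_LT_18"
  if (any(u18)) pt[u18, age := sample(10:17, sum(u18), replace = TRUE)]
  pt[, birth_year := as.integer(format(as.Date(index_day, origin = "1970-01-01"), "%Y")) - age]
  pt[, sex := fifelse(stats::runif(N) < calib$p_male, "M", "F")]
  pt[, region := sample(names(calib$region_shares), N, TRUE, calib$region_shares)]
  pt[, payer := fifelse(stats::runif(N) < calib$p_medicare,
                        "MedicareAdvantage", "Commercial")]

  ## --- durations, censoring, follow-up -------------------------------------
  pt[, d_star := pmax(2, stats::rlnorm(N, log(gi$dur_med_days[category]),
                                       calib$duration_log_sd))]
  pt[, n_cycles := as.integer(ceiling(d_star / cyc))]
  pt[, c_trunc := stats::rlnorm(N, log(gi$cens_med), calib$duration_log_sd)]
  pt[, is_trunc := c_trunc < d_star]
  pt[, fu_trunc := pmax(as.integer(round(c_trunc)), 30L)]
  pt[, study_off := idx_hi - index_day]
  pt[, cyc_cap := pmin(fifelse(is_trunc, fu_trunc, .Machine$integer.max),
                       study_off)]
  pt[, cycles_emit := pmax(1L, pmin(n_cycles, as.integer(cyc_cap %/% cyc) + 1L))]
  pt[, runout_off := cyc * (cycles_emit - 1L) + (cyc - 1L)]
  pt[, derived_emit := runout_off + 1L]

  # enrollment end offset from index
  fu_draw <- as.integer(round(stats::rlnorm(N, gi$fu_meanlog, gi$fu_sdlog)))
  pt[, fu_off := fifelse(is_trunc, fu_trunc,
                         pmax(fu_draw, runout_off + 31L))]
  pt[, fu_off := pmax(fu_off, 30L)]

  ## --- second line ----------------------------------------------------------
  pt[, b2 := stats::runif(N) < calib$p_second_line]
  pt[, censored_pre := is_trunc & fu_trunc < runout_off]
  pt[, budget := study_off - derived_emit]
  cand <- pt$b2 & !pt$censored_pre & full_stream
  mu <- solve_delay_mean(pt$derived_emit[cand & pt$status == "ELIGIBLE"],
                         pt$budget[cand & pt$status == "ELIGIBLE"],
                         calib$ttnt_mean_months * mlen)
  pt[, delay := pmax(1L, as.integer(round(stats::rexp(N, 1 / mu))),
                     (config$regimen_window_days + 1L) - derived_emit)]
  pt[, has_2l := cand & delay <= budget]
  pt[, l2_off := fifelse(has_2l, derived_emit + delay, NA_integer_)]
  pt[has_2l == TRUE, fu_off := pmax(fu_off, l2_off + 45L)]

  ## --- death (recorded only after treatment end, so duration is unaffected) -
  death_cand <- !pt$censored_pre & !pt$has_2l & full_stream &
    stats::runif(N) < calib$p_death
  death_off <- pt$runout_off + 1L + as.integer(round(stats::rexp(N, 1 / 60)))
  death_off <- pmax(death_off, 31L)
  pt[, death_day := NA_integer_]
  take <- death_cand & death_off <= pt$fu_off
  pt[take, death_day := index_day + death_off[take]]
  pt[take, fu_off := death_off[take]]

  ## --- ground-truth duration via the same end-date arithmetic the paper uses
  pt[, nat_end := runout_off]
  pt[, adm_end := pmin(fu_off, study_off)]
  pt[, dur_end := pmin(nat_end, adm_end)]
  pt[, true_dur := dur_end + 1L]
  pt[, true_cens := adm_end < nat_end &
       !(!is.na(death_day) & (death_day - index_day) == adm_end)]

  ## --- SACT period and in-period utilization targets ------------------------
  far <- .Machine$integer.max %/% 2L
  pt[, period_end := pmin(runout_off + config$sact_period_tail_days,
                          fifelse(has_2l, l2_off - 1L, far),
                          fu_off, study_off)]
  pt[, period_days := period_end + 1L]
  pt[, months := period_days / mlen]

  ## --- regimen variants ------------------------------------------------------
  pt[, variant := vapply(category, function(cc) {
    v <- REGIMEN_VARIANTS[[cc]]
    sample.int(length(v), 1L, prob = vapply(v, `[[`, numeric(1), "w"))
  }, integer(1))]
  drug_sets <- lapply(seq_len(N), function(i) {
    if (!full_stream[i]) return(character(0))
    REGIMEN_VARIANTS[[pt$category[i]]][[pt$variant[i]]]$codes
  })
  pt[, n_drugs := lengths(drug_sets)]
  pt[, sact_n := fifelse(full_stream, cycles_emit * n_drugs, 0L)]

  origin <- as.Date("1970-01-01")
  pt[, index_date := as.Date(index_day, origin = origin)]
  pt[, dx_date := as.Date(dx_day, origin = origin)]
  pt[, sm_date := as.Date(sm_day, origin = origin)]

  ## --- assemble claims -------------------------------------------------------
  med <- list(); rx <- list()
  cpi <- config$cpi_table
  deflate <- function(amount2022, dates) {
    yr <- as.character(data.table::year(dates))
    round(amount2022 * unname(cpi[yr]) / cpi[[as.character(config$reference_year)]], 2)
  }
  mk_med <- function(patient_id, date, setting, dx_codes, drug_code, paid2022) {
    data.table(patient_id = patient_id, service_date = date, setting = setting,
               dx_codes = dx_codes, drug_code = drug_code,
               paid_amount = deflate(paid2022, date))
  }

  # diagnosis claim (every patient)
  med$dx <- mk_med(pt$patient_id, pt$dx_date, "OUTPATIENT", "C34.90",
                   NA_character_, rlnorm_mean(N, 200, 0.5))

  # metastasis claim (all but NO_METASTASIS), sites per prevalence
  has_sm <- pt$status != "NO_METASTASIS"
  site_codes <- {
    bone <- stats::runif(N) < 0.216
    brain <- stats::runif(N) < 0.141
    liver <- stats::runif(N) < 0.113
    other <- stats::runif(N) < 0.642
    none <- !(bone | brain | liver | other)
    vapply(seq_len(N), function(i) {
      cds <- c(if (bone[i]) "C79.51", if (brain[i]) "C79.31",
               if (liver[i]) "C78.7", if (other[i] || none[i]) "C79.89")
      paste(c(cds, "C34.90"), collapse = "|")
    }, character(1))
  }
  med$sm <- mk_med(pt$patient_id[has_sm], pt$sm_date[has_sm], "OUTPATIENT",
                   site_codes[has_sm], NA_character_,
                   rlnorm_mean(sum(has_sm), 300, 0.5))

  # pre-diagnosis metastasis claim for the PRIOR_SM_OR_SACT_PREDX filter
  psm <- pt$status == "PRIOR_SM_OR_SACT_PREDX"
  if (any(psm)) {
    med$prior_sm <- mk_med(pt$patient_id[psm], pt$dx_date[psm] - 90L, "OUTPATIENT",
                           "C79.9", NA_character_, rlnorm_mean(sum(psm), 300, 0.5))
  }

  # SCLC-typical agent strictly between Dx and SM dates
  sclc <- pt$status == "SCLC_PRIOR"
  if (any(sclc)) {
    off <- pt$dx_day[sclc] + 5L +
      floor(stats::runif(sum(sclc)) * pmax(1L, pt$sm_day[sclc] - pt$dx_day[sclc] - 5L))
    med$sclc <- mk_med(pt$patient_id[sclc], as.Date(pmin(off, pt$sm_day[sclc] - 1L),
                                                    origin = origin),
                       "OUTPATIENT", "C34.90", "J9351",
                       rlnorm_mean(sum(sclc), 3000, 0.5))
  }

  # targeted-therapy claim after the 1L start (never shifts the index date)
  targ <- pt$status == "TARGETED_ANYTIME"
  if (any(targ)) {
    tday <- pmin(pt$index_day[targ] + 40L, idx_hi, pt$index_day[targ] + pt$fu_off[targ])
    rx$targ <- data.table(patient_id = pt$patient_id[targ],
                          fill_date = as.Date(tday, origin = origin),
                          drug_code = "NDC-OSIM", days_supply = 30L,
                          paid_amount = deflate(rlnorm_mean(sum(targ), 15000, 0.3),
                                                as.Date(tday, origin = origin)))
  }

  # baseline comorbidity claims in [index-180, index-1]
  prev <- c(hypertension = 0.727, copd = 0.443, coronary_heart_disease = 0.292,
            anemia = 0.288, diabetes = 0.285, chronic_kidney_disease = 0.148,
            chronic_liver_disease = 0.125, dementia = 0.017,
            cerebrovascular_disease = 0.011, smoking = 0.798)
  base_code <- c(hypertension = "I10", copd = "J44.9",
                 coronary_heart_disease = "I25.10", anemia = "D64.9",
                 diabetes = "E11.9", chronic_kidney_disease = "N18.3",
                 chronic_liver_disease = "K74.60", dementia = "F03.90",
                 cerebrovascular_disease = "I63.9", smoking = "F17.210")
  has_index <- full_stream
  bl <- list()
  for (cond in names(prev)) {
    hit <- has_index & stats::runif(N) < prev[[cond]]
    if (!any(hit)) next
    offs <- 1L + floor(stats::runif(sum(hit)) * config$pre_dx_lookback_days)
    bl[[cond]] <- mk_med(pt$patient_id[hit],
                         as.Date(pt$index_day[hit] - offs, origin = origin),
                         "OUTPATIENT", base_code[[cond]], NA_character_,
                         rlnorm_mean(sum(hit), 120, 0.5))
  }
  med$baseline <- rbindlist(bl)

  # SACT cycle claims: every drug of the variant on every emitted cycle date
  fs_idx <- which(full_stream)
  sact_tab <- data.table(
    i = rep(fs_idx, pt$cycles_emit[fs_idx] * pt$n_drugs[fs_idx]),
    cycle = unlist(lapply(fs_idx, function(i)
      rep(seq_len(pt$cycles_emit[i]), each = pt$n_drugs[i]))),
    drug_code = unlist(lapply(fs_idx, function(i)
      rep(drug_sets[[i]], times = pt$cycles_emit[i])))
  )
  sact_tab[, date_day := pt$index_day[i] + (cycle - 1L) * cyc]
  # a fraction of carboplatin starters switch to cisplatin from cycle 3 on
  # (same substitution group; exercises substitution collapsing downstream)
  switch_pat <- fs_idx[stats::runif(length(fs_idx)) < 0.10]
  sact_tab[i %in% switch_pat & drug_code == "J9045" & cycle >= 3L,
           drug_code := "J9060"]
  sact_tab[, dx_codes := fifelse(stats::runif(.N) < 0.5, "C34.90", "")]
  med$sact <- data.table(patient_id = pt$patient_id[sact_tab$i],
                         service_date = as.Date(sact_tab$date_day, origin = origin),
                         setting = "OUTPATIENT", dx_codes = sact_tab$dx_codes,
                         drug_code = sact_tab$drug_code,
                         paid_amount = 0)  # cost allocated below

  # second-line cycle claims (outside the 1L SACT period)
  l2_idx <- which(pt$has_2l)
  if (length(l2_idx)) {
    canon <- stats::setNames(dict$canonical_id, dict$drug_code)
    cand_canon <- canon[SECOND_LINE_CANDIDATES]
    n2 <- sample(2:5, length(l2_idx), replace = TRUE)
    l2_rows <- lapply(seq_along(l2_idx), function(jj) {
      i <- l2_idx[jj]
      reg_canon <- canon[drug_sets[[i]]]
      code2 <- SECOND_LINE_CANDIDATES[!cand_canon %in% reg_canon][1L]
      days <- pt$index_day[i] + pt$l2_off[i] + (seq_len(n2[jj]) - 1L) * cyc
      days <- days[days <= pt$index_day[i] + pt$fu_off[i] & days <= idx_hi]
      data.table(i = i, date_day = days, drug_code = code2)
    })
    l2_tab <- rbindlist(l2_rows)
    med$l2 <- data.table(patient_id = pt$patient_id[l2_tab$i],
                         service_date = as.Date(l2_tab$date_day, origin = origin),
                         setting = "OUTPATIENT", dx_codes = "C34.90",
                         drug_code = l2_tab$drug_code,
                         paid_amount = deflate(rlnorm_mean(nrow(l2_tab), 5000, 0.5),
                                               as.Date(l2_tab$date_day, origin = origin)))
  }

  ## --- background utilization within the SACT period ------------------------
  fillers <- c("I10", "E11.9", "Z51.11", "R53.83", "J44.9")
  rnd_dates <- function(i_vec) {
    as.Date(pt$index_day[i_vec] +
              floor(stats::runif(length(i_vec)) * pt$period_days[i_vec]),
            origin = origin)
  }

  # Outpatient visits: background visits top the SACT administration claims up
  # to the category target rate. Patients whose SACT claims alone exceed the
  # target (multi-drug regimens over short periods) would clamp at zero and
  # bias the pooled mean upward, so the overshoot is redistributed within each
  # category across patients with slack, keeping the per-category mean rate on
  # target.
  out_rate <- calib$outpatient_rates[pt$category]
  s_rate <- fifelse(full_stream, pt$sact_n / pt$months, 0)
  slack <- pmax(0, out_rate - s_rate)
  over <- pmax(0, s_rate - out_rate)
  adj <- data.table(cat = pt$category, slack = slack, over = over,
                    full = full_stream)
  adj[, delta := {
    ts <- sum(slack[full]); to <- sum(over[full])
    if (ts > 0) slack * to / ts else 0
  }, by = cat]
  b_rate <- pmax(0, slack - adj$delta)
  b_n <- ifelse(full_stream, stats::rpois(N, b_rate * pt$months), 0L)
  bi <- rep(seq_len(N), b_n)
  if (length(bi)) {
    # NSCLC-related flags on background visits: one pooled probability solved so
    # the overall NSCLC-related share of outpatient visits hits the target
    # (SACT administration claims are NSCLC-related by their drug)
    tot_s <- sum(pt$sact_n[full_stream]); tot_b <- length(bi)
    p_nsclc <- min(1, max(0, (calib$nsclc_related_outpatient_frac * (tot_s + tot_b) -
                                tot_s) / tot_b))
    flagged <- stats::runif(length(bi)) < p_nsclc
    codes <- sample(fillers, length(bi), replace = TRUE)
    codes[flagged] <- paste0(codes[flagged], "|C34.90")
    med$bg_out <- data.table(patient_id = pt$patient_id[bi],
                             service_date = rnd_dates(bi), setting = "OUTPATIENT",
                             dx_codes = codes, drug_code = NA_character_,
                             paid_amount = 0)
  }

  # inpatient stays: spaced starts, 1-4 day lengths, cost on the first day
  inp_rate <- calib$inpatient_rates[pt$category]
  k_n <- ifelse(full_stream, stats::rpois(N, inp_rate * pt$months), 0L)
  k_n <- pmin(k_n, pt$period_days %/% 8L)
  inp_rows <- lapply(which(k_n > 0L), function(i) {
    k <- k_n[i]
    block <- pt$period_days[i] %/% k
    starts <- (seq_len(k) - 1L) * block +
      floor(stats::runif(k) * pmax(1L, block - 6L))
    len <- sample(1:4, k, replace = TRUE)
    stay <- rep(seq_len(k), len)
    day <- pt$index_day[i] + (starts[stay] + sequence(len))
    keep <- day <= pt$index_day[i] + pt$period_end[i]
    data.table(i = i, stay = stay[keep], day = day[keep],
               first = !duplicated(stay[keep]))
  })
  inp_tab <- rbindlist(inp_rows)
  if (nrow(inp_tab)) {
    stay_key <- unique(inp_tab[, .(i, stay)])
    stay_key[, cost := rlnorm_mean(.N, calib$cost_inp_rates[pt$category[i]] /
                                     calib$inpatient_rates[pt$category[i]],
                                   calib$cost_log_sd)]
    stay_key[, nsclc := stats::runif(.N) < calib$nsclc_inpatient_frac]
    inp_tab <- merge(inp_tab, stay_key, by = c("i", "stay"))
    dts <- as.Date(inp_tab$day, origin = origin)
    med$inp <- data.table(patient_id = pt$patient_id[inp_tab$i],
                          service_date = dts, setting = "INPATIENT",
                          dx_codes = fifelse(inp_tab$nsclc, "C34.90|J18.9", "J18.9"),
                          drug_code = NA_character_,
                          paid_amount = deflate(fifelse(inp_tab$first, inp_tab$cost, 0), dts))
  }

  # ED visits
  ed_rate <- calib$ed_rates[pt$category]
  e_n <- ifelse(full_stream, stats::rpois(N, ed_rate * pt$months), 0L)
  ei <- rep(seq_len(N), e_n)
  if (length(ei)) {
    dts <- rnd_dates(ei)
    nsclc <- stats::runif(length(ei)) < 0.5
    med$ed <- data.table(patient_id = pt$patient_id[ei], service_date = dts,
                         setting = "ED",
                         dx_codes = fifelse(nsclc, "C34.90|R07.9", "R07.9"),
                         drug_code = NA_character_,
                         paid_amount = deflate(
                           rlnorm_mean(length(ei),
                                       calib$cost_ed_rates[pt$category[ei]] /
                                         calib$ed_rates[pt$category[ei]],
                                       calib$cost_log_sd), dts))
  }

  # background pharmacy fills
  r_n <- ifelse(full_stream, stats::rpois(N, calib$pharmacy_fill_rate_pppm * pt$months), 0L)
  ri <- rep(seq_len(N), r_n)
  if (length(ri)) {
    dts <- rnd_dates(ri)
    rx$bg <- data.table(patient_id = pt$patient_id[ri], fill_date = dts,
                        drug_code = sample(c("RX-STAT", "RX-METF", "RX-LISI",
                                             "RX-OMEP", "RX-ONDA", "RX-DEXA"),
                                           length(ri), replace = TRUE),
                        days_supply = 30L,
                        paid_amount = deflate(
                          rlnorm_mean(length(ri),
                                      calib$cost_rx_rates[pt$category[ri]] /
                                        calib$pharmacy_fill_rate_pppm,
                                      calib$cost_log_sd), dts))
  }

  medical <- rbindlist(med, fill = TRUE)

  ## --- allocate outpatient cost: one per-patient mean-targeted total, split
  ##     NSCLC / non-NSCLC, divided over the patient's in-period outpatient rows
  out_total <- rlnorm_mean(N, calib$cost_out_rates[pt$category] * pt$months,
                           calib$cost_log_sd)
  medical[, row_id := .I]
  per <- data.table(patient_id = pt$patient_id, index_day = pt$index_day,
                    period_end = pt$period_end, total = out_total,
                    full = full_stream)
  op <- merge(medical[setting == "OUTPATIENT",
                      .(row_id, patient_id, service_date, dx_codes, drug_code)],
              per, by = "patient_id")
  op <- op[full & as.integer(service_date) >= index_day &
             as.integer(service_date) <= index_day + period_end]
  if (nrow(op)) {
    op[, nsclc := grepl("C34", dx_codes, fixed = TRUE) |
         (!is.na(drug_code) & drug_code %in% dict[is_sact(drug_class), drug_code])]
    frac <- calib$nsclc_outpatient_cost_frac
    op[, grp_n := .N, by = .(patient_id, nsclc)]
    op[, any_other := any(!nsclc) & any(nsclc), by = patient_id]
    op[, share := fifelse(any_other,
                          fifelse(nsclc, frac, 1 - frac) / grp_n,
                          1 / .N), by = patient_id]
    op[, paid2022 := total * share]
    dts <- op$service_date
    medical[op$row_id, paid_amount := round(
      op$paid2022 * unname(cpi[as.character(data.table::year(dts))]) /
        cpi[[as.character(config$reference_year)]], 2)]
  }
  medical[, row_id := NULL]
  medical[, claim_id := sprintf("MC%08d", .I)]
  medical[, service_year := data.table::year(service_date)]
  setcolorder(medical, c("claim_id", "patient_id", "service_date", "setting",
                         "dx_codes", "drug_code", "paid_amount", "service_year"))

  pharmacy <- rbindlist(rx, fill = TRUE)
  if (nrow(pharmacy) == 0L) {
    pharmacy <- data.table(patient_id = character(), fill_date = as.Date(character()),
                           drug_code = character(), days_supply = integer(),
                           paid_amount = numeric())
  }
  pharmacy[, claim_id := sprintf("RC%08d", .I)]
  setcolorder(pharmacy, c("claim_id", "patient_id", "fill_date", "drug_code",
                          "days_supply", "paid_amount"))

  ## --- enrollment -----------------------------------------------------------
  enr_start <- pt$dx_day - config$pre_dx_lookback_days -
    floor(stats::runif(N) * 60)
  enr_end <- fifelse(full_stream, pt$index_day + pt$fu_off, pt$dx_day + 400L)
  gap_pat <- pt$status == "ENROLLMENT_GAP"
  hole <- pt$dx_day - 30L - floor(stats::runif(N) * 120)
  enr1 <- data.table(patient_id = pt$patient_id,
                     start_date = as.Date(enr_start, origin = origin),
                     end_date = as.Date(fifelse(gap_pat, hole - 1L, enr_end),
                                        origin = origin),
                     medical = TRUE, pharmacy = TRUE)
  enr2 <- data.table(patient_id = pt$patient_id[gap_pat],
                     start_date = as.Date(hole[gap_pat] + 1L, origin = origin),
                     end_date = as.Date(enr_end[gap_pat], origin = origin),
                     medical = TRUE, pharmacy = TRUE)
  enrollment <- rbind(enr1, enr2)

  patients <- pt[, .(patient_id, birth_year, sex, region, payer,
                     death_date = as.Date(death_day, origin = origin))]

  ## --- ground truth ----------------------------------------------------------
  truth <- pt[, .(
    patient_id,
    eligible = status == "ELIGIBLE",
    failed_filter = fifelse(status == "ELIGIBLE", NA_character_, status),
    true_category = fifelse(status %in% c("NO_METASTASIS", "NO_SACT_AFTER_SM"),
                            NA_character_, category),
    true_lot_starts = fifelse(
      status %in% c("NO_METASTASIS", "NO_SACT_AFTER_SM"), "",
      fifelse(has_2l,
              paste(format(index_date), format(as.Date(index_day + l2_off, origin = origin)),
                    sep = "|"),
              format(index_date))),
    true_1l_duration_days = fifelse(full_stream, true_dur, NA_integer_),
    true_censored = fifelse(full_stream, true_cens, NA),
    true_2l_start = as.Date(fifelse(has_2l, index_day + l2_off, NA_integer_),
                            origin = origin)
  )]

  ds <- claims_dataset(patients, enrollment, medical, pharmacy, dict)
  list(dataset = ds, truth = truth)
}

empty_simulation <- function(dict) {
  patients <- data.table(patient_id = character(), birth_year = integer(),
                         sex = character(), region = character(),
                         payer = character(), death_date = as.Date(character()))
  enrollment <- data.table(patient_id = character(),
                           start_date = as.Date(character()),
                           end_date = as.Date(character()),
                           medical = logical(), pharmacy = logical())
  medical <- data.table(claim_id = character(), patient_id = character(),
                        service_date = as.Date(character()), setting = character(),
                        dx_codes = character(), drug_code = character(),
                        paid_amount = numeric(), service_year = integer())
  pharmacy <- data.table(claim_id = character(), patient_id = character(),
                         fill_date = as.Date(character()), drug_code = character(),
                         days_supply = integer(), paid_amount = numeric())
  truth <- data.table(patient_id = character(), eligible = logical(),
                      failed_filter = character(), true_category = character(),
                      true_lot_starts = character(),
                      true_1l_duration_days = integer(), true_censored = logical(),
                      true_2l_start = as.Date(character()))
  list(dataset = claims_dataset(patients, enrollment, medical, pharmacy, dict),
       truth = truth)
}
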