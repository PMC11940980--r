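library(data.table)

DICT <- load_drug_dictionary()
CFG <- default_config()

# --- hand-built fixture builders ---------------------------------------------

mk_patients <- function(ids, birth_year = 1950L, sex = "M", region = "South",
                        payer = "MedicareAdvantage", death_date = as.Date(NA)) {
  data.table(patient_id = ids, birth_year = birth_year, sex = sex,
             region = region, payer = payer, death_date = death_date)
}

mk_enroll <- function(id, start, end, medical = TRUE, pharmacy = TRUE) {
  data.table(patient_id = id, start_date = as.Date(start), end_date = as.Date(end),
             medical = medical, pharmacy = pharmacy)
}

mk_med <- function(id, date, setting = "OUTPATIENT", dx = "", drug = NA_character_,
                   paid = 0) {
  date <- as.Date(date)
  data.table(claim_id = paste0("T", seq_along(date), "_", id[1],
                               format(date, "%j")),
             patient_id = id, service_date = date, setting = setting,
             dx_codes = dx, drug_code = drug, paid_amount = paid,
             service_year = as.integer(format(date, "%Y")))
}

mk_rx <- function(id, date, drug, days_supply = 21L, paid = 0) {
  date <- as.Date(date)
  data.table(claim_id = paste0("R", seq_along(date), "_", id[1]),
             patient_id = id, fill_date = date, drug_code = drug,
             days_supply = days_supply, paid_amount = paid)
}

build_ds <- function(patients, enrollment, medical = NULL, pharmacy = NULL) {
  if (is.null(medical)) medical <- mk_med(character(0), as.Date(character(0)))[0]
  if (is.null(pharmacy)) pharmacy <- mk_rx(character(0), as.Date(character(0)), character(0))[0]
  claims_dataset(patients, enrollment, medical, pharmacy, DICT)
}

# A fully eligible single patient: C34 dx 2020-02-01, metastasis 2020-03-01,
# pembrolizumab + carboplatin + pemetrexed cycles q21d from 2020-03-15.
eligible_patient_claims <- function(id = "P1", n_cycles = 6,
                                    drugs = c("J9271", "J9045", "J9305"),
                                    index = "2020-03-15") {
  index <- as.Date(index)
  cyc_dates <- index + 21 * (seq_len(n_cycles) - 1)
  rbind(
    mk_med(id, "2020-02-01", dx = "C34.90"),
    mk_med(id, "2020-03-01", dx = "C79.51|C34.90"),
    rbindlist(lapply(drugs, function(d) mk_med(id, cyc_dates, drug = d, dx = "C34.90")))
  )
}

eligible_patient_ds <- function(id = "P1", ...) {
  build_ds(mk_patients(id),
           mk_enroll(id, "2019-06-01", "2022-12-31"),
           eligible_patient_claims(id, ...))
}

# --- independent naive Kaplan-Meier oracle ------------------------------------
# Recomputes the risk set from scratch at every event time; used to cross-check
# the product-limit implementation.
naive_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  surv <- numeric(length(ts))
  for (k in seq_along(ts)) {
    n_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  list(time = ts, surv = surv,
       median = if (any(surv <= 0.5 + 1e-12)) min(ts[surv <= 0.5 + 1e-12]) else NA_real_)
}

# --- shared simulations (memoized; several files reuse the same draws) --------
.sim_cache <- new.env(parent = emptyenv())

shared_sim <- function(n, seed) {
  key <- paste0("n", n, "_s", seed)
  if (!exists(key, .sim_cache)) {
    assign(key, simulate_claims(default_calibration(n_patients = n, seed = seed)),
           .sim_cache)
  }
  get(key, .sim_cache)
}

shared_pipeline <- function(n, seed) {
  key <- paste0("res_n", n, "_s", seed)
  if (!exists(key, .sim_cache)) {
    assign(key, run_pipeline(shared_sim(n, seed)$dataset), .sim_cache)
  }
  get(key, .sim_cache)
}
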