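# Key-date derivation, the eligibility cascade, and baseline profiling.

test_that("dx date is the earliest C34 claim in any dx position", {
  med <- rbind(mk_med("P1", "2020-03-01", dx = "C34.10"),
               mk_med("P1", "2020-02-01", dx = "C34.90"),
               mk_med("P2", "2020-02-01", dx = "I10"),
               mk_med("P3", "2020-04-01", dx = "I10|E11.9|C34.91"))
  ds <- build_ds(mk_patients(c("P1", "P2", "P3")),
                 mk_enroll(c("P1", "P2", "P3"), "2019-01-01", "2021-12-31"))
  ds$medical_claims <- med
  dx <- derive_dx_date(ds, CFG)
  expect_equal(dx[patient_id == "P1", dx_date], as.Date("2020-02-01"))
  expect_false("P2" %in% dx$patient_id)
  expect_equal(dx[patient_id == "P3", dx_date], as.Date("2020-04-01"))
})

test_that("secondary-malignancy date is the earliest metastasis claim on/after dx", {
  med <- rbind(mk_med("P1", "2020-02-01", dx = "C34.90"),
               mk_med("P1", "2020-02-01", dx = "C79.51"),  # on dx date itself
               mk_med("P1", "2020-05-01", dx = "C78.7"),
               mk_med("P2", "2020-02-01", dx = "C34.90"),
               mk_med("P2", "2020-01-22", dx = "C78.00"))  # only before dx
  ds <- build_ds(mk_patients(c("P1", "P2")),
                 mk_enroll(c("P1", "P2"), "2019-01-01", "2021-12-31"))
  ds$medical_claims <- med
  sm <- derive_sm_date(ds, derive_dx_date(ds, CFG), CFG)
  expect_equal(sm[patient_id == "P1", sm_date], as.Date("2020-02-01"))
  expect_false("P2" %in% sm$patient_id)
})

test_that("index date is the first SACT on/after the metastasis date", {
  med <- rbind(mk_med("P1", "2020-02-01", dx = "C34.90"),
               mk_med("P1", "2020-03-01", dx = "C79.51"),
               mk_med("P1", "2020-02-15", drug = "J9045"),   # pre-metastasis SACT
               mk_med("P1", "2020-03-21", drug = "J9045"))
  rx <- mk_rx("P1", "2020-03-21", "J9305")  # same-day pharmacy fill: tie immaterial
  ds <- build_ds(mk_patients("P1"), mk_enroll("P1", "2019-01-01", "2021-12-31"),
                 med, rx)
  sm <- derive_sm_date(ds, derive_dx_date(ds, CFG), CFG)
  idx <- derive_index_date(ds, sm, CFG)
  expect_equal(idx$index_date, as.Date("2020-03-21"))

  # with only pre-metastasis SACT the index is absent
  ds2 <- build_ds(mk_patients("P1"), mk_enroll("P1", "2019-01-01", "2021-12-31"),
                  med[1:3])
  idx2 <- derive_index_date(ds2, derive_sm_date(ds2, derive_dx_date(ds2, CFG), CFG), CFG)
  expect_equal(nrow(idx2), 0L)
})

test_that("continuous enrollment requires full dual coverage, inclusive endpoints", {
  rows <- data.table::data.table(patient_id = "P1",
                                 dx_date = as.Date("2020-03-01"),
                                 index_date = as.Date("2020-06-01"))
  # window is [2019-09-03, 2020-07-01]
  ds_full <- build_ds(mk_patients("P1"), mk_enroll("P1", "2019-09-03", "2020-07-01"))
  expect_true(check_enrollment(ds_full, rows, CFG))

  # span ending exactly index + 30 counts (inclusive endpoint)
  ds_exact <- build_ds(mk_patients("P1"), mk_enroll("P1", "2019-01-01", "2020-07-01"))
  expect_true(check_enrollment(ds_exact, rows, CFG))
  ds_short <- build_ds(mk_patients("P1"), mk_enroll("P1", "2019-01-01", "2020-06-30"))
  expect_false(check_enrollment(ds_short, rows, CFG))

  # one-day hole inside the window breaks strict continuity
  hole <- as.Date("2020-03-01") - 90
  ds_hole <- build_ds(mk_patients("P1"),
                      rbind(mk_enroll("P1", "2019-01-01", hole - 1),
                            mk_enroll("P1", hole + 1, "2020-12-31")))
  expect_false(check_enrollment(ds_hole, rows, CFG))

  # medical-only coverage is not enough
  ds_med_only <- build_ds(mk_patients("P1"),
                          mk_enroll("P1", "2019-01-01", "2020-12-31", pharmacy = FALSE))
  expect_false(check_enrollment(ds_med_only, rows, CFG))
})

test_that("exclusion rules: targeted any time, SCLC-typical before index, VEGF never", {
  base <- function(id) eligible_patient_claims(id)
  # osimertinib AFTER the index still excludes (any time in study period)
  med_t <- rbind(base("P1"), mk_med("P1", "2020-06-01", drug = "NDC-OSIM"))
  # bevacizumab never triggers the targeted exclusion
  med_v <- rbind(base("P2"), mk_med("P2", "2020-04-26", drug = "J9035"))
  # topotecan before the index excludes
  med_s <- rbind(base("P3"), mk_med("P3", "2020-02-13", drug = "J9351"))
  ids <- c("P1", "P2", "P3")
  ds <- build_ds(mk_patients(ids), mk_enroll(ids, "2019-06-01", "2022-12-31"),
                 rbind(med_t, med_v, med_s))
  ch <- build_cohort(ds, CFG)$cohort
  expect_equal(ch[patient_id == "P1", failed_filter], "no_targeted")
  expect_true(ch[patient_id == "P2", eligible])
  expect_equal(ch[patient_id == "P3", failed_filter], "no_sclc")
})

test_that("attrition counts are nonincreasing and empty datasets give zeros", {
  sim <- shared_sim(400, 99)
  att <- build_cohort(sim$dataset, CFG)$attrition
  expect_true(all(diff(att$patients_remaining) <= 0))

  ds0 <- simulate_claims(default_calibration(n_patients = 0, seed = 1))$dataset
  att0 <- build_cohort(ds0, CFG)$attrition
  expect_true(all(att0$patients_remaining == 0L))
})

test_that("cohort eligibility and failure labels match ground truth exactly", {
  sim <- shared_sim(400, 99)
  ch <- build_cohort(sim$dataset, CFG)$cohort
  tr <- data.table::copy(sim$truth)
  data.table::setnames(tr, c("eligible", "failed_filter"),
                       c("true_eligible", "true_failed"))
  m <- merge(ch, tr, by = "patient_id")
  expect_identical(m$eligible, m$true_eligible)
  f2c <- oncolot:::FILTER_TO_CASCADE
  inel <- m[true_eligible == FALSE]
  expect_identical(inel$failed_filter, unname(f2c[inel$true_failed]))
})

test_that("baseline lookback is [index-180, index-1] and the score is a weighted sum", {
  med <- rbind(eligible_patient_claims("P1"),
               mk_med("P1", as.Date("2020-03-15") - 30, dx = "I10"),     # in window
               mk_med("P1", "2020-03-15", dx = "E11.9"),                 # on index: out
               mk_med("P1", as.Date("2020-03-15") - 181, dx = "J44.9"),  # too early
               mk_med("P1", as.Date("2020-03-15") - 10, dx = "N18.3"),
               mk_med("P1", as.Date("2020-03-15") - 10, dx = "F17.210"))
  ds <- build_ds(mk_patients("P1"), mk_enroll("P1", "2019-06-01", "2022-12-31"), med)
  ch <- build_cohort(ds, CFG)$cohort
  expect_true(ch$eligible)
  bl <- baseline_profiles(ds, ch, CFG)
  expect_true(bl$hypertension)
  expect_false(bl$diabetes)   # on the index date itself: excluded
  expect_false(bl$copd)       # outside the 180-day window
  expect_true(bl$chronic_kidney_disease)
  expect_true(bl$smoking_history)
  expect_equal(bl$nci_cci, default_charlson_weights()[["chronic_kidney_disease"]])

  # unit-weight configuration: score is the plain sum of flagged conditions
  cfg2 <- analysis_config(charlson_weights = c(diabetes = 1, copd = 1,
                                               chronic_kidney_disease = 1))
  bl2 <- baseline_profiles(ds, ch, cfg2)
  expect_equal(bl2$nci_cci, 1)  # only CKD flagged among the weighted set
})

test_that("baseline flags ignore claims outside the lookback window", {
  med0 <- eligible_patient_claims("P1")
  ds0 <- build_ds(mk_patients("P1"), mk_enroll("P1", "2019-06-01", "2022-12-31"), med0)
  ch <- build_cohort(ds0, CFG)$cohort
  bl0 <- baseline_profiles(ds0, ch, CFG)

  med1 <- rbind(med0, mk_med("P1", "2021-06-01", dx = "I10"),
                mk_med("P1", "2019-01-15", dx = "J44.9"))
  ds1 <- build_ds(mk_patients("P1"), mk_enroll("P1", "2019-06-01", "2022-12-31"), med1)
  bl1 <- baseline_profiles(ds1, build_cohort(ds1, CFG)$cohort, CFG)
  expect_identical(as.data.frame(bl0), as.data.frame(bl1))
})
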