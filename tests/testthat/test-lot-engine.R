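# Drug episodes, the 30-day regimen window, advancement rules, line derivation,
# and regimen classification.

test_that("episode runout conventions: fill + supply - 1, service + runout - 1", {
  ds <- build_ds(mk_patients("P1"), mk_enroll("P1", "2019-06-01", "2022-12-31"),
                 mk_med("P1", "2020-03-15", drug = "J9271"),
                 mk_rx("P1", "2020-03-15", "J9305", days_supply = 21L))
  ep <- build_episodes(ds, "P1", as.Date("2020-03-15"))
  expect_equal(ep[drug_code == "J9305", runout_date], as.Date("2020-03-15") + 20)
  expect_equal(ep[drug_code == "J9271", runout_date], as.Date("2020-03-15") + 20)
})

test_that("substitution groups collapse to one canonical id", {
  ds <- build_ds(mk_patients("P1"), mk_enroll("P1", "2019-06-01", "2022-12-31"),
                 rbind(mk_med("P1", "2020-03-15", drug = "J9060"),
                       mk_med("P1", "2020-03-29", drug = "J9045")))
  ep <- build_episodes(ds, "P1", as.Date("2020-03-15"))
  expect_equal(unique(ep$canonical_id), "platinum_agent")
  reg <- assemble_initial_regimen(ep, as.Date("2020-03-15"), CFG)
  expect_equal(reg, "platinum_agent")
})

test_that("regimen window includes day 0 and day 29 but not day 30", {
  start <- as.Date("2020-03-15")
  ds <- build_ds(mk_patients("P1"), mk_enroll("P1", "2019-06-01", "2022-12-31"),
                 rbind(mk_med("P1", start, drug = "J9271"),
                       mk_med("P1", start + 29, drug = "J9045"),
                       mk_med("P1", start + 30, drug = "J9171")))
  ep <- build_episodes(ds, "P1", start)
  reg <- assemble_initial_regimen(ep, start, CFG)
  expect_setequal(reg, c("pembrolizumab", "platinum_agent"))
  expect_false("docetaxel" %in% reg)
})

test_that("event evaluation: gap rule first, reintroduction continues, maintenance absorbs", {
  reg <- c("pembrolizumab", "platinum_agent", "pemetrexed")
  d0 <- as.Date("2020-01-01")
  ep <- function(canonical, day, maint = FALSE) {
    list(canonical_id = canonical, maintenance_eligible = maint,
         start_date = d0 + day)
  }
  # reintroduction of an in-regimen drug: continue
  expect_equal(evaluate_event(reg, d0 + 40, ep("pemetrexed", 45, TRUE), CFG),
               "CONTINUE")
  # new non-regimen drug within 60 days of runout: advance
  expect_equal(evaluate_event(c("platinum_agent", "paclitaxel_taxane"),
                              d0 + 55, ep("docetaxel", 70), CFG),
               "ADVANCE_NEW_DRUG")
  # gap of exactly 60 days advances even for an in-regimen drug
  expect_equal(evaluate_event(reg, d0 + 100, ep("pembrolizumab", 160), CFG),
               "ADVANCE_GAP")
  expect_equal(evaluate_event(reg, d0 + 100, ep("pembrolizumab", 159), CFG),
               "CONTINUE")
  # maintenance drug with its backbone present is absorbed
  expect_equal(evaluate_event(c("platinum_agent", "gemcitabine"),
                              d0 + 40, ep("pemetrexed", 45, TRUE), CFG),
               "ABSORB_MAINTENANCE")
  # maintenance-eligible drug without the backbone advances
  expect_equal(evaluate_event(c("pembrolizumab"),
                              d0 + 40, ep("bevacizumab", 45, TRUE), CFG),
               "ADVANCE_NEW_DRUG")
})

test_that("a 59-day internal gap keeps one line; 60 days splits it", {
  start <- as.Date("2020-03-15")
  mk_gap_ds <- function(gap) {
    claims <- rbind(
      eligible_patient_claims("P1", n_cycles = 2, drugs = "J9271", index = start),
      mk_med("P1", start + 21 + 20 + gap, drug = "J9271"))
    build_ds(mk_patients("P1"), mk_enroll("P1", "2019-06-01", "2022-12-31"), claims)
  }
  run <- function(gap) {
    ds <- mk_gap_ds(gap)
    derive_lots(ds, build_cohort(ds, CFG)$cohort, CFG)
  }
  lots59 <- run(59)
  expect_equal(nrow(lots59), 1L)
  lots60 <- run(60)
  expect_equal(nrow(lots60), 2L)
  expect_equal(lots60[lot_number == 2L, start_date], start + 41 + 60)
  expect_equal(lots60[lot_number == 1L, end_reason], "GAP")
  expect_equal(lots60[lot_number == 1L, end_date],
               lots60[lot_number == 2L, start_date] - 1)
})

test_that("single-regimen lines close at follow-up or study end with the right reason", {
  ds <- eligible_patient_ds("P1")
  lots <- derive_lots(ds, build_cohort(ds, CFG)$cohort, CFG)
  expect_equal(nrow(lots), 1L)
  expect_equal(lots$end_reason, "ENROLLMENT_END")
  expect_equal(lots$end_date, as.Date("2022-12-31"))
  expect_equal(lots$category, "ICI_PBCT")

  # death before enrollment end closes the line with reason DEATH
  pats <- mk_patients("P1", death_date = as.Date("2020-09-01"))
  ds2 <- claims_dataset(pats, mk_enroll("P1", "2019-06-01", "2022-12-31"),
                        eligible_patient_claims("P1"),
                        mk_rx(character(0), as.Date(character(0)), character(0))[0], DICT)
  lots2 <- derive_lots(ds2, build_cohort(ds2, CFG)$cohort, CFG)
  expect_equal(lots2$end_reason, "DEATH")
  expect_equal(lots2$end_date, as.Date("2020-09-01"))
})

test_that("a new non-regimen drug after the window opens a second line", {
  start <- as.Date("2020-03-15")
  claims <- rbind(eligible_patient_claims("P1", n_cycles = 6, index = start),
                  mk_med("P1", start + 244, drug = "J9171"),
                  mk_med("P1", start + 265, drug = "J9171"))
  ds <- build_ds(mk_patients("P1"), mk_enroll("P1", "2019-06-01", "2022-12-31"), claims)
  lots <- derive_lots(ds, build_cohort(ds, CFG)$cohort, CFG)
  expect_equal(nrow(lots), 2L)
  expect_equal(lots[lot_number == 2L, start_date], start + 244)
  expect_equal(lots[lot_number == 1L, end_date], start + 243)
  expect_equal(lots[lot_number == 2L, category], "NONPBCT_MONO")
})

test_that("maintenance pemetrexed after a platinum doublet does not advance the line", {
  start <- as.Date("2020-03-15")
  claims <- rbind(
    eligible_patient_claims("P1", n_cycles = 4, drugs = c("J9045", "J9201"),
                            index = start),
    mk_med("P1", start + 4 * 21 + 14, drug = "J9305"),  # pemetrexed, post-window
    mk_med("P1", start + 5 * 21 + 14, drug = "J9305"))
  ds <- build_ds(mk_patients("P1"), mk_enroll("P1", "2019-06-01", "2022-12-31"), claims)
  lots <- derive_lots(ds, build_cohort(ds, CFG)$cohort, CFG)
  expect_equal(nrow(lots), 1L)
  # absorbed drug extends the line but not its classification regimen
  expect_false(grepl("pemetrexed", lots$regimen))
  expect_equal(lots$category, "PBCT_MONO_COMBO")
})

test_that("regimen classification covers all seven categories and the VEGF rules", {
  cases <- list(
    list(reg = c("pembrolizumab", "platinum_agent", "pemetrexed"), cat = "ICI_PBCT"),
    list(reg = c("nivolumab", "ipilimumab"), cat = "ICI_MONO_DUAL"),
    list(reg = "pembrolizumab", cat = "ICI_MONO_DUAL"),
    list(reg = c("atezolizumab", "paclitaxel_taxane"), cat = "ICI_NONPBCT"),
    list(reg = c("platinum_agent", "gemcitabine"), cat = "PBCT_MONO_COMBO"),
    list(reg = "platinum_agent", cat = "PBCT_MONO_COMBO"),
    list(reg = "docetaxel", cat = "NONPBCT_MONO"),
    list(reg = c("gemcitabine", "vinorelbine"), cat = "NONPBCT_COMBO"),
    list(reg = "bevacizumab", cat = "OTHER"),
    list(reg = c("bevacizumab", "pembrolizumab"), cat = "OTHER"),
    # VEGF added to an otherwise-determined category never changes it
    list(reg = c("bevacizumab", "platinum_agent", "pemetrexed"), cat = "PBCT_MONO_COMBO"),
    list(reg = c("bevacizumab", "pembrolizumab", "platinum_agent"), cat = "ICI_PBCT"),
    list(reg = c("bevacizumab", "docetaxel"), cat = "NONPBCT_MONO")
  )
  for (cs in cases) {
    expect_equal(classify_regimen(cs$reg, DICT), cs$cat,
                 label = paste(cs$reg, collapse = "+"))
  }
})

test_that("episodes partition the treated interval; derivation is idempotent", {
  sim <- shared_sim(400, 99)
  res <- shared_pipeline(400, 99)
  lots <- res$lots
  sact <- oncolot:::sact_claims(sim$dataset)
  elig <- res$cohort[eligible == TRUE, .(patient_id, index_date)]
  ep <- merge(sact, elig, by = "patient_id")
  ep <- ep[date >= index_date]
  j <- lots[ep, on = .(patient_id, start_date <= date, end_date >= date),
            nomatch = NULL]
  # every episode on/after the 1L start lies in exactly one segment
  expect_equal(nrow(j), nrow(ep))
  expect_true(all(lots[, .N, by = .(patient_id, start_date)]$N == 1L))
  # segments are ordered and non-overlapping
  ord <- lots[order(patient_id, lot_number),
              .(ok = all(diff(as.integer(start_date)) > 0) &&
                  all(utils::head(end_date, -1) < utils::tail(start_date, -1)),
                consec = identical(lot_number, seq_len(.N))), by = patient_id]
  expect_true(all(ord$ok) && all(ord$consec))

  lots2 <- derive_lots(sim$dataset, res$cohort, CFG)
  expect_identical(as.data.frame(lots), as.data.frame(lots2))
})

test_that("cisplatin/carboplatin swaps never change segments or categories", {
  sim <- shared_sim(400, 99)
  res <- shared_pipeline(400, 99)
  ds2 <- sim$dataset
  med <- data.table::copy(ds2$medical_claims)
  swap <- med$drug_code %in% c("J9045", "J9060")
  med[swap, drug_code := data.table::fifelse(drug_code == "J9045", "J9060", "J9045")]
  ds2$medical_claims <- med
  lots2 <- derive_lots(ds2, build_cohort(ds2, CFG)$cohort, CFG)
  cols <- c("patient_id", "lot_number", "start_date", "end_date", "category")
  expect_identical(as.data.frame(res$lots[, ..cols]), as.data.frame(lots2[, ..cols]))
})
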