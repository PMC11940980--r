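test_that("abutting and overlapping enrollment spans merge; covered days invariant", {
  enr <- rbind(mk_enroll("P1", "2020-01-01", "2020-06-30"),
               mk_enroll("P1", "2020-07-01", "2020-12-31"))
  m <- merge_enrollment_spans(enr)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start_date, as.Date("2020-01-01"))
  expect_equal(m$end_date, as.Date("2020-12-31"))

  # random spans: merged spans are pairwise disjoint and cover the same days
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    s <- as.Date("2020-01-01") + sample(0:200, n, replace = TRUE)
    e <- s + sample(0:90, n, replace = TRUE)
    enr <- data.table::data.table(patient_id = "P1", start_date = s, end_date = e,
                                  medical = TRUE, pharmacy = TRUE)
    m <- merge_enrollment_spans(enr)
    covered <- unique(unlist(Map(seq, as.integer(s), as.integer(e))))
    merged_days <- unlist(Map(seq, as.integer(m$start_date), as.integer(m$end_date)))
    expect_equal(sort(merged_days), sort(covered))
    expect_false(anyDuplicated(merged_days) > 0)
    if (nrow(m) > 1) {
      expect_true(all(m$start_date[-1] > m$end_date[-nrow(m)] + 1))
    }
  }
})

test_that("a gap between spans is preserved unless within tolerance", {
  enr <- rbind(mk_enroll("P1", "2020-01-01", "2020-06-30"),
               mk_enroll("P1", "2020-07-02", "2020-12-31"))  # 1-day hole (07-01)
  expect_equal(nrow(merge_enrollment_spans(enr)), 2L)
  expect_equal(nrow(merge_enrollment_spans(enr, gap_tolerance = 1L)), 1L)
})

test_that("write/read round trip is the identity on a generated dataset", {
  sim <- shared_sim(150, 21)
  dir <- file.path(tempdir(), "roundtrip")
  write_claims_dataset(sim$dataset, dir)
  back <- read_claims_dataset(dir)
  for (tb in c("patients", "enrollment", "medical_claims", "pharmacy_claims")) {
    expect_equal(as.data.frame(back[[tb]]), as.data.frame(sim$dataset[[tb]]),
                 ignore_attr = TRUE, label = tb)
  }
  expect_equal(as.data.frame(back$drug_dictionary),
               as.data.frame(sim$dataset$drug_dictionary), ignore_attr = TRUE)
  expect_equal(sum(back$rejections$n), 0L)
})

test_that("an empty dataset writes five header-only files that re-read empty", {
  sim <- simulate_claims(default_calibration(n_patients = 0, seed = 1))
  dir <- file.path(tempdir(), "empty_ds")
  paths <- write_claims_dataset(sim$dataset, dir)
  expect_length(paths, 5L)
  expect_true(all(file.exists(paths)))
  back <- read_claims_dataset(dir)
  expect_equal(nrow(back$patients), 0L)
  expect_equal(nrow(back$medical_claims), 0L)
})

test_that("a claim with no dx codes and no drug is accepted", {
  ds <- build_ds(mk_patients("P1"), mk_enroll("P1", "2020-01-01", "2020-12-31"),
                 mk_med("P1", "2020-05-01", dx = "", drug = NA_character_, paid = 50))
  expect_equal(nrow(ds$medical_claims), 1L)
})

test_that("malformed rows are rejected and counted; missing files are fatal", {
  sim <- shared_sim(30, 22)
  dir <- file.path(tempdir(), "rejects")
  write_claims_dataset(sim$dataset, dir)
  med <- data.table::fread(file.path(dir, "medical_claims.csv"),
                           colClasses = "character")
  med$service_date[1] <- "2020-13-45"   # malformed date
  med$setting[2] <- "HOME"              # unknown setting
  med$paid_amount[3] <- "-5"            # negative amount
  data.table::fwrite(med, file.path(dir, "medical_claims.csv"))
  ds <- read_claims_dataset(dir)
  expect_equal(sum(ds$rejections$n), 3L)
  expect_equal(nrow(ds$medical_claims), nrow(med) - 3L)

  file.remove(file.path(dir, "patients.csv"))
  expect_error(read_claims_dataset(dir), "missing dataset file")
})

test_that("unresolvable SACT drug codes are fatal and carry the code", {
  med <- mk_med("P1", "2020-05-01", drug = "J9999")
  expect_error(
    claims_dataset(mk_patients("P1"), mk_enroll("P1", "2020-01-01", "2020-12-31"),
                   med, mk_rx(character(0), as.Date(character(0)), character(0))[0],
                   DICT),
    "J9999")
})

test_that("drug lookup resolves classes, substitution groups, and SACT status", {
  pem <- lookup_drug("J9271", DICT)
  expect_equal(pem$drug_class, "ICI")
  expect_true(is_sact(pem))

  carb <- lookup_drug("J9045", DICT)
  expect_equal(carb$drug_class, "PLATINUM")
  expect_equal(carb$substitution_group, "platinum_agent")
  cis <- lookup_drug("J9060", DICT)
  expect_equal(cis$canonical_id, carb$canonical_id)

  # paclitaxel and albumin-bound paclitaxel share a substitution group
  expect_equal(lookup_drug("J9267", DICT)$canonical_id,
               lookup_drug("J9264", DICT)$canonical_id)

  statin <- lookup_drug("RX-STAT", DICT)
  expect_equal(statin$drug_class, "OTHER")
  expect_false(is_sact(statin))

  expect_error(lookup_drug("NOPE", DICT), "NOPE")
})
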