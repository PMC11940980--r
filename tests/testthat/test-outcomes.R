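# Censored durations, the product-limit estimator, TTNT and the SACT period.

d0 <- as.Date("2020-01-01")

mk_lots <- function(runout_off, next_off = NA, followup_off = 500,
                    death_off = NA, study_end = as.Date("2023-03-31")) {
  l1 <- data.table::data.table(
    patient_id = "P1", lot_number = 1L, start_date = d0,
    end_date = d0 + followup_off, regimen = "pembrolizumab",
    category = "ICI_MONO_DUAL", max_runout = d0 + runout_off,
    end_reason = "ENROLLMENT_END",
    followup_end = min(d0 + followup_off,
                       if (is.na(death_off)) as.Date("9999-12-31") else d0 + death_off))
  if (!is.na(next_off)) {
    l2 <- data.table::copy(l1)
    l2[, `:=`(lot_number = 2L, start_date = d0 + next_off,
              end_date = d0 + followup_off)]
    l1 <- rbind(l1, l2)
  }
  l1
}

fake_ds <- function(death_off = NA) {
  list(patients = data.table::data.table(
    patient_id = "P1",
    death_date = if (is.na(death_off)) as.Date(NA) else d0 + death_off))
}

test_that("duration is an inclusive day count to the earliest qualifying end", {
  # runout at day 180, no 2L, long follow-up: 181 days, uncensored
  r <- compute_durations(mk_lots(180), fake_ds(), CFG)
  expect_equal(r$duration_days, 181L)
  expect_false(r$censored)

  # 2L at day 120 with runout at day 200: ends day 119, uncensored
  r <- compute_durations(mk_lots(200, next_off = 120), fake_ds(), CFG)
  expect_equal(r[1, duration_days], 120L)
  expect_false(r[1, censored])

  # enrollment ends day 90 before the runout: 91 days, censored
  r <- compute_durations(mk_lots(180, followup_off = 90), fake_ds(), CFG)
  expect_equal(r$duration_days, 91L)
  expect_true(r$censored)

  # death before the runout is an event, not censoring
  r <- compute_durations(mk_lots(180, followup_off = 90, death_off = 90),
                         fake_ds(death_off = 90), CFG)
  expect_equal(r$duration_days, 91L)
  expect_false(r$censored)
})

test_that("product-limit estimate matches hand computation and conventions", {
  # durations 1 (event), 2 (censored), 3 (event): S = 2/3 then 0; median 3
  rec <- data.table::data.table(patient_id = c("A", "B", "C"),
                                category = "X",
                                duration_days = c(1L, 2L, 3L),
                                censored = c(FALSE, TRUE, FALSE))
  km <- km_fit(rec, CFG)
  ev <- km$n_event > 0
  expect_equal(km$surv[ev], c(2 / 3, 0))
  expect_equal(km$median_days, 3)

  # no censoring: median is the usual "smallest t with S <= 0.5"
  rec2 <- data.table::data.table(patient_id = c("A", "B", "C"), category = "X",
                                 duration_days = c(2L, 4L, 6L), censored = FALSE)
  expect_equal(km_fit(rec2, CFG)$median_days, 4)

  # all censored: survival stays at 1, median undefined
  rec3 <- data.table::data.table(patient_id = c("A", "B"), category = "X",
                                 duration_days = c(5L, 9L), censored = TRUE)
  km3 <- km_fit(rec3, CFG)
  expect_true(all(km3$surv == 1))
  expect_true(is.na(km3$median_days))

  expect_error(km_fit(rec2[0], CFG), "at least one")
})

test_that("with no censoring the KM curve equals the empirical survival function", {
  set.seed(17)
  dur <- sample(1:40, 60, replace = TRUE)
  rec <- data.table::data.table(patient_id = as.character(1:60), category = "X",
                                duration_days = dur, censored = FALSE)
  km <- km_fit(rec, CFG)
  for (k in seq_along(km$time)) {
    expect_equal(km$surv[k], mean(dur > km$time[k]))
  }
})

test_that("product-limit estimator agrees exactly with a naive risk-set oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:50, 1)
    dur <- sample(1:30, n, replace = TRUE)
    cen <- stats::runif(n) < 0.35
    rec <- data.table::data.table(patient_id = as.character(seq_len(n)),
                                  category = "X", duration_days = dur,
                                  censored = cen)
    if (all(cen)) cen[1] <- FALSE
    rec$censored <- cen
    km <- km_fit(rec, CFG)
    oracle <- naive_km(dur, !cen)
    ev <- km$n_event > 0
    expect_equal(km$time[ev], oracle$time)
    expect_equal(km$surv[ev], oracle$surv, tolerance = 1e-12)
    expect_equal(km$median_days, oracle$median)
  }
})

test_that("TTNT is days from 1L start to the day before 2L, only with a 2L", {
  t1 <- compute_ttnt(mk_lots(200, next_off = 244))
  expect_equal(t1$ttnt_days, 244L)
  expect_equal(nrow(compute_ttnt(mk_lots(200))), 0L)
  # degenerate: 2L the day after the 1L start
  expect_equal(compute_ttnt(mk_lots(200, next_off = 1))$ttnt_days, 1L)
})

test_that("SACT period ends at the earliest of runout+30, day before 2L, follow-up end", {
  p <- compute_sact_periods(mk_lots(100), CFG)
  expect_equal(p$end_date, d0 + 130)
  p <- compute_sact_periods(mk_lots(100, next_off = 110), CFG)
  expect_equal(p[1, end_date], d0 + 109)
  p <- compute_sact_periods(mk_lots(100, followup_off = 90), CFG)
  expect_equal(p$end_date, d0 + 90)
})

test_that("SACT periods always lie within [index, follow-up end]", {
  res <- shared_pipeline(400, 99)
  l1 <- res$lots[lot_number == 1L]
  p <- merge(res$sact_periods, l1[, .(patient_id, index = start_date, followup_end)],
             by = "patient_id")
  expect_true(all(p$start_date == p$index))
  expect_true(all(p$end_date <= p$followup_end))
  expect_true(all(p$end_date >= p$start_date))
})

test_that("derived durations and censoring flags equal generator ground truth", {
  sim <- shared_sim(400, 99)
  res <- shared_pipeline(400, 99)
  m <- merge(sim$truth[eligible == TRUE], res$durations, by = "patient_id")
  expect_equal(nrow(m), sum(sim$truth$eligible))
  expect_identical(m$duration_days, m$true_1l_duration_days)
  expect_identical(m$censored, m$true_censored)
})
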