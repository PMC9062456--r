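# curation: adjustment, imputation, exclusions, audit log

test_that("completeness adjustment interpolates between its endpoints", {
  expect_equal(adjust_for_completeness(100, 0.8, 0), 100)
  expect_equal(adjust_for_completeness(100, 0.8, 1), 125)
  expect_equal(adjust_for_completeness(100, 0.8, 0.25), 106.25)
  expect_error(adjust_for_completeness(100, 0, 0.25), "c = 0")
  # monotone in k, never decreases the count
  ks <- seq(0, 1, 0.1)
  adj <- adjust_for_completeness(100, 0.7, ks)
  expect_true(all(diff(adj) > 0))
  expect_true(all(adj >= 100))
})

test_that("calendar-median imputation uses the clean cells' median", {
  x <- c(10, 12, 14, 500, 11, 13, 10, 12, 11, 13, 12, 10)
  flags <- x == 500
  # independent sort oracle over the 11 clean values
  clean <- sort(x[!flags])
  oracle <- clean[(length(clean) + 1) / 2]
  expect_equal(oracle, 12)
  imp <- impute_calendar_median(x, flags)
  expect_equal(imp[4], 12)
  expect_equal(imp[-4], x[-4], ignore_attr = TRUE)
  # idempotence without flags
  expect_equal(as.numeric(impute_calendar_median(x, rep(FALSE, 12))), x)
  # true-zero override wins
  tz <- rep(FALSE, 12); tz[4] <- TRUE
  expect_equal(impute_calendar_median(x, flags, true_zero = tz)[4], 0)
  # all cells flagged -> escalation
  expect_warning(out <- impute_calendar_median(x, rep(TRUE, 12)),
                 "escalate")
  expect_equal(as.numeric(out), x)
})

test_that("exclusion windows drop exactly the union of matches, once each", {
  cfg <- flat_config(n_districts = 2, months = c(201701, 202012))
  rec <- simulate_scenario(cfg)$records
  w <- list(scope = "all", from = 201904, to = 201910, reason = "strike")
  ex <- apply_exclusions(rec, list(w))
  gone <- period_seq(201904, 201910)
  expect_false(any(ex$records$period %in% gone))
  expect_equal(nrow(ex$log), 2 * length(gone))
  expect_true(all(ex$log$action == "excluded"))
  # empty window list: unchanged
  ex0 <- apply_exclusions(rec, list())
  expect_identical(ex0$records, rec)
  # overlapping windows: union applied once, one log entry per record
  w2 <- list(scope = "all", from = 201908, to = 201912, reason = "strike2")
  ex2 <- apply_exclusions(rec, list(w, w2))
  gone2 <- period_seq(201904, 201912)
  expect_false(any(ex2$records$period %in% gone2))
  expect_equal(nrow(ex2$log), 2 * length(gone2))
  expect_equal(anyDuplicated(ex2$log[c("district_id", "period", "service")]),
               0)
  # district-scoped window
  wd <- list(scope = "district", id = "D001", from = 201701, to = 201701,
             reason = "pilot")
  exd <- apply_exclusions(rec, list(wd))
  expect_equal(sum(rec$period == 201701) - sum(exd$records$period == 201701),
               1)
})

test_that("curate is an identity on a clean fully-reported dataset", {
  cfg <- flat_config(n_districts = 3, baseline = 200)
  rec <- simulate_scenario(cfg)$records
  cur <- curate(rec)
  expect_equal(cur$records$adjusted_value, cur$records$value)
  expect_equal(nrow(cur$log), 0)
})

test_that("low-completeness months are imputed, not adjusted", {
  rec <- make_records(rep(100, 12), expected = 100, actual = rep(95, 12))
  rec$reports_actual[5] <- 70  # c = 0.70 < 0.75
  cur <- curate(rec, adjustment_policy(k_by_service = 0.25))
  log5 <- cur$log[cur$log$period == rec$period[5], ]
  expect_equal(log5$action, "imputed_low_completeness")
  expect_equal(cur$records$adjusted_value[5], 100)  # clean median, unadjusted
  other <- cur$records$adjusted_value[-5]
  expect_equal(other, rep(adjust_for_completeness(100, 0.95, 0.25), 11))
})

test_that("true-zero overrides are kept at zero and logged", {
  rec <- make_records(c(rep(100, 6), 0, rep(100, 5)), expected = 100,
                      actual = c(rep(95, 6), 50, rep(95, 5)))
  tz <- data.frame(district_id = "D001", period = rec$period[7],
                   service = "ANC1")
  cur <- curate(rec, adjustment_policy(true_zero_overrides = tz))
  expect_equal(cur$records$adjusted_value[7], 0)
  expect_equal(cur$log$action[cur$log$period == rec$period[7]], "kept_zero")
})

test_that("curation log replays to the curated dataset exactly", {
  cfg <- scenario_config(n_districts = 12, services = c("ANC1", "IPD"),
                         completeness_mean = 0.85, outlier_rate = 0.01,
                         missing_rate = 0.01, seed = 21)
  rec <- simulate_scenario(cfg)$records
  pol <- adjustment_policy(exclusion_windows = list(
    list(scope = "all", from = 201704, to = 201706, reason = "strike")))
  cur <- curate(rec, pol)
  replayed <- replay_curation_log(rec, cur$log)
  expect_identical(replayed$adjusted_value, cur$records$adjusted_value)
  expect_identical(replayed$district_id, cur$records$district_id)
  # determinism
  cur2 <- curate(rec, pol)
  expect_identical(cur$records, cur2$records)
  expect_identical(cur$log, cur2$log)
  # imputation never yields negatives; adjustment never decreases a count
  adj <- cur$log[cur$log$action == "adjusted", ]
  expect_true(all(adj$replacement >= adj$original))
  expect_true(all(cur$records$adjusted_value >= 0, na.rm = TRUE))
})

test_that("curated national totals recover the truth within 1%", {
  cfg <- scenario_config(n_districts = 30, services = "ANC1",
                         completeness_mean = 0.85, q_nonreporting = 0.25,
                         shock = list(ANC1 = 0), outlier_rate = 0,
                         missing_rate = 0, seed = 31)
  sim <- simulate_scenario(cfg)
  cur <- curate(sim$records, adjustment_policy(k_by_service = 0.25))
  for (yr in 2017:2020) {
    tot_true <- sum(sim$truth$true_count[sim$truth$period %/% 100 == yr])
    sel <- cur$records$period %/% 100 == yr
    tot_cur <- sum(cur$records$adjusted_value[sel])
    expect_lt(abs(tot_cur - tot_true) / tot_true, 0.01)
  }
})
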