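# mixed-effects disruption model

test_that("frame construction yields the specified design columns", {
  cfg <- flat_config(n_districts = 3, months = c(201701, 202012))
  rec <- simulate_scenario(cfg)$records
  fr <- build_frame(rec, mode = "monthly")
  expect_equal(range(fr$time), c(0, 47))
  cols <- attr(fr, "covid_cols")
  expect_length(cols, 10)
  for (col in cols) expect_equal(sum(fr[[col]]), 3)  # one month x 3 districts
  expect_true(all(rowSums(fr[, cols]) <= 1))
  expect_true(all(fr[fr$period < 202003, cols] == 0))
  frp <- build_frame(rec, mode = "period")
  expect_equal(sum(frp$covid_period), 3 * 10)
  # excluded districts' rows are absent
  cur <- curate(rec, adjustment_policy(exclusion_windows = list(
    list(scope = "district", id = "D001", from = 202001, to = 202012,
         reason = "w"))))
  fr2 <- build_frame(cur$records)
  expect_equal(nrow(fr2), nrow(fr) - 12)
  # guards
  expect_error(build_frame(rec[rec$period < 202003, ]), "COVID window")
  expect_error(build_frame(rec, min_pre_months = 60), "pre-COVID months")
})

test_that("noise-free linear data are fitted exactly", {
  periods <- period_seq(201701, 202012)
  rec <- do.call(rbind, lapply(sprintf("D%03d", 1:3), function(d)
    make_records(100 + 2 * seq_along(periods) - 2, district_id = d,
                 periods = periods)))
  fr <- build_frame(rec)
  fit <- suppressMessages(fit_mixed_model(fr))
  co <- if (inherits(fit$model, "lm")) coef(fit$model)
        else lme4::fixef(fit$model)
  expect_equal(unname(co[["(Intercept)"]]), 100, tolerance = 1e-4)
  expect_equal(unname(co[["time"]]), 2, tolerance = 1e-4)
  expect_equal(unname(co[["covid_period"]]), 0, tolerance = 1e-4)
  # no shock: percent change 0 with a CI symmetric about 0
  pc <- percent_change(fit, fr)
  expect_equal(pc$pct_change, 0, tolerance = 1e-6)
  expect_equal(pc$ci_low, -pc$ci_high, tolerance = 1e-6)
})

test_that("zero district heterogeneity reproduces pooled OLS", {
  periods <- period_seq(201701, 202012)
  set.seed(5)
  rec <- do.call(rbind, lapply(sprintf("D%03d", 1:20), function(d)
    make_records(rpois(length(periods), 200), district_id = d,
                 periods = periods)))
  fr <- build_frame(rec)
  fit <- suppressMessages(fit_mixed_model(fr))
  ols <- lm(y ~ time + month + covid_period, data = fr)
  co <- if (inherits(fit$model, "lm")) coef(fit$model)
        else lme4::fixef(fit$model)
  expect_equal(unname(co[names(coef(ols))]), unname(coef(ols)),
               tolerance = 1e-3)
})

test_that("random-intercept SD is recovered at n = 100 districts", {
  set.seed(6)
  periods <- period_seq(201701, 202012)
  rec <- do.call(rbind, lapply(sprintf("D%03d", 1:100), function(d) {
    b <- rnorm(1, 0, 20)
    make_records(500 + b + 0.5 * (seq_along(periods) - 1) +
                   rnorm(length(periods), 0, 10),
                 district_id = d, periods = periods)
  }))
  fr <- build_frame(rec)
  fit <- suppressMessages(fit_mixed_model(fr))
  expect_false(inherits(fit$model, "lm"))
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  sd_int <- vc$sdcor[vc$grp == "district" & vc$var1 == "(Intercept)" &
                       is.na(vc$var2)]
  expect_lt(abs(sd_int - 20) / 20, 0.30)
})

test_that("percent-change conversion matches independent arithmetic on the fit", {
  cfg <- model_config(seed = 8, n_districts = 25)
  rec <- simulate_scenario(cfg)$records
  fr <- build_frame(rec)
  fit <- fit_mixed_model(fr)
  pc <- percent_change(fit, fr)
  # oracle: recompute 100*(b +/- 1.96 se)/mean from the fitted object itself
  b <- lme4::fixef(fit$model)[["covid_period"]]
  se <- sqrt(as.matrix(vcov(fit$model))["covid_period", "covid_period"])
  cf <- fr[fr$covid_period == 1, ]
  cf$covid_period <- 0
  em <- mean(predict(fit$model, newdata = cf, re.form = NULL))
  expect_equal(pc$coefficient, b)
  expect_equal(pc$expected_mean, em)
  expect_equal(pc$pct_change, 100 * b / em)
  expect_equal(pc$ci_low, 100 * (b - 1.96 * se) / em)
  expect_equal(pc$ci_high, 100 * (b + 1.96 * se) / em)
  expect_true(pc$ci_low <= pc$pct_change & pc$pct_change <= pc$ci_high)
  # the district-aggregated alternative estimator is in the same ballpark
  expect_lt(abs(pc$alt_pct - pc$pct_change), 2)
})

test_that("a uniform -15% shock is recovered by the period estimate", {
  cfg <- model_config(seed = 9)
  rec <- simulate_scenario(cfg)$records
  fr <- build_frame(rec)
  pc <- percent_change(fit_mixed_model(fr), fr)
  expect_gt(pc$pct_change, -18)
  expect_lt(pc$pct_change, -12)
})

test_that("pure seasonality without a shock is not mistaken for one", {
  cfg <- scenario_config(n_districts = 40, services = "ANC1",
                         shock = list(ANC1 = 0), annual_growth = 0,
                         completeness_mean = 1, outlier_rate = 0,
                         missing_rate = 0, seed = 10)
  rec <- simulate_scenario(cfg)$records
  fr <- build_frame(rec)
  pc <- percent_change(fit_mixed_model(fr), fr)
  expect_lt(abs(pc$pct_change), 2)
})

test_that("monthly estimates average to the period estimate within 2 points", {
  cfg <- model_config(seed = 12, shock = shock_profile(-0.2, 0))
  rec <- simulate_scenario(cfg)$records
  frp <- build_frame(rec, mode = "period")
  frm <- build_frame(rec, mode = "monthly")
  pcp <- percent_change(fit_mixed_model(frp), frp)
  pcm <- percent_change(fit_mixed_model(frm), frm)
  expect_equal(nrow(pcm), 10)
  expect_lt(abs(mean(pcm$pct_change) - pcp$pct_change), 2)
})

test_that("area strata with different shocks order correctly", {
  # craft: rural districts get an extra -10% in COVID months, urban -5%
  cfg <- scenario_config(n_districts = 40, services = "ANC1",
                         shock = list(ANC1 = 0), completeness_mean = 1,
                         outlier_rate = 0, missing_rate = 0, seed = 13)
  rec <- simulate_scenario(cfg)$records
  covid <- rec$period >= 202003
  rec$value[covid & rec$area_type == "rural"] <-
    round(rec$value[covid & rec$area_type == "rural"] * 0.90)
  rec$value[covid & rec$area_type == "urban"] <-
    round(rec$value[covid & rec$area_type == "urban"] * 0.95)
  rec <- rec[rec$area_type != "mixed", ]
  est <- suppressMessages(stratified_estimates(rec))
  expect_setequal(unique(est$stratum), c("urban", "rural"))
  expect_lt(est$pct_change[est$stratum == "rural"],
            est$pct_change[est$stratum == "urban"])
  # a stratum with < 2 districts is skipped with a warning
  one_urban <- rec[rec$area_type == "rural" | rec$district_id == "D001", ]
  expect_warning(stratified_estimates(one_urban), "< 2 districts")
})
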