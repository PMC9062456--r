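# OWID ingestion, monthly metrics, pooled association

owid_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

test_that("OWID loader round-trips, fills gaps and parses by name", {
  days <- as.Date("2020-03-01") + 0:9
  df <- data.frame(location = "Atlantis", date = as.character(days),
                   new_cases = 1:10, stringency_index = 50,
                   population = 1e6)
  s <- load_owid(owid_csv(df))
  expect_equal(nrow(s), 10)
  expect_equal(s$new_cases, 1:10)
  expect_equal(s$stringency_index, rep(50, 10))
  # 3-day gap forward-filled
  df2 <- df
  df2$stringency_index[4:6] <- NA
  s2 <- load_owid(owid_csv(df2))
  expect_equal(s2$stringency_index, rep(50, 10))
  # gap longer than the limit stays missing
  df3 <- df
  df3$stringency_index[2:10] <- NA
  s3 <- load_owid(owid_csv(df3))
  expect_equal(sum(is.na(s3$stringency_index)), 2)  # days 9-10 beyond 7 days
  # shuffled column order parses by name; extra columns ignored
  df4 <- df[, c(5, 3, 1, 2, 4)]
  df4$iso_code <- "ATL"
  expect_equal(load_owid(owid_csv(df4))$new_cases, 1:10)
  # negative cases clamp to missing with a warning
  df5 <- df
  df5$new_cases[3] <- -7
  expect_warning(s5 <- load_owid(owid_csv(df5)), "negative")
  expect_true(is.na(s5$new_cases[3]))
})

test_that("monthly metrics compute means, sums and cumulative incidence", {
  mar <- as.Date("2020-03-01") + 0:30
  rest <- seq(as.Date("2020-04-01"), as.Date("2020-12-31"), by = "day")
  df <- data.frame(location = "Atlantis",
                   date = as.character(c(mar, rest)),
                   new_cases = c(rep(10, 31), rep(1, length(rest))),
                   stringency_index = c(rep(0, 10), rep(62, 21),
                                        rep(30, length(rest))),
                   population = 1e6)
  s <- load_owid(owid_csv(df))
  m <- monthly_metrics(s)
  march <- m$monthly[m$monthly$period == 202003, ]
  expect_equal(march$mean_stringency, (10 * 0 + 21 * 62) / 31)
  expect_equal(round_half_out(march$mean_stringency, 1), 42.0)
  expect_equal(march$new_cases, 310)
  # constant stringency -> every monthly mean equals it
  expect_true(all(m$monthly$mean_stringency[m$monthly$period > 202003] == 30))
  # 310 + 275 days x 1 case; per 100k of 1m population
  expect_equal(m$cumulative$cum_cases_per_100k,
               (310 + length(rest)) / 1e6 * 1e5)
  # order invariance within month
  s_shuf <- s[sample(nrow(s)), ]
  class(s_shuf) <- class(s)
  m2 <- monthly_metrics(s_shuf)
  expect_equal(m2$monthly, m$monthly)
  # zero population errors
  s$population[1] <- 0
  expect_error(monthly_metrics(s), "population")
})

association_data <- function(noise_sd = 0, seed = 1,
                             effect = c(stringency = -0.3)) {
  set.seed(seed)
  countries <- sprintf("C%02d", 1:11)
  grid <- expand.grid(country = countries, period = period_seq(202003, 202012),
                      stringsAsFactors = FALSE)
  grid$service <- "OPD"
  grid$stringency <- round(runif(nrow(grid), 10, 90), 1)
  grid$monthly_cases <- round(runif(nrow(grid), 0, 5000))
  pop <- stats::setNames(round(runif(11, 5e6, 9e7)), countries)
  den <- stats::setNames(round(runif(11, 10, 500)), countries)
  grid$population <- pop[grid$country]
  grid$pop_density <- den[grid$country]
  grid$pct_change <- effect[["stringency"]] * grid$stringency +
    0.05 * grid$monthly_cases / 1000 + rnorm(nrow(grid), 0, noise_sd)
  grid
}

test_that("a planted stringency effect is recovered to 3 decimals at zero noise", {
  d <- association_data(noise_sd = 0)
  res <- suppressWarnings(fit_association(d))
  b <- res$estimate[res$term == "stringency"]
  expect_equal(b, -0.300, tolerance = 1e-3 / 0.3)
  expect_equal(res$marker[res$term == "stringency"], "***")
})

test_that("permuted stringency gives a null coefficient in >= 90% of runs", {
  d0 <- association_data(noise_sd = 2, seed = 3,
                         effect = c(stringency = 0))
  covers <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    d <- d0
    d$stringency <- sample(d$stringency)
    res <- suppressWarnings(fit_association(d))
    i <- which(res$term == "stringency")
    ci <- res$estimate[i] + c(-1.96, 1.96) * res$se[i]
    ci[1] <= 0 && ci[2] >= 0
  }, logical(1))
  expect_gte(mean(covers), 0.90)
})

test_that("degenerate covariates are dropped or rejected by name", {
  d <- association_data(noise_sd = 1)
  d$pop_density <- 7
  expect_warning(res <- fit_association(d), "pop_density")
  expect_false("pop_density" %in% res$term)
  d2 <- d
  d2$stringency <- 1; d2$monthly_cases <- 0; d2$population <- 1e6
  expect_error(suppressWarnings(fit_association(d2)), "zero variance")
  expect_error(fit_association(d[d$country == "C01", ]), ">= 2 countries")
})
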