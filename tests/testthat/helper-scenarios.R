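# Shared scenario builders for the test suite.

# exact world: no noise, no shock, flat trend, flat seasonality, one level
flat_config <- function(n_districts = 3, services = "ANC1", baseline = 100,
                        months = c(201701, 202012), seed = 1, ...) {
  args <- list(
    n_districts = n_districts, months = months, services = services,
    baseline_level = stats::setNames(rep(baseline, length(services)),
                                     services),
    district_cv = 0, annual_growth = 0, trend_sd = 0,
    seasonal_factors = matrix(1, 12, length(services),
                              dimnames = list(NULL, services)),
    shock = stats::setNames(rep(list(0), length(services)), services),
    completeness_mean = 1, outlier_rate = 0, missing_rate = 0,
    noise = "none", seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scenario_config, args)
}

# model-isolation world: Poisson noise, perfect reporting, one service
model_config <- function(seed, n_districts = 60, shock = -0.15,
                         service = "ANC1", ...) {
  scenario_config(
    n_districts = n_districts, services = service,
    shock = stats::setNames(list(shock), service),
    completeness_mean = 1, outlier_rate = 0, missing_rate = 0,
    seed = seed, ...)
}

# hand-built service records: one district-service grid with given values
make_records <- function(values, district_id = "D001", region = "R01",
                         area_type = "rural", population = 100000,
                         periods = NULL, service = "ANC1",
                         expected = 20, actual = 20) {
  if (is.null(periods)) periods <- period_seq(201701, 201712)[seq_along(values)]
  data.frame(district_id = district_id, region = region,
             area_type = area_type, population = population,
             period = periods, service = service, value = values,
             reports_expected = expected, reports_actual = actual,
             stringsAsFactors = FALSE)
}

# brute-force modified Z-score oracle built from sorted values only
oracle_mzscore <- function(x, constant = 0.6745) {
  v <- x[!is.na(x)]
  med_sorted <- function(s) {
    s <- sort(s); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  med <- med_sorted(v)
  devs <- abs(v - med)
  mad0 <- med_sorted(devs)
  denom <- if (mad0 > 0) mad0 else mean(devs)
  if (denom == 0) return(ifelse(is.na(x), NA_real_, 0))
  constant * abs(x - med) / denom
}
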