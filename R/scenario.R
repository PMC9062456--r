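# Synthetic DHIS2-style district-month scenario generator.
#
# The generator states a world with known ground truth: log-linear service
# trends, calendar-month seasonality, district heterogeneity in level and
# trend, a facility reporting process with per-district-month completeness,
# injected missingness and extreme outliers, and a COVID shock (step plus
# partial rebound) from March 2020. Every downstream stage is tested against
# this world.

#' Default service codes
#'
#' The nine routinely reported services tracked by the pipeline: antenatal
#' care (first and fourth visit), institutional delivery, caesarean section,
#' pentavalent vaccination (doses 1 and 3), measles vaccination, outpatient
#' consultations and inpatient admissions.
#'
#' @return character vector of service codes.
#' @export
default_services <- function() {
  c("ANC1", "ANC4", "DELIV", "CSEC", "PENTA1", "PENTA3", "MEASLES",
    "OPD", "IPD")
}

# mild cosine seasonality, normalised so the 12 factors multiply to 1
seasonal_profile <- function(amplitude = 0.10, peak_month = 7) {
  s <- 1 + amplitude * cos(2 * pi * ((1:12) - peak_month) / 12)
  s / prod(s)^(1 / 12)
}

#' COVID shock profile over March--December 2020
#'
#' Linear interpolation from an initial drop to a final level across the ten
#' COVID months, emulating the observed pattern of a sharp early reduction
#' followed by a (possibly partial) rebound.
#'
#' @param initial relative change in March 2020 (e.g. `-0.25` for -25\%).
#' @param final relative change in December 2020 (default full rebound, 0).
#' @param n_months number of COVID months (default 10).
#' @return numeric vector of per-month multiplicative changes, each > -1.
#' @export
shock_profile <- function(initial, final = 0, n_months = 10) {
  stopifnot(initial > -1, final > -1, n_months >= 1)
  if (n_months == 1) return(initial)
  seq(initial, final, length.out = n_months)
}

#' Build a synthetic HMIS scenario configuration
#'
#' Defines the generating process for a multi-district, multi-service
#' monthly count dataset with a facility reporting overlay. Defaults emulate
#' the kind of national DHIS2 extract analysed in multi-country service
#' continuity assessments: 2017--2020, nine services, high (about 95\%)
#' reporting completeness, rare missing values and extreme outliers, and a
#' COVID-period shock that is largest for outpatient and inpatient care.
#'
#' @param n_districts number of districts.
#' @param months inclusive `c(start, end)` period range as YYYYMM integers.
#' @param services character vector of service codes.
#' @param baseline_level named per-service mean monthly district count.
#' @param district_cv coefficient of variation of the district-level
#'   multiplier on the baseline (log-normal).
#' @param annual_growth named per-service relative trend per year.
#' @param trend_sd between-district SD of the annual growth rate.
#' @param seasonal_factors 12 x n_services matrix of multiplicative
#'   calendar-month factors; each column must multiply to 1 (within 1e-9).
#' @param shock named list of per-service COVID-month multipliers (fractions,
#'   each > -1), one value per COVID month; `NULL` entries mean no shock.
#' @param covid_start,covid_end COVID window as YYYYMM (March--December 2020).
#' @param completeness_mean,completeness_conc mean and concentration of the
#'   Beta distribution of per-district-month facility reporting completeness.
#' @param completeness_floor lower floor on completeness (avoids division
#'   blow-ups in the adjustment step).
#' @param q_nonreporting relative service volume of a non-reporting facility
#'   versus a reporting one, in \[0, 1\].
#' @param outlier_rate,missing_rate per-record probabilities of an injected
#'   extreme outlier (x10--x50) and of a missing value.
#' @param noise count-noise family per service: `"poisson"`, `"gaussian"`
#'   (rounded, SD = `gaussian_cv` x mean; used for large-count services) or
#'   `"none"`. A single value is recycled.
#' @param gaussian_cv coefficient of variation for the Gaussian noise mode.
#' @param facilities_mean mean number of reporting facilities per district.
#' @param n_regions number of first-level administrative regions.
#' @param area_probs named probabilities of urban / rural / mixed districts.
#' @param population_mean mean district population.
#' @param seed integer RNG seed; identical (config, seed) pairs give
#'   byte-identical output.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(n_districts = 60,
                            months = c(201701, 202012),
                            services = default_services(),
                            baseline_level = NULL,
                            district_cv = 0.40,
                            annual_growth = NULL,
                            trend_sd = 0.01,
                            seasonal_factors = NULL,
                            shock = NULL,
                            covid_start = 202003,
                            covid_end = 202012,
                            completeness_mean = 0.95,
                            completeness_conc = 40,
                            completeness_floor = 0.05,
                            q_nonreporting = 0.25,
                            outlier_rate = 0.005,
                            missing_rate = 0.002,
                            noise = "poisson",
                            gaussian_cv = 0.05,
                            facilities_mean = 20,
                            n_regions = 4,
                            area_probs = c(urban = 0.3, rural = 0.5,
                                           mixed = 0.2),
                            population_mean = 150000,
                            seed = 1) {
  stopifnot(n_districts >= 1, length(months) == 2)
  if (!is_period(months[1]) || !is_period(months[2]) || months[1] > months[2])
    stop("invalid period range: ", months[1], "-", months[2])
  services <- as.character(services)

  defaults_level <- c(ANC1 = 400, ANC4 = 250, DELIV = 300, CSEC = 30,
                      PENTA1 = 350, PENTA3 = 320, MEASLES = 300,
                      OPD = 8000, IPD = 500)
  defaults_growth <- stats::setNames(rep(0.03, length(services)), services)
  if (is.null(baseline_level))
    baseline_level <- ifelse(services %in% names(defaults_level),
                             defaults_level[services], 200)
  baseline_level <- fill_named(baseline_level, services, 200)
  annual_growth <- fill_named(annual_growth %||% defaults_growth, services, 0.03)

  if (is.null(seasonal_factors)) {
    seasonal_factors <- vapply(seq_along(services), function(i)
      seasonal_profile(0.10, peak_month = 3 + (i %% 4)), numeric(12))
    colnames(seasonal_factors) <- services
  }
  seasonal_factors <- as.matrix(seasonal_factors)
  if (nrow(seasonal_factors) != 12 || ncol(seasonal_factors) != length(services))
    stop("seasonal_factors must be a 12 x n_services matrix")
  if (is.null(colnames(seasonal_factors))) colnames(seasonal_factors) <- services
  prods <- apply(seasonal_factors, 2, prod)
  if (any(abs(prods - 1) > 1e-9))
    stop("seasonal_factors must multiply to 1 per service (within 1e-9)")

  covid_months <- period_seq(covid_start, covid_end)
  n_cm <- length(covid_months)
  if (is.null(shock)) {
    shock <- list(ANC1 = shock_profile(-0.05), ANC4 = shock_profile(-0.08),
                  DELIV = shock_profile(-0.05), CSEC = shock_profile(-0.05),
                  PENTA1 = shock_profile(-0.08), PENTA3 = shock_profile(-0.08),
                  MEASLES = shock_profile(-0.08), OPD = shock_profile(-0.25),
                  IPD = shock_profile(-0.25, final = -0.10))
    shock <- shock[intersect(names(shock), services)]
  }
  shock <- lapply(shock, function(v) {
    if (length(v) == 1) v <- rep(v, n_cm)
    if (length(v) != n_cm)
      stop("each shock profile needs ", n_cm, " values (one per COVID month)")
    if (any(v <= -1)) stop("shock multipliers must be > -1")
    v
  })
  if (!all(names(shock) %in% services))
    stop("shock names must be service codes")

  rates <- c(completeness_mean = completeness_mean,
             q_nonreporting = q_nonreporting,
             outlier_rate = outlier_rate, missing_rate = missing_rate,
             completeness_floor = completeness_floor)
  if (any(rates < 0 | rates > 1))
    stop("rates/probabilities must lie in [0,1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  default_noise <- identical(noise, "poisson")
  noise <- fill_named(noise, services, noise[[1]])
  # large-count services get rounded-Gaussian noise by default
  if (default_noise && "OPD" %in% services) noise["OPD"] <- "gaussian"
  if (!all(noise %in% c("poisson", "gaussian", "none")))
    stop("noise must be 'poisson', 'gaussian' or 'none'")

  cfg <- list(n_districts = as.integer(n_districts), months = months,
              services = services, baseline_level = baseline_level,
              district_cv = district_cv, annual_growth = annual_growth,
              trend_sd = trend_sd, seasonal_factors = seasonal_factors,
              shock = shock, covid_start = covid_start, covid_end = covid_end,
              covid_months = covid_months,
              completeness_mean = completeness_mean,
              completeness_conc = completeness_conc,
              completeness_floor = completeness_floor,
              q_nonreporting = q_nonreporting,
              outlier_rate = outlier_rate, missing_rate = missing_rate,
              noise = noise, gaussian_cv = gaussian_cv,
              facilities_mean = facilities_mean, n_regions = n_regions,
              area_probs = area_probs, population_mean = population_mean,
              seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

# recycle/complete a possibly-named vector over the service list
fill_named <- function(x, services, default) {
  out <- stats::setNames(rep(default, length(services)), services)
  if (is.null(x)) return(out)
  if (is.null(names(x))) {
    if (length(x) == 1) out[] <- x
    else if (length(x) == length(services)) out[] <- x
    else stop("unnamed per-service vector has wrong length")
  } else {
    bad <- setdiff(names(x), services)
    if (length(bad)) stop("unknown service(s): ", paste(bad, collapse = ", "))
    out[names(x)] <- x
  }
  out
}

#' District metadata table for a scenario
#'
#' Deterministic under the scenario seed: region assignment, urban/rural/mixed
#' type, population and expected number of reporting facilities per district.
#'
#' @param config a [scenario_config()].
#' @return data.frame with one row per district.
#' @export
district_table <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed * 2L + 11L, {
    n <- config$n_districts
    area <- sample(names(config$area_probs), n, replace = TRUE,
                   prob = config$area_probs)
    # guarantee both urban and rural present when n allows stratified fits
    if (n >= 4) { area[1] <- "urban"; area[2] <- "rural" }
    data.frame(
      district_id = sprintf("D%03d", seq_len(n)),
      region = sprintf("R%02d", rep_len(seq_len(config$n_regions), n)),
      area_type = area,
      population = round(stats::rlnorm(n, log(config$population_mean), 0.5)),
      n_facilities = pmax(1L, stats::rpois(n, config$facilities_mean)),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate ground-truth district-month service counts
#'
#' Expected count for district j, month t, service s is
#' `B_js * (1 + g_js)^(years since start) * S_s[month] * (1 + shock_st)`,
#' where `B_js` is the district baseline (log-normal around the service
#' baseline), `g_js` the district growth rate, `S_s` the seasonal factor and
#' `shock_st` the configured COVID-month change. The realised `true_count` is
#' drawn from the configured noise family around that mean.
#'
#' @param config a [scenario_config()].
#' @return data.frame of truth records (`district_id`, `period`, `service`,
#'   `true_count`, `true_shock_pct`, `expected_count`) with the district table
#'   attached as attribute `"districts"` and the config as `"config"`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  districts <- district_table(config)
  periods <- period_seq(config$months[1], config$months[2])
  nS <- length(config$services)
  nD <- config$n_districts

  with_seed(config$seed, {
    # district x service level multipliers; district trend deviations
    sdlog <- sqrt(log(1 + config$district_cv^2))
    lvl <- matrix(stats::rlnorm(nD * nS, -sdlog^2 / 2, sdlog), nD, nS,
                  dimnames = list(districts$district_id, config$services))
    tdev <- stats::rnorm(nD, 0, config$trend_sd)

    grid <- expand.grid(district_id = districts$district_id,
                        period = periods, service = config$services,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    di <- match(grid$district_id, districts$district_id)
    si <- match(grid$service, config$services)
    yrs <- period_diff(grid$period, config$months[1]) / 12
    mon <- period_month(grid$period)

    shock_pct <- numeric(nrow(grid))
    for (s in names(config$shock)) {
      prof <- config$shock[[s]]
      idx <- match(grid$period, config$covid_months)
      sel <- grid$service == s & !is.na(idx)
      shock_pct[sel] <- 100 * prof[idx[sel]]
    }

    mu <- config$baseline_level[si] * lvl[cbind(di, si)] *
      (1 + config$annual_growth[si] + tdev[di])^yrs *
      config$seasonal_factors[cbind(mon, si)] *
      (1 + shock_pct / 100)

    fam <- config$noise[si]
    cnt <- mu
    pois <- fam == "poisson"
    gaus <- fam == "gaussian"
    if (any(pois)) cnt[pois] <- stats::rpois(sum(pois), mu[pois])
    if (any(gaus))
      cnt[gaus] <- pmax(0, round(stats::rnorm(
        sum(gaus), mu[gaus], config$gaussian_cv * mu[gaus])))

    out <- data.frame(grid, true_count = cnt, true_shock_pct = shock_pct,
                      expected_count = mu, stringsAsFactors = FALSE)
    out <- out[order(out$district_id, out$service, out$period), ]
    rownames(out) <- NULL
    attr(out, "districts") <- districts
    attr(out, "config") <- config
    out
  })
}

#' Pass truth through the facility reporting process
#'
#' Draws a per-district-month completeness `c` (scaled Beta, floored), sets
#' the expected/actual facility report counts consistently with it, and
#' observes `reported = round(true_count * c / (c + (1 - c) * q))`, the share
#' of total service volume held by reporting facilities when a non-reporting
#' facility delivers `q` times the volume of a reporting one. Injects missing
#' values and extreme (x10--x50) outliers at the configured rates.
#'
#' @param truth output of [generate_truth()].
#' @param config the same [scenario_config()].
#' @return data.frame of service records in the pipeline input schema
#'   (`district_id`, `region`, `area_type`, `population`, `period`,
#'   `service`, `value`, `reports_expected`, `reports_actual`) plus bookkeeping
#'   columns `injected_outlier` and `injected_missing` used by test harnesses.
#' @export
apply_reporting <- function(truth, config) {
  stopifnot(inherits(config, "scenario_config"))
  q <- config$q_nonreporting
  if (q < 0 || q > 1) stop("q_nonreporting outside [0,1]")
  districts <- attr(truth, "districts")
  if (is.null(districts)) stop("truth lacks its districts attribute")

  with_seed(config$seed + 1L, {
    periods <- sort(unique(truth$period))
    key <- expand.grid(district_id = districts$district_id, period = periods,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    m <- config$completeness_mean
    k <- config$completeness_conc
    craw <- if (m >= 1) rep(1, nrow(key)) else
      stats::rbeta(nrow(key), m * k, (1 - m) * k)
    key$c_target <- pmax(config$completeness_floor, craw)
    di <- match(key$district_id, districts$district_id)
    key$reports_expected <- districts$n_facilities[di]
    key$reports_actual <- pmax(1L, as.integer(
      round(key$c_target * key$reports_expected)))

    i <- match(paste(truth$district_id, truth$period),
               paste(key$district_id, key$period))
    di2 <- match(truth$district_id, districts$district_id)
    cc <- key$reports_actual[i] / key$reports_expected[i]
    value <- round(truth$true_count * cc / (cc + (1 - cc) * q))

    out_mult <- stats::runif(nrow(truth), 10, 50)
    is_out <- stats::runif(nrow(truth)) < config$outlier_rate
    value[is_out] <- round(value[is_out] * out_mult[is_out])
    is_mis <- stats::runif(nrow(truth)) < config$missing_rate & !is_out
    value[is_mis] <- NA_real_

    out <- data.frame(
      district_id = truth$district_id,
      region = districts$region[di2],
      area_type = districts$area_type[di2],
      population = districts$population[di2],
      period = truth$period,
      service = truth$service,
      value = value,
      reports_expected = key$reports_expected[i],
      reports_actual = key$reports_actual[i],
      injected_outlier = is_out,
      injected_missing = is_mis,
      stringsAsFactors = FALSE
    )
    attr(out, "config") <- config
    out
  })
}

#' Simulate a complete scenario
#'
#' Convenience wrapper: [generate_truth()] then [apply_reporting()].
#'
#' @param config a [scenario_config()].
#' @return list with elements `records` (service records) and `truth`.
#' @export
simulate_scenario <- function(config) {
  truth <- generate_truth(config)
  list(records = apply_reporting(truth, config), truth = truth)
}

# ---- dataset i/o -------------------------------------------------------------

hmis_schema <- c("district_id", "region", "area_type", "population",
                 "period", "service", "value",
                 "reports_expected", "reports_actual")

#' Write service records to the pipeline CSV schema
#'
#' Columns `district_id,region,area_type,population,period,service,value,`
#' `reports_expected,reports_actual`; missing values are written as empty
#' fields (never `"0"`). Round-trips losslessly through [read_hmis_csv()].
#'
#' @param records service-record data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hmis_csv <- function(records, path) {
  stopifnot(nrow(records) > 0)
  miss <- setdiff(hmis_schema, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  utils::write.csv(records[hmis_schema], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read service records from the pipeline CSV schema
#'
#' @param path CSV file path (header required, empty string = missing value).
#' @return service-record data.frame.
#' @export
read_hmis_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "", colClasses = c(
                          district_id = "character", region = "character",
                          area_type = "character", service = "character"))
  miss <- setdiff(hmis_schema, names(df))
  if (length(miss)) stop("input lacks columns: ", paste(miss, collapse = ", "))
  df$period <- as.integer(df$period)
  df$value <- as.numeric(df$value)
  df
}

#' Write the ground-truth sidecar CSV
#'
#' @param truth output of [generate_truth()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  cols <- c("district_id", "period", "service", "true_count",
            "true_shock_pct")
  utils::write.csv(truth[cols], path, row.names = FALSE, na = "")
  invisible(path)
}
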