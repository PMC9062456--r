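# OWID-dialect COVID case/stringency ingestion and the pooled association
# between monthly percent change in service utilisation and the government
# response stringency index.

#' Load an OWID-dialect COVID CSV
#'
#' Requires columns `location`, `date`, `new_cases`, `stringency_index`,
#' `population` (any column order; extra columns ignored). Negative case
#' counts are clamped to missing with a warning. Gaps in the stringency
#' index are forward-filled per country for up to `max_ffill` days and left
#' missing beyond that.
#'
#' @param path CSV file path.
#' @param max_ffill maximum forward-fill span in days (default 7).
#' @return data.frame of class `stringency_series` with `country`, `date`,
#'   `new_cases`, `stringency_index`, `population`.
#' @export
load_owid <- function(path, max_ffill = 7) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("location", "date", "new_cases", "stringency_index", "population")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("OWID input lacks columns: ",
                         paste(miss, collapse = ", "))
  date <- as.Date(df$date)
  if (any(is.na(date) & !is.na(df$date))) stop("malformed dates in OWID input")
  out <- data.frame(country = df$location, date = date,
                    new_cases = as.numeric(df$new_cases),
                    stringency_index = as.numeric(df$stringency_index),
                    population = as.numeric(df$population),
                    stringsAsFactors = FALSE)
  neg <- !is.na(out$new_cases) & out$new_cases < 0
  if (any(neg)) {
    warning(sum(neg), " negative new_cases value(s) set to missing")
    out$new_cases[neg] <- NA_real_
  }
  bad_si <- !is.na(out$stringency_index) &
    (out$stringency_index < 0 | out$stringency_index > 100)
  if (any(bad_si)) stop("stringency_index outside [0,100]")
  out <- out[order(out$country, out$date), ]
  if (anyDuplicated(out[c("country", "date")]))
    stop("duplicate (country, date) rows")
  out$stringency_index <- stats::ave(
    seq_len(nrow(out)), out$country,
    FUN = function(i) ffill_limited(out$stringency_index[i],
                                    out$date[i], max_ffill))
  rownames(out) <- NULL
  class(out) <- c("stringency_series", "data.frame")
  out
}

# forward fill y over dates, carrying a value at most `limit` days
ffill_limited <- function(y, dates, limit) {
  last_val <- NA_real_; last_date <- as.Date(NA)
  out <- y
  for (i in seq_along(y)) {
    if (!is.na(y[i])) { last_val <- y[i]; last_date <- dates[i] }
    else if (!is.na(last_val) &&
             as.numeric(dates[i] - last_date) <= limit) out[i] <- last_val
  }
  out
}

#' Monthly stringency/case metrics per country
#'
#' For each country and calendar month in the window: mean of the daily
#' stringency index over the days present and the sum of new cases. Also
#' returns the 2020 cumulative incidence per 100 000 population.
#'
#' @param series a [load_owid()] result.
#' @param window `c(start, end)` YYYYMM window (default March--December
#'   2020).
#' @return list with `monthly` (country, period, mean_stringency,
#'   new_cases) and `cumulative` (country, cum_cases_per_100k for 2020).
#' @export
monthly_metrics <- function(series, window = c(202003, 202012)) {
  stopifnot(inherits(series, "stringency_series"))
  if (any(is.na(series$population) | series$population <= 0))
    stop("population must be positive for cumulative incidence")
  period <- as.integer(format(series$date, "%Y%m"))
  sel <- period >= window[1] & period <= window[2]
  sub <- series[sel, ]
  psub <- period[sel]
  monthly <- stats::aggregate(
    list(mean_stringency = sub$stringency_index),
    by = list(country = sub$country, period = psub),
    FUN = mean, na.rm = TRUE)
  cases <- stats::aggregate(
    list(new_cases = sub$new_cases),
    by = list(country = sub$country, period = psub),
    FUN = function(x) sum(x, na.rm = TRUE))
  monthly <- merge(monthly, cases, by = c("country", "period"))
  monthly <- monthly[order(monthly$country, monthly$period), ]

  y2020 <- period %/% 100 == 2020
  cum <- do.call(rbind, lapply(split(series[y2020, ], series$country[y2020]),
    function(s) data.frame(
      country = s$country[1],
      cum_cases_per_100k = sum(s$new_cases, na.rm = TRUE) /
        s$population[1] * 1e5,
      stringsAsFactors = FALSE)))
  rownames(cum) <- NULL
  rownames(monthly) <- NULL
  list(monthly = monthly, cumulative = cum)
}

#' Pooled association between monthly change and COVID indicators
#'
#' Per service, fits a linear mixed model of the monthly percent change in
#' utilisation on monthly COVID-19 cases (per 1000), the stringency index
#' (percent), total population (per 100 000) and population density, with a
#' country random intercept. Falls back to pooled OLS when the random
#' intercept is inestimable (e.g. zero between-country variance).
#' Zero-variance covariates are dropped with a warning; if all covariates
#' are degenerate an error names them.
#'
#' @param data data.frame with columns `country`, `period`, `service`,
#'   `pct_change`, `monthly_cases`, `stringency`, `population`,
#'   `pop_density`.
#' @return data.frame of class `association_result`: one row per service x
#'   covariate with `estimate`, `se`, `p_value` (normal approximation) and
#'   significance `marker` (`*` p<0.05, `***` p<0.001).
#' @export
fit_association <- function(data) {
  need <- c("country", "period", "service", "pct_change", "monthly_cases",
            "stringency", "population", "pop_density")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("association input lacks columns: ",
                         paste(miss, collapse = ", "))
  if (length(unique(data$country)) < 2)
    stop("need >= 2 countries for the pooled model")
  if (length(unique(data$period)) < 6)
    stop("need >= 6 months for the pooled model")

  data$cases_1000 <- data$monthly_cases / 1000
  data$pop_100k <- data$population / 1e5
  covs <- c(cases_1000 = "monthly COVID-19 cases (in 1000s)",
            stringency = "stringency index (%)",
            pop_100k = "population (in 100000)",
            pop_density = "population density")

  out <- lapply(split(data, data$service), function(d) {
    keep <- names(covs)[vapply(names(covs),
                               function(v) stats::var(d[[v]]) > 0, logical(1))]
    dropped <- setdiff(names(covs), keep)
    if (!length(keep))
      stop("all covariates have zero variance: ",
           paste(names(covs), collapse = ", "))
    if (length(dropped))
      warning("zero-variance covariate(s) dropped: ",
              paste(dropped, collapse = ", "))
    fml <- stats::as.formula(paste("pct_change ~",
                                   paste(keep, collapse = " + ")))
    fit <- tryCatch(suppressWarnings(suppressMessages(
      lme4::lmer(stats::update(fml, . ~ . + (1 | country)), data = d,
                 REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")))),
      error = function(e) NULL)
    if (is.null(fit)) fit <- stats::lm(fml, data = d)
    beta <- if (inherits(fit, "lm")) stats::coef(fit) else lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    rows <- lapply(keep, function(v) {
      b <- beta[[v]]; se <- sqrt(V[v, v])
      p <- 2 * stats::pnorm(-abs(b / se))
      data.frame(service = d$service[1], covariate = covs[[v]],
                 term = v, estimate = b, se = se, p_value = p,
                 marker = if (p < 0.001) "***" else if (p < 0.05) "*" else "",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("association_result", "data.frame")
  res
}
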