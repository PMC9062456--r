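# Mixed-effects interrupted-period estimation of COVID-period changes in
# district-month service counts.
#
# Model (per service, per country): the curated monthly count Y_ij of
# district j is regressed on a linear month index (time trend), calendar
# month factors (seasonality), district population, area type, region and
# COVID-month indicators, with a random intercept and random time slope per
# district. The COVID coefficient is the average absolute change in monthly
# utilisation; dividing by the counterfactual predicted mean (COVID
# indicators forced to zero) turns it into a percent change.

#' Build the model frame for one service
#'
#' @param records curated service records of a single service (uses
#'   `adjusted_value` when present).
#' @param covid_start,covid_end COVID window (YYYYMM), default March to
#'   December 2020.
#' @param mode `"period"` (one whole-period indicator) or `"monthly"` (one
#'   indicator per COVID month).
#' @param min_pre_months minimum number of pre-COVID months required.
#' @return data.frame of class `disruption_frame` with outcome `y`, `time`
#'   (months since series start), `month` (factor, January reference),
#'   `pop` (district population, 100 000s), `area` (urban reference),
#'   `region`, `district` and the COVID indicator column(s); attributes
#'   `covid_cols`, `mode`, `service`.
#' @export
build_frame <- function(records, covid_start = 202003, covid_end = 202012,
                        mode = c("period", "monthly"),
                        min_pre_months = 24) {
  mode <- match.arg(mode)
  svc <- unique(records$service)
  if (length(svc) != 1)
    stop("build_frame expects a single service; got: ",
         paste(svc, collapse = ", "))
  origin <- min(records$period)
  covid_months <- period_seq(covid_start, covid_end)
  pre <- sort(unique(records$period[records$period < covid_start]))
  if (!length(pre)) stop("all data fall in the COVID window")
  if (length(pre) < min_pre_months)
    stop("need >= ", min_pre_months, " pre-COVID months, have ", length(pre))
  if (!any(records$period %in% covid_months))
    stop("no data in the COVID window")

  val <- if ("adjusted_value" %in% names(records)) records$adjusted_value
         else records$value
  fr <- data.frame(
    y = val,
    time = period_diff(records$period, origin),
    month = factor(period_month(records$period), levels = 1:12),
    pop = records$population / 1e5,
    area = factor(records$area_type, levels = c("urban", "rural", "mixed")),
    region = factor(records$region),
    district = factor(records$district_id),
    period = records$period,
    stringsAsFactors = FALSE
  )
  fr$area <- droplevels(fr$area)
  if (mode == "period") {
    fr$covid_period <- as.integer(records$period %in% covid_months)
    covid_cols <- "covid_period"
  } else {
    covid_cols <- sprintf("covid_m%02d", period_month(covid_months))
    for (i in seq_along(covid_months))
      fr[[covid_cols[i]]] <- as.integer(records$period == covid_months[i])
  }
  fr <- fr[!is.na(fr$y), , drop = FALSE]
  structure(fr, covid_cols = covid_cols, mode = mode, service = svc,
            covid_months = covid_months,
            class = c("disruption_frame", "data.frame"))
}

frame_formula <- function(frame, random) {
  covid_cols <- attr(frame, "covid_cols")
  terms <- c("time")
  if (nlevels(droplevels(frame$month)) > 1) terms <- c(terms, "month")
  if (stats::var(frame$pop) > 0) terms <- c(terms, "pop")
  if (nlevels(droplevels(frame$area)) > 1) terms <- c(terms, "area")
  if (nlevels(droplevels(frame$region)) > 1) terms <- c(terms, "region")
  terms <- c(terms, covid_cols)
  rhs <- paste(terms, collapse = " + ")
  if (!is.null(random)) rhs <- paste(rhs, "+", random)
  stats::as.formula(paste("y ~", rhs))
}

lmer_ok <- function(fit) {
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  !length(msgs) || !any(grepl("failed to converge", msgs, ignore.case = TRUE))
}

#' Fit the mixed-effects disruption model
#'
#' Gaussian linear mixed model (REML) with random intercept and random time
#' slope per district. On failure or non-convergence the model falls back,
#' with a message, to a random intercept only and finally to pooled OLS.
#' Collinear blocks (single-level area/region, zero-variance population) are
#' dropped from the fixed effects before fitting.
#'
#' @param frame a [build_frame()] result.
#' @return object of class `disruption_fit`: list with the fitted `model`,
#'   the `variant` used (`"slope"`, `"intercept"`, `"ols"`) and frame
#'   metadata.
#' @export
fit_mixed_model <- function(frame) {
  stopifnot(inherits(frame, "disruption_frame"))
  if (nlevels(droplevels(frame$district)) < 2)
    stop("need >= 2 districts to fit the mixed model")
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- NULL; variant <- NULL
  for (cand in list(c("slope", "(1 + time | district)"),
                    c("intercept", "(1 | district)"))) {
    f <- tryCatch(suppressWarnings(
      lme4::lmer(frame_formula(frame, cand[2]), data = frame, REML = TRUE,
                 control = ctrl)),
      error = function(e) NULL)
    if (!is.null(f) && lmer_ok(f)) { fit <- f; variant <- cand[1]; break }
    message("disruption model: ", cand[1],
            "-level random effects failed, falling back")
  }
  if (is.null(fit)) {
    fit <- stats::lm(frame_formula(frame, NULL), data = frame)
    variant <- "ols"
  }
  structure(list(model = fit, variant = variant,
                 covid_cols = attr(frame, "covid_cols"),
                 mode = attr(frame, "mode"),
                 service = attr(frame, "service"),
                 covid_months = attr(frame, "covid_months")),
            class = "disruption_fit")
}

fit_coefs <- function(fit) {
  m <- fit$model
  if (inherits(m, "lm")) list(beta = stats::coef(m), V = stats::vcov(m))
  else list(beta = lme4::fixef(m), V = as.matrix(stats::vcov(m)))
}

predict_frame <- function(fit, newdata) {
  m <- fit$model
  if (inherits(m, "lm")) stats::predict(m, newdata = newdata)
  else stats::predict(m, newdata = newdata, re.form = NULL)
}

#' Convert COVID coefficients into percent-change estimates
#'
#' The counterfactual expected utilisation is the mean model prediction over
#' the COVID rows (of the stratum) with all COVID indicators forced to zero,
#' keeping district random effects. Percent change = 100 x coefficient /
#' counterfactual mean; the 95\% CI scales the coefficient's normal CI
#' (+/- 1.96 SE) by the same denominator (denominator treated as fixed).
#' Also reports the alternative estimator that aggregates predicted changes
#' across districts (`alt_pct`).
#'
#' @param fit a [fit_mixed_model()] result.
#' @param frame the frame it was fitted on.
#' @param stratum optional label and row filter: `NULL` for national or a
#'   named list like `list(area = "rural")`.
#' @return data.frame of disruption estimates: one row per COVID month in
#'   monthly mode, one row for the whole period in period mode, with
#'   `coefficient`, `expected_mean`, `pct_change`, `ci_low`, `ci_high`,
#'   `alt_pct`, `model_variant`.
#' @export
percent_change <- function(fit, frame, stratum = NULL) {
  stopifnot(inherits(fit, "disruption_fit"),
            inherits(frame, "disruption_frame"))
  covid_cols <- fit$covid_cols
  in_covid <- rowSums(frame[, covid_cols, drop = FALSE]) > 0
  keep <- in_covid
  label <- "national"
  if (!is.null(stratum)) {
    for (nm in names(stratum)) keep <- keep & frame[[nm]] == stratum[[nm]]
    label <- paste(unlist(stratum), collapse = ":")
  }
  if (!any(keep)) stop("stratum has no COVID rows")
  rows <- frame[keep, , drop = FALSE]
  cf <- rows
  cf[covid_cols] <- 0
  pred_cf <- predict_frame(fit, cf)
  pred_obs <- predict_frame(fit, rows)
  co <- fit_coefs(fit)

  one <- function(col, sel) {
    em <- mean(pred_cf[sel])
    if (!is.finite(em) || em <= 0)
      stop("counterfactual expected mean is not positive; percent change undefined")
    if (!col %in% names(co$beta)) stop("coefficient missing: ", col)
    b <- co$beta[[col]]
    se <- sqrt(co$V[col, col])
    alt <- 100 * (sum(pred_obs[sel]) - sum(pred_cf[sel])) / sum(pred_cf[sel])
    data.frame(service = fit$service, stratum = label,
               coefficient = b, expected_mean = em,
               pct_change = 100 * b / em,
               ci_low = 100 * (b - 1.96 * se) / em,
               ci_high = 100 * (b + 1.96 * se) / em,
               alt_pct = alt, model_variant = fit$variant,
               stringsAsFactors = FALSE)
  }

  if (fit$mode == "period") {
    out <- one("covid_period", rep(TRUE, nrow(rows)))
    out$period <- "202003-202012"
  } else {
    out <- do.call(rbind, lapply(seq_along(covid_cols), function(i) {
      sel <- rows[[covid_cols[i]]] > 0
      if (!any(sel)) return(NULL)
      r <- one(covid_cols[i], sel)
      r$period <- as.character(fit$covid_months[i])
      r
    }))
  }
  rownames(out) <- NULL
  out[c("service", "stratum", "period", "coefficient", "expected_mean",
        "pct_change", "ci_low", "ci_high", "alt_pct", "model_variant")]
}

#' Estimate disruption for every service in a curated dataset
#'
#' Builds the frame, fits the mixed model and converts coefficients to
#' percent changes, per service.
#'
#' @param records curated service records (multiple services allowed).
#' @param mode `"period"` or `"monthly"`.
#' @param covid_start,covid_end COVID window.
#' @param min_pre_months see [build_frame()].
#' @return data.frame of disruption estimates.
#' @export
estimate_disruption <- function(records, mode = "period",
                                covid_start = 202003, covid_end = 202012,
                                min_pre_months = 24) {
  do.call(rbind, lapply(split(records, records$service), function(r) {
    fr <- build_frame(r, covid_start, covid_end, mode = mode,
                      min_pre_months = min_pre_months)
    percent_change(fit_mixed_model(fr), fr)
  })) -> out
  rownames(out) <- NULL
  out
}

#' Stratified disruption estimates by area type
#'
#' Refits the model within each stratum (urban / rural / mixed districts).
#' Strata with fewer than two districts are skipped with a warning.
#'
#' @param records curated service records.
#' @param strata column to stratify on (default `area_type`).
#' @param mode,covid_start,covid_end,min_pre_months passed through.
#' @return data.frame of per-stratum estimates.
#' @export
stratified_estimates <- function(records, strata = "area_type",
                                 mode = "period", covid_start = 202003,
                                 covid_end = 202012, min_pre_months = 24) {
  out <- list()
  for (lev in sort(unique(records[[strata]]))) {
    sub <- records[records[[strata]] == lev, , drop = FALSE]
    if (length(unique(sub$district_id)) < 2) {
      warning("stratum '", lev, "' has < 2 districts: skipped")
      next
    }
    est <- do.call(rbind, lapply(split(sub, sub$service), function(r) {
      fr <- build_frame(r, covid_start, covid_end, mode = mode,
                        min_pre_months = min_pre_months)
      percent_change(fit_mixed_model(fr), fr)
    }))
    est$stratum <- lev
    out[[lev]] <- est
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
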