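# Data-quality assessment: facility reporting completeness, missing values,
# and extreme outliers via the modified Z-score.

#' Reporting completeness of a set of service records
#'
#' Completeness of a district-month is `reports_actual / reports_expected`
#' taken from the reporting-form metadata. Rows are de-duplicated on
#' (district, period, expected, actual) before summing, so the summary is
#' invariant to replicating the same form metadata across services.
#'
#' @param records service-record data.frame.
#' @param year calendar year (e.g. 2020).
#' @return object of class `completeness_summary`: a list with
#'   `national_pct` (sum actual / sum expected x 100), `pct_districts_gt90`
#'   (share of districts whose annual completeness exceeds 0.90, strictly),
#'   `n_district_months_below75` and their display-rounded versions.
#' @export
completeness_summary <- function(records, year) {
  rec <- records[period_year(records$period) == year, ]
  if (!nrow(rec)) stop("no records in year ", year)
  meta <- unique(rec[c("district_id", "period", "reports_expected",
                       "reports_actual")])
  if (sum(meta$reports_expected) == 0)
    stop("completeness undefined: reports_expected all zero in ", year)
  national <- 100 * sum(meta$reports_actual) / sum(meta$reports_expected)

  by_d <- stats::aggregate(
    cbind(reports_actual, reports_expected) ~ district_id, meta, sum)
  ann_c <- by_d$reports_actual / by_d$reports_expected
  pct_gt90 <- 100 * mean(ann_c > 0.90)

  cdm <- meta$reports_actual / meta$reports_expected
  below75 <- sum(cdm < 0.75)

  structure(list(year = year,
                 national_pct = national,
                 pct_districts_gt90 = pct_gt90,
                 n_district_months_below75 = below75,
                 national_pct_rounded = round_half_out(national),
                 pct_districts_gt90_rounded = round_half_out(pct_gt90)),
            class = "completeness_summary")
}

#' @export
print.completeness_summary <- function(x, ...) {
  cat(sprintf(
    "Completeness %d: national %.1f%% | districts >90%%: %.1f%% | district-months <75%%: %d\n",
    x$year, x$national_pct, x$pct_districts_gt90,
    x$n_district_months_below75))
  invisible(x)
}

quality_flag <- function(district_id, period, service, kind,
                         score = NA_real_, threshold = NA_real_) {
  data.frame(district_id = district_id, period = period, service = service,
             kind = kind, score = score, threshold = threshold,
             stringsAsFactors = FALSE)
}

empty_flags <- function() {
  quality_flag(character(0), integer(0), character(0), character(0),
               numeric(0), numeric(0))
}

#' Flag district-months with low facility reporting completeness
#'
#' "Below 75\%" is read strictly: `c < low` is flagged, `c == low` is not.
#' The moderate band (`low <= c <= moderate`) appears only in summaries.
#'
#' @param records service-record data.frame.
#' @param low low-completeness threshold (default 0.75).
#' @param moderate moderate threshold used for summaries (default 0.90).
#' @return data.frame of flags (`kind == "low_completeness"`), one per
#'   district-month-service with completeness below `low`.
#' @export
flag_low_completeness <- function(records, low = 0.75, moderate = 0.90) {
  stopifnot(low > 0, low <= 1, moderate > 0, moderate <= 1)
  cc <- records$reports_actual / records$reports_expected
  sel <- !is.na(cc) & cc < low
  if (!any(sel)) return(empty_flags())
  quality_flag(records$district_id[sel], records$period[sel],
               records$service[sel], "low_completeness",
               score = cc[sel], threshold = low)
}

#' Modified Z-scores of a monthly series
#'
#' `score_i = constant * |x_i - median(x)| / MAD(x)` with the raw (unscaled)
#' median absolute deviation. When the MAD is zero the mean absolute
#' deviation from the median is used instead; if that is also zero all
#' scores are zero.
#'
#' @param x numeric vector (missing values allowed; their score is `NA`).
#' @param constant normalising constant (default 0.6745, making the score
#'   comparable to an SD unit under normality).
#' @return numeric vector of scores, same length as `x`.
#' @export
modified_zscore <- function(x, constant = 0.6745) {
  med <- stats::median(x, na.rm = TRUE)
  dev <- abs(x - med)
  mad0 <- stats::median(dev, na.rm = TRUE)
  denom <- if (mad0 > 0) mad0 else mean(dev, na.rm = TRUE)
  if (is.na(denom) || denom == 0) return(ifelse(is.na(x), NA_real_, 0))
  constant * dev / denom
}

#' Detect extreme outliers in one district-service calendar year
#'
#' Flags months whose modified Z-score exceeds `cutoff` (strictly), i.e.
#' values more than `cutoff` SD-equivalents from the annual median.
#'
#' @param series numeric vector of monthly values (typically 12) for one
#'   district, service and calendar year.
#' @param cutoff score threshold (default 5).
#' @param constant see [modified_zscore()]; set to 1 to use the raw
#'   MAD-denominated score.
#' @param district_id,period,service optional identifiers attached to flags;
#'   `period` must have the length of `series` when given.
#' @return data.frame of flags (`kind == "outlier"`) carrying the score and
#'   threshold; zero rows when nothing exceeds the cutoff.
#' @export
detect_outliers <- function(series, cutoff = 5, constant = 0.6745,
                            district_id = NA_character_, period = NULL,
                            service = NA_character_) {
  if (all(is.na(series))) {
    warning("all-missing series: no outlier detection possible")
    return(empty_flags())
  }
  if (sum(!is.na(series)) < 2) {
    warning("fewer than 2 non-missing values: no outlier detection")
    return(empty_flags())
  }
  if (is.null(period)) period <- seq_along(series)
  stopifnot(length(period) == length(series))
  score <- modified_zscore(series, constant)
  sel <- !is.na(score) & score > cutoff
  if (!any(sel)) return(empty_flags())
  quality_flag(district_id, period[sel], service, "outlier",
               score = score[sel], threshold = cutoff)
}

#' Flag absent or null values on the expected reporting lattice
#'
#' The expected grid is the full district x period x service lattice; a flag
#' is raised for every cell that has no row or a null `value`. A reported
#' zero is a value and is never flagged.
#'
#' @param records service-record data.frame.
#' @param districts,periods,services the lattice; defaults are the distinct
#'   values present in `records`.
#' @return data.frame of flags (`kind == "missing"`).
#' @export
missing_scan <- function(records,
                         districts = unique(records$district_id),
                         periods = unique(records$period),
                         services = unique(records$service)) {
  grid <- expand.grid(district_id = districts, period = periods,
                      service = services, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  key_g <- paste(grid$district_id, grid$period, grid$service)
  key_r <- paste(records$district_id, records$period, records$service)
  i <- match(key_g, key_r)
  absent <- is.na(i) | is.na(records$value[i])
  if (!any(absent)) return(empty_flags())
  quality_flag(grid$district_id[absent], grid$period[absent],
               grid$service[absent], "missing")
}

#' Assess all three data-quality dimensions of a dataset
#'
#' Runs the missing-value scan, low-completeness flagging and per
#' district-service-calendar-year outlier detection on raw reported values.
#'
#' @param records service-record data.frame.
#' @param low low-completeness threshold (default 0.75).
#' @param cutoff,constant outlier score parameters, see [detect_outliers()].
#' @return data.frame of all flags.
#' @export
assess_quality <- function(records, low = 0.75, cutoff = 5,
                           constant = 0.6745) {
  flags <- list(missing_scan(records), flag_low_completeness(records, low))
  grp <- split(seq_len(nrow(records)),
               list(records$district_id, records$service,
                    period_year(records$period)), drop = TRUE)
  out <- lapply(grp, function(idx) {
    r <- records[idx, ]
    if (sum(!is.na(r$value)) < 2) return(empty_flags())
    detect_outliers(r$value, cutoff = cutoff, constant = constant,
                    district_id = r$district_id[1], period = r$period,
                    service = r$service[1])
  })
  do.call(rbind, c(flags, out, list(make.row.names = FALSE)))
}
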