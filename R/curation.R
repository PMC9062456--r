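# Curation: completeness adjustment, calendar-year median imputation of
# flagged cells, exclusion windows, and a replayable audit log.

#' Build an adjustment policy
#'
#' @param k_by_service named per-service adjustment factor `k` in \[0, 1\]:
#'   the assumed service volume of a non-reporting facility relative to a
#'   reporting one (0 = none, 1 = equal). Unnamed scalar applies to all
#'   services. Default 0.25, the conventional conservative choice.
#' @param low_completeness_threshold completeness below which a month is
#'   imputed rather than adjusted (default 0.75, strict).
#' @param outlier_cutoff modified Z-score cutoff (default 5).
#' @param outlier_constant normalising constant of the score (default 0.6745).
#' @param true_zero_overrides data.frame with columns `district_id`,
#'   `period`, `service`: flagged cells believed to be genuine zeros are kept
#'   at 0 instead of imputed.
#' @param exclusion_windows list of windows, each a list with `scope`
#'   (`"all"`, `"region"` or `"district"`), `id` (ignored for `"all"`),
#'   `from`, `to` (YYYYMM, inclusive) and `reason`.
#' @return object of class `adjustment_policy`.
#' @export
adjustment_policy <- function(k_by_service = 0.25,
                              low_completeness_threshold = 0.75,
                              outlier_cutoff = 5,
                              outlier_constant = 0.6745,
                              true_zero_overrides = NULL,
                              exclusion_windows = list()) {
  if (any(unlist(k_by_service) < 0 | unlist(k_by_service) > 1))
    stop("adjustment factors k must lie in [0,1]")
  stopifnot(low_completeness_threshold > 0, low_completeness_threshold <= 1)
  for (w in exclusion_windows) {
    stopifnot(w$scope %in% c("all", "region", "district"),
              is_period(w$from), is_period(w$to), w$from <= w$to)
  }
  structure(list(k_by_service = k_by_service,
                 low_completeness_threshold = low_completeness_threshold,
                 outlier_cutoff = outlier_cutoff,
                 outlier_constant = outlier_constant,
                 true_zero_overrides = true_zero_overrides,
                 exclusion_windows = exclusion_windows),
            class = "adjustment_policy")
}

policy_k <- function(policy, services) {
  k <- policy$k_by_service
  if (is.null(names(k))) stats::setNames(rep(k[[1]], length(services)), services)
  else fill_named(unlist(k), services, 0.25)
}

#' Adjust a reported count for incomplete facility reporting
#'
#' `adjusted = count * (1 + (1/c - 1) * k)`: linear interpolation between the
#' two stated endpoints — `k = 0` assumes non-reporting facilities provided
#' no services (no change) and `k = 1` assumes they provided services at the
#' same level as reporting ones (`count / c`).
#'
#' @param count reported count (>= 0).
#' @param c completeness of reporting, in (0, 1].
#' @param k adjustment factor in \[0, 1\].
#' @return adjusted count (never below `count`).
#' @export
adjust_for_completeness <- function(count, c, k) {
  if (any(is.na(c)) || any(c <= 0))
    stop("cannot adjust with completeness c = 0 or missing; impute instead")
  if (any(c > 1)) stop("completeness c must lie in (0,1]")
  if (any(k < 0 | k > 1)) stop("adjustment factor k must lie in [0,1]")
  if (any(count < 0, na.rm = TRUE)) stop("count must be nonnegative")
  count * (1 + (1 / c - 1) * k)
}

#' Impute flagged cells of one calendar year with the clean median
#'
#' Every flagged cell is replaced by the median of the year's non-flagged,
#' non-missing cells. Cells listed as true zeros stay at 0. If no clean cell
#' remains the series is returned unchanged and escalated via a warning.
#'
#' @param series numeric vector: one district-service calendar year.
#' @param flags logical vector marking cells to impute (missing cells with
#'   `NA` in `series` are imputed whether or not flagged).
#' @param true_zero logical vector marking override cells kept at 0.
#' @return numeric vector with imputations applied; attribute
#'   `"imputed_value"` carries the median used (NA when escalated).
#' @export
impute_calendar_median <- function(series, flags,
                                   true_zero = rep(FALSE, length(series))) {
  stopifnot(length(flags) == length(series),
            length(true_zero) == length(series))
  target <- (flags | is.na(series)) & !true_zero
  clean <- !flags & !is.na(series)
  out <- series
  out[true_zero] <- 0
  if (!any(target)) {
    attr(out, "imputed_value") <- NA_real_
    return(out)
  }
  if (!any(clean)) {
    warning("no clean cells in calendar year: cells left missing, escalate")
    attr(out, "imputed_value") <- NA_real_
    return(out)
  }
  med <- stats::median(series[clean])
  out[target] <- med
  attr(out, "imputed_value") <- med
  out
}

window_matches <- function(records, w) {
  in_period <- records$period >= w$from & records$period <= w$to
  switch(w$scope,
         all = in_period,
         region = in_period & records$region == w$id,
         district = in_period & records$district_id == w$id)
}

#' Apply exclusion windows
#'
#' Records falling in any window (union of overlapping windows) are dropped
#' from downstream modelling frames and logged once each with the (first
#' matching) reason.
#'
#' @param records service-record data.frame (with `adjusted_value` if already
#'   curated).
#' @param windows list of windows (see [adjustment_policy()]).
#' @return list with `records` (rows outside all windows) and `log` entries
#'   of action `"excluded"`.
#' @export
apply_exclusions <- function(records, windows) {
  if (!length(windows))
    return(list(records = records, log = empty_curation_log()))
  drop <- rep(FALSE, nrow(records))
  reason <- rep(NA_character_, nrow(records))
  for (w in windows) {
    m <- window_matches(records, w)
    if (!any(m)) warning("exclusion window matches no records (", w$reason %||% "", ")")
    reason[m & !drop] <- w$reason %||% NA_character_
    drop <- drop | m
  }
  log <- if (any(drop)) data.frame(
    district_id = records$district_id[drop], period = records$period[drop],
    service = records$service[drop],
    original = records$value[drop], action = "excluded",
    replacement = NA_real_, params = reason[drop],
    stringsAsFactors = FALSE) else empty_curation_log()
  list(records = records[!drop, , drop = FALSE], log = log)
}

empty_curation_log <- function() {
  data.frame(district_id = character(0), period = integer(0),
             service = character(0), original = numeric(0),
             action = character(0), replacement = numeric(0),
             params = character(0), stringsAsFactors = FALSE)
}

#' Curate a raw dataset
#'
#' Fixed order of operations: (1) quality flags are computed on the raw
#' data; (2) missing, extreme-outlier and low-completeness cells are imputed
#' with the calendar-year median of clean cells (imputed values stand in for
#' a fully-reported month and are not additionally adjusted); (3) remaining
#' cells are adjusted for completeness with the service-specific factor `k`;
#' (4) exclusion windows are applied. Every changed cell gets exactly one
#' log entry; replaying the log on the raw data reproduces the curated
#' dataset exactly (see [replay_curation_log()]).
#'
#' @param records raw service-record data.frame.
#' @param policy an [adjustment_policy()].
#' @return list with `records` (curated; adds `adjusted_value`), `log`
#'   (curation log) and `flags` (the quality flags used).
#' @export
curate <- function(records, policy = adjustment_policy()) {
  stopifnot(inherits(policy, "adjustment_policy"))
  rec <- records
  rec$.row <- seq_len(nrow(rec))
  flags <- assess_quality(rec, low = policy$low_completeness_threshold,
                          cutoff = policy$outlier_cutoff,
                          constant = policy$outlier_constant)
  fkey <- paste(flags$district_id, flags$period, flags$service)
  rkey <- paste(rec$district_id, rec$period, rec$service)
  kind_of <- function(kind) rkey %in% fkey[flags$kind == kind]
  is_missing <- is.na(rec$value)
  is_outlier <- kind_of("outlier")
  is_lowc <- kind_of("low_completeness")
  flagged <- is_missing | is_outlier | is_lowc

  tz <- rep(FALSE, nrow(rec))
  if (!is.null(policy$true_zero_overrides)) {
    o <- policy$true_zero_overrides
    tz <- rkey %in% paste(o$district_id, o$period, o$service)
  }

  k_s <- policy_k(policy, unique(rec$service))
  rec$adjusted_value <- rec$value
  logs <- list()

  grp <- split(seq_len(nrow(rec)),
               list(rec$district_id, rec$service, period_year(rec$period)),
               drop = TRUE)
  for (idx in grp) {
    fl <- flagged[idx]
    if (!any(fl)) next
    imp <- impute_calendar_median(rec$value[idx], fl, true_zero = tz[idx])
    rec$adjusted_value[idx] <- as.numeric(imp)
    med <- attr(imp, "imputed_value")
    act <- ifelse(tz[idx], "kept_zero",
           ifelse(is_missing[idx], "imputed_missing",
           ifelse(is_outlier[idx], "imputed_outlier",
                  "imputed_low_completeness")))
    sel <- fl
    changed <- sel & (tz[idx] | !is.na(med))
    if (any(changed)) {
      ii <- idx[changed]
      logs[[length(logs) + 1]] <- data.frame(
        district_id = rec$district_id[ii], period = rec$period[ii],
        service = rec$service[ii], original = rec$value[ii],
        action = act[changed],
        replacement = rec$adjusted_value[ii],
        params = sprintf("calendar_median=%s",
                         ifelse(tz[idx][changed], "true_zero",
                                format(med, digits = 12))),
        stringsAsFactors = FALSE)
    }
  }

  # completeness adjustment on unflagged cells
  cc <- rec$reports_actual / rec$reports_expected
  adj <- !flagged & !tz & !is.na(rec$adjusted_value) & !is.na(cc) & cc > 0
  if (any(adj)) {
    kk <- k_s[rec$service[adj]]
    new <- adjust_for_completeness(rec$adjusted_value[adj], cc[adj], kk)
    changed <- new != rec$adjusted_value[adj]
    rec$adjusted_value[adj] <- new
    if (any(changed)) {
      ii <- which(adj)[changed]
      logs[[length(logs) + 1]] <- data.frame(
        district_id = rec$district_id[ii], period = rec$period[ii],
        service = rec$service[ii], original = rec$value[ii],
        action = "adjusted", replacement = rec$adjusted_value[ii],
        params = sprintf("c=%s;k=%s", format(cc[ii], digits = 12),
                         format(k_s[rec$service[ii]], digits = 12)),
        stringsAsFactors = FALSE)
    }
  }

  excl <- apply_exclusions(rec, policy$exclusion_windows)
  rec <- excl$records
  rec$.row <- NULL
  log <- do.call(rbind, c(logs, list(excl$log), list(make.row.names = FALSE)))
  list(records = rec, log = log, flags = flags)
}

#' Replay a curation log against the raw dataset
#'
#' Applies the logged replacements and exclusions to the raw records,
#' reproducing the curated dataset exactly.
#'
#' @param records the raw service-record data.frame fed to [curate()].
#' @param log the curation log returned by [curate()].
#' @return curated data.frame (with `adjusted_value`).
#' @export
replay_curation_log <- function(records, log) {
  rec <- records
  rec$adjusted_value <- rec$value
  rkey <- paste(rec$district_id, rec$period, rec$service)
  if (nrow(log)) {
    lkey <- paste(log$district_id, log$period, log$service)
    repl <- log[log$action != "excluded", ]
    i <- match(paste(repl$district_id, repl$period, repl$service), rkey)
    rec$adjusted_value[i] <- repl$replacement
    rec <- rec[!(rkey %in% lkey[log$action == "excluded"]), , drop = FALSE]
  }
  rec
}

#' Write the curated dataset and log as CSV
#'
#' @param curated result of [curate()].
#' @param data_path,log_path output paths.
#' @return invisibly, the two paths.
#' @export
write_curated_csv <- function(curated, data_path, log_path) {
  cols <- c(hmis_schema, "adjusted_value")
  utils::write.csv(curated$records[intersect(cols, names(curated$records))],
                   data_path, row.names = FALSE, na = "")
  utils::write.csv(curated$log, log_path, row.names = FALSE, na = "")
  invisible(c(data_path, log_path))
}
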