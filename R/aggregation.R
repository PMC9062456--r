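# Bottom-up aggregation and the median/mean margins used in report tables.

#' Roll curated district data up to a stratum level
#'
#' National, region or urban/rural/mixed sums per period and service,
#' bottom-up from the curated district values. Partitions are exhaustive and
#' disjoint, so stratum sums conserve the national total.
#'
#' @param records curated service-record data.frame (uses `adjusted_value`
#'   when present, else `value`).
#' @param level `"national"`, `"region"` or `"area_type"`.
#' @return data.frame with `stratum`, `service`, `period`, `count`.
#' @export
rollup <- function(records, level = c("national", "region", "area_type")) {
  level <- match.arg(level)
  if (level == "area_type") {
    bad <- !(records$area_type %in% c("urban", "rural", "mixed"))
    if (any(bad))
      stop("unknown area_type for district(s): ",
           paste(unique(records$district_id[bad]), collapse = ", "))
  }
  val <- if ("adjusted_value" %in% names(records)) records$adjusted_value
         else records$value
  stratum <- switch(level, national = rep("national", nrow(records)),
                    region = records$region, area_type = records$area_type)
  agg <- stats::aggregate(
    list(count = val),
    by = list(stratum = stratum, service = records$service,
              period = records$period),
    FUN = sum, na.rm = TRUE)
  agg[order(agg$stratum, agg$service, agg$period), , drop = FALSE]
}

#' Median of a column with gaps
#'
#' Missing cells are skipped (never zero-filled); an even number of values
#' gives the midpoint of the two central ones. The unrounded value is
#' returned; report tables display it via [round_half_out()] at 1 decimal.
#'
#' @param values numeric, possibly with `NA` gaps.
#' @return unrounded median.
#' @export
column_median <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("column median undefined: all values missing")
  stats::median(v)
}

#' Mean of a column with gaps
#'
#' @param values numeric, possibly with `NA` gaps.
#' @return unrounded arithmetic mean of the non-missing values.
#' @export
column_mean <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("column mean undefined: all values missing")
  mean(v)
}

#' Margins of a country x service percent-change grid
#'
#' Computes the per-service medians by country group (West / Eastern Africa)
#' and overall, the per-country median across services, and the overall
#' median and range of those country medians — the margin cells of the
#' whole-period summary table.
#'
#' @param grid data.frame with columns `country`, `group` and one numeric
#'   column per service (gaps as `NA`).
#' @return list with `service_margins` (data.frame: service, median by group
#'   and overall, rounded to 1 decimal for display), `country_medians`,
#'   `overall_median` and `overall_range` (unrounded and rounded).
#' @export
summarise_change_grid <- function(grid) {
  svc <- setdiff(names(grid), c("country", "group"))
  med_for <- function(rows, s) column_median(grid[rows, s])
  groups <- unique(grid$group)
  sm <- do.call(rbind, lapply(svc, function(s) {
    row <- data.frame(service = s, stringsAsFactors = FALSE)
    for (g in groups)
      row[[paste0("median_", gsub("\\s+", "_", tolower(g)))]] <-
        round_half_out(med_for(grid$group == g, s), 1)
    row$median_all <- round_half_out(med_for(TRUE, s), 1)
    row
  }))
  cm <- vapply(seq_len(nrow(grid)), function(i)
    column_median(as.numeric(grid[i, svc])), numeric(1))
  list(service_margins = sm,
       country_medians = data.frame(country = grid$country,
                                    median = round_half_out(cm, 1)),
       overall_median = column_median(cm),
       overall_median_rounded = round_half_out(column_median(cm), 1),
       overall_range = range(cm),
       overall_range_rounded = round_half_out(range(cm), 1))
}

#' Build report summary tables
#'
#' Emits the three standard report tables from their inputs: a data-quality
#' table (one row per year with national completeness and the percent of
#' districts above 90\%), a whole-period estimate grid with group margins,
#' and a per-service urban/rural median table.
#'
#' @param quality named list of [completeness_summary()] objects (names =
#'   years) or `NULL`.
#' @param change_grid country x service grid (see [summarise_change_grid()])
#'   or `NULL`.
#' @param area_estimates data.frame with `service`, `stratum`
#'   (urban/rural), `pct_change` per country, or `NULL`.
#' @return named list of data.frames (`quality`, `changes`, `by_area`);
#'   absent inputs give zero-row tables with headers.
#' @export
build_summary_tables <- function(quality = NULL, change_grid = NULL,
                                 area_estimates = NULL) {
  qt <- if (length(quality)) do.call(rbind, lapply(quality, function(q)
    data.frame(year = q$year,
               national_completeness = q$national_pct_rounded,
               pct_districts_gt90 = q$pct_districts_gt90_rounded,
               district_months_below75 = q$n_district_months_below75)))
  else data.frame(year = integer(0), national_completeness = numeric(0),
                  pct_districts_gt90 = numeric(0),
                  district_months_below75 = integer(0))

  ct <- if (!is.null(change_grid) && nrow(change_grid)) {
    m <- summarise_change_grid(change_grid)
    margins <- m$service_margins
    names(margins) <- sub("^median_west_africa$", "Median (West Africa)",
      sub("^median_eastern_africa$", "Median (Eastern Africa)",
        sub("^median_all$", "Median", names(margins))))
    margins
  } else data.frame(service = character(0), Median = numeric(0))

  at <- if (!is.null(area_estimates) && nrow(area_estimates)) {
    ae <- area_estimates[area_estimates$stratum %in% c("urban", "rural"), ]
    stats::aggregate(list(median_pct_change = ae$pct_change),
                     by = list(service = ae$service, stratum = ae$stratum),
                     FUN = function(x) round_half_out(column_median(x), 1))
  } else data.frame(service = character(0), stratum = character(0),
                    median_pct_change = numeric(0))

  list(quality = qt, changes = ct, by_area = at)
}
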