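# Configuration-driven orchestration: simulate-or-ingest -> quality ->
# curate -> aggregate -> model -> stringency link -> report bundle.

#' Validate a pipeline input file or data.frame
#'
#' Checks the CSV schema, YYYYMM period format, reporting-metadata
#' consistency (`reports_actual <= reports_expected`) and duplicate
#' (district, period, service) keys. Problems are reported with row numbers
#' (header = row 1), never thrown.
#'
#' @param x path to a CSV in the pipeline schema, or a data.frame.
#' @return data.frame with columns `row`, `problem`; zero rows when clean.
#' @export
validate_input <- function(x) {
  problems <- list()
  add <- function(row, problem)
    problems[[length(problems) + 1]] <<- data.frame(
      row = row, problem = problem, stringsAsFactors = FALSE)
  df <- if (is.character(x)) {
    raw <- utils::read.csv(x, stringsAsFactors = FALSE, na.strings = "")
    miss <- setdiff(hmis_schema, names(raw))
    if (length(miss)) {
      add(1L, paste("missing column(s):", paste(miss, collapse = ", ")))
      return(do.call(rbind, problems))
    }
    raw
  } else x
  rown <- seq_len(nrow(df)) + 1L  # data rows start after the header

  bad_p <- !grepl("^[0-9]{6}$", as.character(df$period)) |
    suppressWarnings(as.integer(df$period) %% 100) < 1 |
    suppressWarnings(as.integer(df$period) %% 100) > 12
  for (i in which(bad_p)) add(rown[i], paste("invalid period:", df$period[i]))

  bad_area <- !(df$area_type %in% c("urban", "rural", "mixed"))
  for (i in which(bad_area))
    add(rown[i], paste("unknown area_type:", df$area_type[i]))

  bad_rep <- !is.na(df$reports_actual) & !is.na(df$reports_expected) &
    df$reports_actual > df$reports_expected
  for (i in which(bad_rep))
    add(rown[i], sprintf("reports_actual (%s) > reports_expected (%s)",
                         df$reports_actual[i], df$reports_expected[i]))

  key <- paste(df$district_id, df$period, df$service)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  for (k in unique(key[dup])) {
    rows <- rown[key == k]
    add(rows[1], sprintf("duplicate key (%s) in rows %s", k,
                         paste(rows, collapse = ", ")))
  }

  neg <- !is.na(df$value) & df$value < 0
  for (i in which(neg)) add(rown[i], paste("negative value:", df$value[i]))

  if (!length(problems))
    return(data.frame(row = integer(0), problem = character(0)))
  do.call(rbind, problems)
}

#' Build a pipeline configuration
#'
#' @param input path to an input CSV in the pipeline schema, or `NULL` to
#'   simulate the `scenario`.
#' @param scenario a [scenario_config()] (used when `input` is `NULL`).
#' @param policy an [adjustment_policy()].
#' @param mode model mode, `"period"` or `"monthly"`.
#' @param strata stratification column for area estimates, or `NULL`.
#' @param stringency_file optional OWID-dialect CSV path.
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed recorded in the manifest and applied to the
#'   scenario.
#' @param min_pre_months passed to [build_frame()].
#' @param services allowed service codes; input records with other codes
#'   abort the run before any computation. Default [default_services()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, scenario = NULL,
                            policy = adjustment_policy(),
                            mode = c("period", "monthly"),
                            strata = "area_type",
                            stringency_file = NULL,
                            out_dir = tempfile("hmis_run_"),
                            seed = 1, min_pre_months = 24,
                            services = default_services()) {
  mode <- match.arg(mode)
  if (is.null(input) && is.null(scenario))
    stop("either an input path or a scenario must be given")
  if (!is.null(input) && !file.exists(input))
    stop("input file does not exist: ", input)
  if (!is.null(stringency_file) && !file.exists(stringency_file))
    stop("stringency file does not exist: ", stringency_file)
  structure(list(input = input, scenario = scenario, policy = policy,
                 mode = mode, strata = strata,
                 stringency_file = stringency_file, out_dir = out_dir,
                 seed = as.integer(seed), min_pre_months = min_pre_months,
                 services = services),
            class = "pipeline_config")
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(serialize_config(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

serialize_config <- function(config) {
  sc <- config$scenario
  list(input = config$input,
       scenario = if (!is.null(sc))
         lapply(unclass(sc), function(x)
           if (is.matrix(x)) as.data.frame(x) else x),
       policy = unclass(config$policy), mode = config$mode,
       strata = config$strata, stringency_file = config$stringency_file,
       seed = config$seed, min_pre_months = config$min_pre_months,
       services = config$services)
}

#' Run the full pipeline
#'
#' Stages in fixed order: input (simulate or read + validate), quality
#' assessment, curation, aggregation, disruption modelling (national and by
#' stratum), optional stringency association, and report-bundle writing.
#' Any stage failure aborts with the stage name. Reruns with the same
#' config and seed produce byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage progress messages.
#' @return invisibly, a list with the in-memory artifacts (`records`,
#'   `flags`, `curated`, `rollup`, `estimates`, `area_estimates`,
#'   `association`, `manifest`) and the paths written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  say("input")
  records <- stage("input", {
    if (!is.null(config$input)) {
      probs <- validate_input(config$input)
      fatal <- grepl("missing column|invalid period|unknown area_type",
                     probs$problem)
      if (any(fatal))
        stop("schema violations:\n", paste(
          sprintf("  row %d: %s", probs$row[fatal], probs$problem[fatal]),
          collapse = "\n"))
      df <- read_hmis_csv(config$input)
      unknown <- setdiff(unique(df$service), config$services)
      if (length(unknown))
        stop("unknown service code(s): ", paste(unknown, collapse = ", "))
      df
    } else {
      sc <- config$scenario
      sc$seed <- config$seed
      simulate_scenario(sc)$records
    }
  })

  say("quality")
  quality <- stage("quality", {
    years <- sort(unique(period_year(records$period)))
    summaries <- lapply(years, function(y) completeness_summary(records, y))
    names(summaries) <- years
    summaries
  })

  say("curate")
  curated <- stage("curate", curate(records, config$policy))

  say("aggregate")
  agg <- stage("aggregate", rollup(curated$records, "national"))

  say("model")
  estimates <- stage("model", estimate_disruption(
    curated$records, mode = config$mode,
    min_pre_months = config$min_pre_months))
  area_estimates <- NULL
  if (!is.null(config$strata))
    area_estimates <- stage("model", stratified_estimates(
      curated$records, strata = config$strata, mode = config$mode,
      min_pre_months = config$min_pre_months))

  association <- NULL
  if (!is.null(config$stringency_file)) {
    say("stringency")
    association <- stage("stringency", {
      series <- load_owid(config$stringency_file)
      monthly_metrics(series)
    })
  }

  say("report")
  paths <- stage("report", {
    p <- list(quality = "quality_report.csv", flags = "quality_flags.csv",
              curated = "curated.csv", log = "curation_log.csv",
              rollup = "national_series.csv", estimates = "estimates.csv")
    p <- lapply(p, function(f) file.path(config$out_dir, f))
    qt <- build_summary_tables(quality = quality)$quality
    utils::write.csv(qt, p$quality, row.names = FALSE, na = "")
    utils::write.csv(curated$flags, p$flags, row.names = FALSE, na = "")
    write_curated_csv(curated, p$curated, p$log)
    utils::write.csv(agg, p$rollup, row.names = FALSE, na = "")
    est_out <- estimates
    if (!is.null(area_estimates)) est_out <- rbind(est_out, area_estimates)
    utils::write.csv(est_out, p$estimates, row.names = FALSE, na = "")
    if (!is.null(association)) {
      p$stringency <- file.path(config$out_dir, "stringency_monthly.csv")
      utils::write.csv(association$monthly, p$stringency,
                       row.names = FALSE, na = "")
    }
    manifest <- list(package = "hmisdisrupt",
                     version = as.character(utils::packageVersion("hmisdisrupt")),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."),
                     seed = config$seed,
                     config_md5 = config_digest(config),
                     artifacts = unlist(p))
    p$manifest <- file.path(config$out_dir, "manifest.json")
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               p$manifest)
    p
  })

  invisible(list(records = records, quality = quality, flags = curated$flags,
                 curated = curated, rollup = agg, estimates = estimates,
                 area_estimates = area_estimates, association = association,
                 paths = paths))
}
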