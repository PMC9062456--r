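#' @keywords internal
"_PACKAGE"

# ---- period (YYYYMM) helpers -------------------------------------------------

#' Sequence of YYYYMM periods
#'
#' Inclusive sequence of calendar months encoded as integers `YYYYMM`.
#'
#' @param from,to integer periods, e.g. `201701`, `202012`.
#' @return integer vector of periods.
#' @export
period_seq <- function(from, to) {
  stopifnot(is_period(from), is_period(to))
  if (from > to) stop("invalid period range: ", from, " > ", to)
  d0 <- period_to_date(from)
  d1 <- period_to_date(to)
  out <- seq(d0, d1, by = "month")
  as.integer(format(out, "%Y%m"))
}

is_period <- function(p) {
  is.numeric(p) && length(p) >= 1 && all(!is.na(p)) &&
    all(p %% 100 >= 1) && all(p %% 100 <= 12) && all(p >= 190001 & p <= 210012)
}

period_to_date <- function(p) {
  as.Date(sprintf("%04d-%02d-01", p %/% 100, p %% 100))
}

#' Months elapsed between two periods
#'
#' @param p,origin integer YYYYMM periods.
#' @return integer number of calendar months from `origin` to `p`
#'   (0 when equal).
#' @export
period_diff <- function(p, origin) {
  (p %/% 100 - origin %/% 100) * 12L + (p %% 100 - origin %% 100)
}

period_month <- function(p) as.integer(p %% 100)
period_year  <- function(p) as.integer(p %/% 100)

# ---- reporting-style rounding ------------------------------------------------

#' Round half away from zero
#'
#' Display rounding used in report tables (so 95.5 -> 96, -1.95 -> -2.0),
#' unlike [base::round()]'s round-half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_out <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# ---- seeded evaluation -------------------------------------------------------

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
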