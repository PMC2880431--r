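#' Construct a reference incidence-rate table
#'
#' A rate table holds female breast-cancer incidence rates on a rectangular
#' age x calendar-period grid. Cells are half-open on both axes
#' (`[age_lo, age_hi)` x `[period_lo, period_hi)`), rates are stored per
#' woman-year, and the cells must tile the covered rectangle exactly: no
#' gaps, no overlaps. This is the reference against which expected counts
#' ("E") are computed for the familial relative risk O/E estimator.
#'
#' @param cells data.frame with columns `age_lo`, `age_hi`, `period_lo`,
#'   `period_hi`, `rate` (per woman-year).
#' @return an object of class `rate_table` with components `age_breaks`,
#'   `period_breaks` (sorted break points) and `rates` (matrix, age bands in
#'   rows, periods in columns).
#' @seealso [read_rate_table()], [lookup_rate()]
#' @export
rate_table <- function(cells) {
  req <- c("age_lo", "age_hi", "period_lo", "period_hi", "rate")
  miss <- setdiff(req, names(cells))
  if (length(miss)) stop("rate table missing column(s): ", paste(miss, collapse = ", "))
  cells <- as.data.frame(cells)[req]
  for (v in req) cells[[v]] <- as.numeric(cells[[v]])
  if (anyNA(cells)) stop("rate table contains missing values")
  if (any(cells$rate < 0)) {
    i <- which(cells$rate < 0)[1]
    stop(sprintf("negative rate in cell [%g,%g)x[%g,%g)",
                 cells$age_lo[i], cells$age_hi[i], cells$period_lo[i], cells$period_hi[i]))
  }
  if (any(cells$age_lo >= cells$age_hi) || any(cells$period_lo >= cells$period_hi)) {
    stop("each cell needs age_lo < age_hi and period_lo < period_hi")
  }
  ab <- sort(unique(c(cells$age_lo, cells$age_hi)))
  pb <- sort(unique(c(cells$period_lo, cells$period_hi)))
  na <- length(ab) - 1L
  np <- length(pb) - 1L
  count <- matrix(0L, na, np)
  rates <- matrix(NA_real_, na, np)
  for (k in seq_len(nrow(cells))) {
    ia <- which(ab >= cells$age_lo[k] & ab < cells$age_hi[k])
    ip <- which(pb >= cells$period_lo[k] & pb < cells$period_hi[k])
    count[ia, ip] <- count[ia, ip] + 1L
    rates[ia, ip] <- cells$rate[k]
  }
  if (any(count > 1L)) {
    w <- which(count > 1L, arr.ind = TRUE)[1L, ]
    stop(sprintf("overlapping rate cells at age [%g,%g), period [%g,%g)",
                 ab[w[1]], ab[w[1] + 1L], pb[w[2]], pb[w[2] + 1L]))
  }
  if (any(count == 0L)) {
    w <- which(count == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("gap in rate grid at age [%g,%g), period [%g,%g)",
                 ab[w[1]], ab[w[1] + 1L], pb[w[2]], pb[w[2] + 1L]))
  }
  structure(list(age_breaks = ab, period_breaks = pb, rates = rates),
            class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("<rate_table> ages [%g, %g) x periods [%g, %g): %d x %d cells, rates %.3g-%.3g per woman-year\n",
              min(x$age_breaks), max(x$age_breaks),
              min(x$period_breaks), max(x$period_breaks),
              nrow(x$rates), ncol(x$rates), min(x$rates), max(x$rates)))
  invisible(x)
}

#' Cells of a rate table as a data.frame
#'
#' @param x a `rate_table`.
#' @param ... unused.
#' @export
as.data.frame.rate_table <- function(x, ...) {
  na <- nrow(x$rates); np <- ncol(x$rates)
  data.frame(
    age_lo = rep(x$age_breaks[-(na + 1L)], times = np),
    age_hi = rep(x$age_breaks[-1L], times = np),
    period_lo = rep(x$period_breaks[-(np + 1L)], each = na),
    period_hi = rep(x$period_breaks[-1L], each = na),
    rate = as.vector(x$rates)
  )
}

#' Read a reference rate table from CSV
#'
#' The CSV dialect has a mandatory header `age_lo,age_hi,period_lo,period_hi,rate`
#' with rates given per `rate_scale` woman-years (registry tables are
#' conventionally per 100,000). Rates are converted to per woman-year on
#' input; grid completeness is validated.
#'
#' @param path CSV file path.
#' @param rate_scale divisor applied to the `rate` column; default `1e5`.
#' @return a [rate_table()].
#' @export
read_rate_table <- function(path, rate_scale = 1e5) {
  stopifnot(is.numeric(rate_scale), rate_scale > 0)
  cells <- utils::read.csv(path, check.names = TRUE)
  req <- c("age_lo", "age_hi", "period_lo", "period_hi", "rate")
  miss <- setdiff(req, names(cells))
  if (length(miss)) stop("rate CSV ", path, " missing column(s): ", paste(miss, collapse = ", "))
  cells$rate <- cells$rate / rate_scale
  rate_table(cells)
}

#' Write a rate table in the canonical CSV dialect
#'
#' Round-trips bit-identically with [read_rate_table()] when the same
#' `rate_scale` is used and rates are exactly representable.
#'
#' @param table a `rate_table`.
#' @param path output path.
#' @param rate_scale multiplier applied to the stored per-woman-year rates
#'   before writing (default 1e5, the registry convention).
#' @export
write_rate_table <- function(table, path, rate_scale = 1e5) {
  stopifnot(inherits(table, "rate_table"))
  df <- as.data.frame(table)
  df <- df[order(df$period_lo, df$age_lo), ]
  df$rate <- df$rate * rate_scale
  df[] <- lapply(df, function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up the incidence rate at an exact (age, date) point
#'
#' Cell membership uses half-open intervals `[lo, hi)` on both axes, so age
#' 55.0 with bands `[50,55)`, `[55,60)` falls in the `[55,60)` band.
#'
#' @param table a `rate_table`.
#' @param age attained age in exact (fractional) years; vectorised.
#' @param date calendar time in decimal years; recycled against `age`.
#' @param out_of_coverage `"error"` (default) to fail on points outside the
#'   covered rectangle, or `"truncate"` to clamp to the edge cell.
#' @return numeric vector of rates per woman-year.
#' @export
lookup_rate <- function(table, age, date, out_of_coverage = c("error", "truncate")) {
  stopifnot(inherits(table, "rate_table"))
  out_of_coverage <- match.arg(out_of_coverage)
  n <- max(length(age), length(date))
  age <- rep_len(as.numeric(age), n)
  date <- rep_len(as.numeric(date), n)
  ia <- findInterval(age, table$age_breaks)
  ip <- findInterval(date, table$period_breaks)
  na <- nrow(table$rates); np <- ncol(table$rates)
  bad <- ia < 1L | ia > na | ip < 1L | ip > np
  if (any(bad)) {
    if (out_of_coverage == "error") {
      i <- which(bad)[1]
      stop(sprintf("point (age %g, date %g) outside rate-table coverage", age[i], date[i]))
    }
    ia <- pmin(pmax(ia, 1L), na)
    ip <- pmin(pmax(ip, 1L), np)
  }
  table$rates[cbind(ia, ip)]
}

#' Normalise a set of age weights
#'
#' Age weights are used to average age-specific familial relative risks over
#' the age distribution of breast-cancer cases. Weights are rescaled to sum
#' to one; order (which must be strictly increasing in age) is preserved.
#'
#' @param age ages in years, strictly increasing.
#' @param weight non-negative raw weights with at least one positive entry.
#' @return an `age_weights` data.frame with columns `age`, `weight`.
#' @export
normalize_weights <- function(age, weight) {
  age <- as.numeric(age); weight <- as.numeric(weight)
  if (length(age) != length(weight) || !length(age)) stop("age and weight must be equal-length, non-empty")
  if (is.unsorted(age, strictly = TRUE)) stop("ages must be strictly increasing")
  if (any(weight < 0)) stop("negative weight")
  s <- sum(weight)
  if (s <= 0) stop("weights must include at least one positive value")
  structure(data.frame(age = age, weight = weight / s),
            class = c("age_weights", "data.frame"))
}

#' Incidence-shaped case-age weights from a rate table
#'
#' The conventional weighting for age-averaged FRRs: weight each age by the
#' population incidence rate at that age, i.e. the (approximate) age
#' distribution of cases. Rates are taken at the midpoint of each one-year
#' age band, in the given calendar period.
#'
#' @param table a `rate_table`.
#' @param ages integer ages to weight; default `20:69` (cases aged 20-70).
#' @param date calendar year at which to read the rates; defaults to the
#'   midpoint of the table's period coverage.
#' @return an `age_weights` object.
#' @export
case_age_weights <- function(table, ages = 20:69, date = NULL) {
  if (is.null(date)) date <- mean(range(table$period_breaks))
  r <- lookup_rate(table, ages + 0.5, date)
  normalize_weights(ages, r)
}
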