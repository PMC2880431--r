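#' Split follow-up intervals on the age x period rate grid
#'
#' Expected counts require piecewise-constant reference rates, so each
#' relative's follow-up is split at every crossing of an age-band or
#' calendar-period boundary (a Lexis expansion: follow-up runs along the
#' 45-degree life line, so both kinds of crossing are cut points on the
#' same time axis). Segments lie wholly within one rate cell and their
#' person-years sum exactly to the interval length.
#'
#' @param intervals data.frame with columns `entry_age`, `exit_age`,
#'   `entry_date` (and optionally `family_id`, `person_id`, `event`), e.g.
#'   from [derive_follow_up()].
#' @param table a [rate_table()].
#' @param out_of_coverage `"error"` to fail when follow-up leaves the rate
#'   grid, `"truncate"` to clip follow-up to the covered rectangle (dropping
#'   events that fall outside it).
#' @return data.frame of segments: interval row index `.row`, any id columns,
#'   `age_start`, `age_end`, `date_start`, `person_years`, `rate`.
#' @export
expand_lexis <- function(intervals, table, out_of_coverage = c("error", "truncate")) {
  stopifnot(inherits(table, "rate_table"))
  out_of_coverage <- match.arg(out_of_coverage)
  x <- as.data.frame(intervals)
  n <- nrow(x)
  if (!n) {
    return(data.frame(.row = integer(), age_start = numeric(), age_end = numeric(),
                      date_start = numeric(), person_years = numeric(), rate = numeric()))
  }
  entry_age <- as.numeric(x$entry_age)
  exit_age <- as.numeric(x$exit_age)
  entry_date <- as.numeric(x$entry_date)
  exit_date <- entry_date + (exit_age - entry_age)
  if (any(exit_age < entry_age)) stop("interval with exit_age < entry_age")

  ab <- table$age_breaks
  pb <- table$period_breaks
  x <- clip_to_coverage(x, table, out_of_coverage)
  n <- nrow(x)
  if (!n) {
    return(data.frame(.row = integer(), age_start = numeric(), age_end = numeric(),
                      date_start = numeric(), person_years = numeric(), rate = numeric()))
  }
  entry_age <- as.numeric(x$entry_age)
  exit_age <- as.numeric(x$exit_age)
  entry_date <- as.numeric(x$entry_date)
  exit_date <- entry_date + (exit_age - entry_age)

  # interior cut points, as ages along each interval's life line
  f_lo_a <- findInterval(entry_age, ab)
  f_hi_a <- findInterval(exit_age, ab, left.open = TRUE)
  n_a <- pmax(0L, f_hi_a - f_lo_a)
  f_lo_p <- findInterval(entry_date, pb)
  f_hi_p <- findInterval(exit_date, pb, left.open = TRUE)
  n_p <- pmax(0L, f_hi_p - f_lo_p)

  idx_a <- sequence(n_a, from = f_lo_a + 1L)
  own_a <- rep(seq_len(n), n_a)
  cuts_a <- ab[idx_a]
  idx_p <- sequence(n_p, from = f_lo_p + 1L)
  own_p <- rep(seq_len(n), n_p)
  cuts_p <- entry_age[own_p] + (pb[idx_p] - entry_date[own_p])

  dt <- data.table(
    .row = c(seq_len(n), own_a, own_p, seq_len(n)),
    age = c(entry_age, cuts_a, cuts_p, exit_age)
  )
  setorder(dt, .row, age)
  age <- NULL; .row <- NULL; person_years <- NULL  # NSE note for R CMD check
  seg <- dt[, list(age_start = age[-.N], age_end = age[-1L]), by = .row]
  seg <- seg[age_end - age_start > 0]
  seg[, person_years := age_end - age_start]
  mid_age <- (seg$age_start + seg$age_end) / 2
  mid_date <- entry_date[seg$.row] + (mid_age - entry_age[seg$.row])
  seg_rate <- table$rates[cbind(findInterval(mid_age, ab),
                                findInterval(mid_date, pb))]
  out <- as.data.frame(seg)
  out$date_start <- entry_date[out$.row] + (out$age_start - entry_age[out$.row])
  out$rate <- seg_rate
  for (v in intersect(c("family_id", "person_id"), names(x))) {
    out[[v]] <- x[[v]][out$.row]
  }
  out
}

#' Clip follow-up intervals to the rate-table coverage
#'
#' With `out_of_coverage = "error"` any follow-up outside the covered
#' age x period rectangle is an error (silent truncation hides data
#' problems); with `"truncate"` intervals are clipped along the life line to
#' the rectangle, events falling outside the clipped interval are dropped,
#' and intervals left with no at-risk time are removed.
#'
#' @param intervals follow-up data.frame (`entry_age`, `exit_age`,
#'   `entry_date`, optionally `event`).
#' @param table a [rate_table()].
#' @param out_of_coverage `"error"` or `"truncate"`.
#' @return the (possibly clipped) intervals.
#' @export
clip_to_coverage <- function(intervals, table, out_of_coverage = c("error", "truncate")) {
  out_of_coverage <- match.arg(out_of_coverage)
  x <- as.data.frame(intervals)
  if (!nrow(x)) return(x)
  entry_age <- as.numeric(x$entry_age)
  exit_age <- as.numeric(x$exit_age)
  entry_date <- as.numeric(x$entry_date)
  exit_date <- entry_date + (exit_age - entry_age)
  ab <- table$age_breaks; pb <- table$period_breaks
  a_min <- ab[1]; a_max <- ab[length(ab)]
  p_min <- pb[1]; p_max <- pb[length(pb)]
  outside <- entry_age < a_min | exit_age > a_max | entry_date < p_min | exit_date > p_max
  if (!any(outside)) return(x)
  if (out_of_coverage == "error") {
    i <- which(outside)[1]
    stop(sprintf("follow-up (ages %g-%g, dates %g-%g) outside rate-table coverage",
                 entry_age[i], exit_age[i], entry_date[i], exit_date[i]))
  }
  lo_shift <- pmax(0, pmax(a_min - entry_age, p_min - entry_date))
  hi_shift <- pmax(0, pmax(exit_age - a_max, exit_date - p_max))
  x$entry_age <- entry_age + lo_shift
  x$entry_date <- entry_date + lo_shift
  x$exit_age <- exit_age - hi_shift
  x$exit_date <- exit_date - hi_shift
  if (!is.null(x$event)) x$event <- x$event & hi_shift == 0
  x[x$exit_age > x$entry_age, , drop = FALSE]
}

#' Expected number of breast cancers from Lexis segments
#'
#' The expected count is the sum over segments of person-years times the
#' reference rate of the containing cell, i.e. the denominator of the
#' standardized-incidence-ratio-style FRR estimator.
#'
#' @param segments data.frame from [expand_lexis()].
#' @return non-negative scalar E.
#' @export
expected_count <- function(segments) {
  sum(segments$person_years * segments$rate)
}
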