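#' Convert dates to decimal calendar years
#'
#' All person-time arithmetic in frrcohort is carried out on real-valued
#' calendar years, so that `exit_date - entry_date` equals `exit_age -
#' entry_age` exactly and age/period boundaries are unambiguous half-open
#' intervals. ISO dates are converted as `year + days_since_jan1 / 365.25`;
#' a bare year ("1950") is read as mid-year (July 1, i.e. `year + 0.5`).
#'
#' @param x character vector of ISO `YYYY-MM-DD` dates and/or bare years,
#'   a `Date` vector, or a numeric vector (returned unchanged). Empty strings
#'   and `NA` give `NA`.
#' @return numeric vector of decimal years.
#' @examples
#' decimal_year(c("1950-01-01", "1950", "1950-07-01"))
#' @export
decimal_year <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "Date")) {
    yr <- as.integer(format(x, "%Y"))
    jan1 <- as.Date(paste0(yr, "-01-01"))
    return(yr + as.numeric(x - jan1) / 365.25)
  }
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  x[!nzchar(x)] <- NA_character_
  bare <- !is.na(x) & grepl("^[0-9]{3,4}$", x)
  out[bare] <- as.numeric(x[bare]) + 0.5
  iso <- !is.na(x) & !bare
  if (any(iso)) {
    d <- as.Date(x[iso], format = "%Y-%m-%d")
    if (anyNA(d)) {
      stop("unparseable date(s): ", paste(utils::head(x[iso][is.na(d)], 5), collapse = ", "))
    }
    out[iso] <- decimal_year(d)
  }
  out
}

#' Convert decimal years back to ISO dates
#'
#' Inverse of [decimal_year()] to the nearest day.
#'
#' @param x numeric vector of decimal years.
#' @return character vector of `YYYY-MM-DD` dates (`NA` preserved).
#' @export
iso_date <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (!any(ok)) return(out)
  yr <- floor(x[ok])
  jan1 <- as.Date(paste0(yr, "-01-01"))
  out[ok] <- format(jan1 + round((x[ok] - yr) * 365.25), "%Y-%m-%d")
  out
}
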