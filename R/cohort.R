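#' @importFrom data.table data.table setorder := .N .SD fifelse
NULL

.marker_levels <- c("positive", "negative", "unknown")

.subtype_levels <- c("luminal", "luminal_her2pos", "luminal_her2neg",
                     "nonluminal_her2pos", "triple_negative", "unclassifiable")

.norm_marker <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | !nzchar(x)] <- "unknown"
  bad <- !x %in% .marker_levels
  if (any(bad)) stop("invalid marker status: ", paste(unique(x[bad]), collapse = ", "),
                     " (use positive/negative/unknown)")
  x
}

#' Classify a tumour into an immunohistochemical subtype
#'
#' Subtypes follow the standard ER/PR/HER2 taxonomy: luminal tumours express
#' ER and/or PR; luminal tumours split by HER2 when HER2 is known; tumours
#' negative for both ER and PR are non-luminal HER2-positive or triple
#' negative according to HER2. When the deciding markers are unknown the
#' tumour is `unclassifiable` (or stays at the coarser `luminal` label when
#' only the HER2 split is unavailable).
#'
#' @param er,pr,her2 marker status vectors: `"positive"`, `"negative"` or
#'   `"unknown"` (`NA`/empty treated as unknown). Recycled to a common length.
#' @return factor with levels `r paste(.subtype_levels, collapse = ", ")`.
#' @examples
#' classify_subtype("negative", "negative", "negative")   # triple_negative
#' classify_subtype("positive", "negative", "unknown")    # luminal
#' @export
classify_subtype <- function(er, pr, her2) {
  n <- max(length(er), length(pr), length(her2))
  er <- .norm_marker(rep_len(er, n))
  pr <- .norm_marker(rep_len(pr, n))
  her2 <- .norm_marker(rep_len(her2, n))
  out <- rep("unclassifiable", n)
  luminal <- er == "positive" | pr == "positive"
  nonluminal <- er == "negative" & pr == "negative"
  out[luminal] <- "luminal"
  out[luminal & her2 == "positive"] <- "luminal_her2pos"
  out[luminal & her2 == "negative"] <- "luminal_her2neg"
  out[nonluminal & her2 == "positive"] <- "nonluminal_her2pos"
  out[nonluminal & her2 == "negative"] <- "triple_negative"
  factor(out, levels = .subtype_levels)
}

.family_columns <- c("family_id", "person_id", "role", "birth_date",
                     "diagnosis_date", "er", "pr", "her2",
                     "breast_cancer_date", "other_cancer_date",
                     "death_date", "questionnaire_date")

#' Read a family-history cohort table
#'
#' The cohort TSV has one row per person: probands (the index breast-cancer
#' cases, carrying diagnosis date and ER/PR/HER2 marker status) and their
#' first-degree female relatives (mothers and sisters, carrying event dates
#' and the family-history questionnaire date). Dates are ISO `YYYY-MM-DD` or
#' bare years (read as July 1); empty string means missing. Exactly one
#' proband per family is required and every relative must reference an
#' existing family.
#'
#' @param path TSV file path.
#' @return a `family_cohort`: list with data.frames `probands` and
#'   `relatives`. Both keep the raw date strings and add decimal-year
#'   columns (`birth`, `diagnosis`, `breast_cancer`, `other_cancer`,
#'   `death`, `questionnaire` as applicable); probands gain
#'   `age_at_diagnosis` and `subtype`.
#' @export
read_family_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                          check.names = TRUE)
  miss <- setdiff(.family_columns, names(df))
  if (length(miss)) stop("family table missing column(s): ", paste(miss, collapse = ", "))
  as_family_cohort(df)
}

#' Build a `family_cohort` from a raw person-per-row data.frame
#'
#' Performs the same validation as [read_family_table()]; useful when the
#' cohort is assembled in memory (e.g. by [simulate_cohort()]).
#'
#' @param df data.frame with the family-table columns (see
#'   [read_family_table()]); all columns coerced to character.
#' @return a `family_cohort`.
#' @export
as_family_cohort <- function(df) {
  df <- as.data.frame(df)
  for (v in .family_columns) {
    if (!v %in% names(df)) stop("family table missing column: ", v)
    df[[v]] <- as.character(df[[v]])
    df[[v]][is.na(df[[v]])] <- ""
  }
  if (anyDuplicated(df$person_id)) {
    stop("duplicate person_id: ", df$person_id[anyDuplicated(df$person_id)])
  }
  role <- tolower(df$role)
  bad <- !role %in% c("proband", "mother", "sister")
  if (any(bad)) stop("invalid role(s): ", paste(unique(df$role[bad]), collapse = ", "))
  pro <- df[role == "proband", ]
  rel <- df[role != "proband", ]
  dup <- names(which(table(pro$family_id) > 1L))
  if (length(dup)) stop("family with more than one proband: ", dup[1])
  orphan <- setdiff(rel$family_id, pro$family_id)
  if (length(orphan)) stop("relative references unknown family_id: ", orphan[1])
  if (any(!nzchar(pro$birth_date))) stop("proband with missing birth_date")
  if (any(!nzchar(pro$diagnosis_date))) stop("proband with missing diagnosis_date")
  if (any(!nzchar(rel$questionnaire_date))) stop("relative with missing questionnaire_date")

  pro$birth <- decimal_year(pro$birth_date)
  pro$diagnosis <- decimal_year(pro$diagnosis_date)
  if (any(pro$diagnosis <= pro$birth)) stop("proband diagnosed before birth")
  pro$age_at_diagnosis <- pro$diagnosis - pro$birth
  pro$er <- .norm_marker(pro$er)
  pro$pr <- .norm_marker(pro$pr)
  pro$her2 <- .norm_marker(pro$her2)
  pro$subtype <- classify_subtype(pro$er, pro$pr, pro$her2)

  rel$role <- tolower(rel$role)
  rel$birth <- decimal_year(rel$birth_date)
  rel$birth_date_imputed <- FALSE
  for (v in c("breast_cancer", "other_cancer", "death", "questionnaire")) {
    rel[[v]] <- decimal_year(rel[[paste0(v, "_date")]])
  }
  for (v in c("breast_cancer", "other_cancer", "death", "questionnaire")) {
    bad <- !is.na(rel[[v]]) & !is.na(rel$birth) & rel[[v]] <= rel$birth
    if (any(bad)) stop("relative ", rel$person_id[which(bad)[1]], ": ", v,
                       " date not after birth date")
  }
  structure(list(probands = pro, relatives = rel), class = "family_cohort")
}

#' @export
print.family_cohort <- function(x, ...) {
  cat(sprintf("<family_cohort> %d families: %d probands, %d relatives (%d mothers, %d sisters)\n",
              length(unique(x$probands$family_id)), nrow(x$probands), nrow(x$relatives),
              sum(x$relatives$role == "mother"), sum(x$relatives$role == "sister")))
  print(table(subtype = x$probands$subtype))
  invisible(x)
}

#' Write a family cohort back to TSV
#'
#' Writes the canonical column set; `read_family_table(write_family_table(x))`
#' is stable.
#'
#' @param cohort a `family_cohort`.
#' @param path output TSV path.
#' @export
write_family_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "family_cohort"))
  df <- rbind(cohort$probands[, .family_columns],
              cohort$relatives[, .family_columns])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Impute missing relative birth dates from the proband
#'
#' Relatives with unknown date of birth are assigned one from their
#' relationship to the index case: mothers are given a birth date 30 years
#' before the proband's, sisters the proband's own birth date. The
#' `birth_date_imputed` flag is set on imputed records; relatives with a
#' known birth date are untouched.
#'
#' @param cohort a `family_cohort`.
#' @return the cohort with `relatives$birth` filled in.
#' @export
impute_birth_dates <- function(cohort) {
  stopifnot(inherits(cohort, "family_cohort"))
  rel <- cohort$relatives
  pro_birth <- cohort$probands$birth[match(rel$family_id, cohort$probands$family_id)]
  need <- is.na(rel$birth)
  rel$birth[need & rel$role == "mother"] <- pro_birth[need & rel$role == "mother"] - 30
  rel$birth[need & rel$role == "sister"] <- pro_birth[need & rel$role == "sister"]
  rel$birth_date_imputed <- need
  rel$birth_date[need] <- iso_date(rel$birth[need])
  cohort$relatives <- rel
  cohort
}

#' Derive at-risk follow-up intervals for relatives
#'
#' Implements the cohort's entry and censoring rules. Each relative enters
#' follow-up at the later of the cohort start (1 January 1960) and her birth,
#' and is censored at the first of: breast-cancer diagnosis, any other
#' cancer diagnosis, death, completion of the family-history questionnaire,
#' or reaching `max_age`. The interval carries an event flag only when the
#' breast-cancer date is the censoring date (ties broken in favour of the
#' event by default). Relatives born before `min_birth_year` are excluded,
#' as are relatives with no at-risk time inside the window.
#'
#' @param cohort a `family_cohort` with all relative birth dates present
#'   (run [impute_birth_dates()] first).
#' @param max_age administrative censoring age (years), default 85.
#' @param cohort_start calendar entry cut-off in decimal years, default 1960.
#' @param min_birth_year relatives born before this year are excluded,
#'   default 1890.
#' @param tie_break `"event_first"` (default) counts a breast cancer
#'   diagnosed on the censoring date as an event; `"censor_first"` does not.
#' @return data.frame of follow-up intervals (`family_id`, `person_id`,
#'   `role`, `entry_age`, `exit_age`, `entry_date`, `exit_date`, `event`)
#'   with an `exclusions` attribute (data.frame of excluded persons and
#'   reason codes).
#' @export
derive_follow_up <- function(cohort, max_age = 85, cohort_start = 1960,
                             min_birth_year = 1890,
                             tie_break = c("event_first", "censor_first")) {
  stopifnot(inherits(cohort, "family_cohort"))
  tie_break <- match.arg(tie_break)
  rel <- cohort$relatives
  if (anyNA(rel$birth)) {
    stop("relatives with missing birth dates; run impute_birth_dates() first")
  }
  entry <- pmax(cohort_start, rel$birth)
  censor <- pmin(rel$other_cancer, rel$death, rel$questionnaire,
                 rel$birth + max_age, na.rm = TRUE)
  exit <- pmin(rel$breast_cancer, censor, na.rm = TRUE)
  event <- if (tie_break == "event_first") {
    !is.na(rel$breast_cancer) & rel$breast_cancer <= censor
  } else {
    !is.na(rel$breast_cancer) & rel$breast_cancer < censor
  }
  reason <- rep(NA_character_, nrow(rel))
  reason[exit <= entry] <- "no_at_risk_time"
  reason[rel$birth < min_birth_year] <- "pre_1890_birth"
  keep <- is.na(reason)
  out <- data.frame(
    family_id = rel$family_id[keep],
    person_id = rel$person_id[keep],
    role = rel$role[keep],
    entry_age = entry[keep] - rel$birth[keep],
    exit_age = exit[keep] - rel$birth[keep],
    entry_date = entry[keep],
    exit_date = exit[keep],
    event = event[keep]
  )
  excl <- data.frame(person_id = rel$person_id[!keep], reason = reason[!keep])
  attr(out, "exclusions") <- excl
  if (nrow(excl)) {
    message(sprintf("excluded %d relative(s): %s", nrow(excl),
                    paste(sprintf("%s=%d", names(table(excl$reason)), table(excl$reason)),
                          collapse = ", ")))
  }
  out
}

#' Restrict follow-up intervals to an age window
#'
#' The age-window subanalyses follow relatives either from birth up to
#' censoring or age 50 (whichever comes first), or from age 50 to censoring.
#' `under50` caps `exit_age` at 50 and keeps the event only if it occurred at
#' or before the cap; `from50` floors `entry_age` at 50 and keeps events
#' occurring after 50. The two windows partition each interval's person-time
#' exactly; an event at exactly age 50 is attributed to the `under50` window.
#'
#' @param intervals follow-up data.frame from [derive_follow_up()].
#' @param window one of `"full"`, `"under50"`, `"from50"`.
#' @param cut age cut point, default 50.
#' @return the clipped intervals; rows with non-positive clipped length are
#'   dropped.
#' @export
restrict_age_window <- function(intervals, window = c("full", "under50", "from50"),
                                cut = 50) {
  window <- match.arg(window)
  if (window == "full") return(intervals)
  x <- intervals
  if (window == "under50") {
    new_exit <- pmin(x$exit_age, cut)
    x$event <- x$event & x$exit_age <= cut
    x$exit_date <- x$entry_date + (new_exit - x$entry_age)
    x$exit_age <- new_exit
  } else {
    new_entry <- pmax(x$entry_age, cut)
    x$event <- x$event & x$exit_age > cut
    x$entry_date <- x$entry_date + (new_entry - x$entry_age)
    x$entry_age <- new_entry
  }
  x[x$exit_age > x$entry_age, , drop = FALSE]
}
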