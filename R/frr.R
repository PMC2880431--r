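.z <- function(conf_level) stats::qnorm(1 - (1 - conf_level) / 2)

new_frr_estimate <- function(label, observed, expected, robust_se, n_families,
                             conf_level = 0.95) {
  frr <- observed / expected
  if (observed == 0) {
    # zero-event stratum: exact Poisson upper bound 3.69/E (97.5% one-sided)
    ci_lo <- 0
    ci_hi <- 3.69 / expected
    robust_se <- NA_real_
  } else {
    z <- .z(conf_level)
    ci_lo <- exp(log(frr) - z * robust_se)
    ci_hi <- exp(log(frr) + z * robust_se)
  }
  structure(list(label = label, observed = observed, expected = expected,
                 frr = frr, robust_se = robust_se,
                 ci_lo = ci_lo, ci_hi = ci_hi,
                 conf_level = conf_level, n_families = n_families),
            class = "frr_estimate")
}

#' @export
print.frr_estimate <- function(x, ...) {
  cat(sprintf("FRR [%s]: O = %d, E = %.2f, FRR = %.2f (%d%% CI %.2f - %.2f), %s families\n",
              x$label, x$observed, x$expected, x$frr,
              round(100 * x$conf_level), x$ci_lo, x$ci_hi,
              ifelse(is.na(x$n_families), "?", x$n_families)))
  invisible(x)
}

#' @export
as.data.frame.frr_estimate <- function(x, ...) {
  data.frame(label = x$label, observed = x$observed, expected = x$expected,
             frr = x$frr, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
             robust_se = x$robust_se, n_families = x$n_families)
}

#' Familial relative risk from pre-tabulated observed and expected counts
#'
#' The point estimate FRR = O/E; useful for reproducing published tables
#' where only the counts are printed. No robust standard error is available
#' on this route, so confidence limits are Poisson-based unless `robust_se`
#' is supplied.
#'
#' @param observed integer observed breast cancers O.
#' @param expected expected count E > 0.
#' @param label stratum label.
#' @param robust_se optional robust SE of log(FRR).
#' @param conf_level confidence level, default 0.95.
#' @return an `frr_estimate`.
#' @examples
#' frr_from_counts(1079, 606.06)  # FRR 1.78
#' @export
frr_from_counts <- function(observed, expected, label = "all", robust_se = NULL,
                            conf_level = 0.95) {
  if (expected <= 0) stop("expected count must be positive")
  se <- if (!is.null(robust_se)) robust_se else if (observed > 0) 1 / sqrt(observed) else NA_real_
  new_frr_estimate(label, observed, expected, se, NA_integer_, conf_level)
}

#' Pool familial relative risk estimates by summing counts
#'
#' Observed and expected counts are additive across disjoint strata (e.g.
#' mothers + sisters reproduce the all-relatives row exactly), so pooling
#' sums O and E and recomputes the ratio. Robust variances are pooled on the
#' score scale when all inputs carry per-family score sums.
#'
#' @param ... `frr_estimate` objects over disjoint sets of relatives.
#' @param label label for the pooled estimate.
#' @return an `frr_estimate`.
#' @export
pool_frr <- function(..., label = "pooled") {
  ests <- list(...)
  stopifnot(length(ests) > 0, all(vapply(ests, inherits, TRUE, "frr_estimate")))
  O <- sum(vapply(ests, `[[`, 0, "observed"))
  E <- sum(vapply(ests, `[[`, 0, "expected"))
  ss <- vapply(ests, function(e) if (is.null(e$score_sq)) NA_real_ else e$score_sq, 0)
  nf <- vapply(ests, `[[`, 0L, "n_families")
  se <- if (!anyNA(ss) && O > 0) sqrt(sum(ss)) / O else if (O > 0) 1 / sqrt(O) else NA_real_
  out <- new_frr_estimate(label, O, E, se, if (anyNA(nf)) NA_integer_ else sum(nf))
  out
}

#' Estimate the familial relative risk from follow-up intervals
#'
#' FRR is the ratio of the observed number of breast cancers in relatives to
#' the number expected from reference age- and period-specific incidence
#' rates applied to their person-time (a standardized-incidence-ratio-style
#' estimator). Because several relatives of the same index case share
#' familial risk factors, the variance treats each family as an independent
#' cluster: with per-family observed o_f and expected e_f, the sandwich
#' variance of log(FRR) is sum_f (o_f - FRR e_f)^2 / O^2 (the cluster-score
#' form of the one-parameter Poisson SIR model). Confidence limits are
#' computed on the log scale and exponentiated.
#'
#' @param intervals follow-up data.frame from [derive_follow_up()] (columns
#'   `family_id`, `entry_age`, `exit_age`, `entry_date`, `event`).
#' @param table a [rate_table()].
#' @param label stratum label attached to the estimate.
#' @param conf_level confidence level, default 0.95.
#' @param out_of_coverage policy for follow-up outside the rate grid; see
#'   [clip_to_coverage()].
#' @return an `frr_estimate`: observed, expected, FRR, robust SE, CI and
#'   family count.
#' @export
estimate_frr <- function(intervals, table, label = "all", conf_level = 0.95,
                         out_of_coverage = c("error", "truncate")) {
  out_of_coverage <- match.arg(out_of_coverage)
  if (!nrow(as.data.frame(intervals))) stop("no follow-up intervals")
  x <- clip_to_coverage(intervals, table, out_of_coverage)
  segs <- expand_lexis(x, table)
  E <- expected_count(segs)
  if (E <= 0) stop("expected count is zero; FRR undefined")
  O <- sum(x$event)
  fam <- unique(as.character(x$family_id))
  e_f <- tapply(segs$person_years * segs$rate, factor(as.character(segs$family_id), fam), sum)
  e_f[is.na(e_f)] <- 0
  o_f <- tapply(as.numeric(x$event), factor(as.character(x$family_id), fam), sum)
  frr <- O / E
  score_sq <- sum((o_f - frr * e_f)^2)
  se <- if (O > 0) sqrt(score_sq) / O else NA_real_
  out <- new_frr_estimate(label, O, E, se, length(fam), conf_level)
  out$score_sq <- score_sq
  out
}

#' Wald test for heterogeneity of two familial relative risks
#'
#' Two-sided test of equality of log-FRRs between strata assumed to come
#' from disjoint families, using the combined cluster-robust variance.
#'
#' @param a,b `frr_estimate` objects carrying robust SEs.
#' @return list with `labels`, `statistic` (z), `p_value`.
#' @export
test_frr_heterogeneity <- function(a, b) {
  stopifnot(inherits(a, "frr_estimate"), inherits(b, "frr_estimate"))
  v <- a$robust_se^2 + b$robust_se^2
  if (is.na(v) || v <= 0) stop("zero or missing robust variance; cannot test")
  z <- (log(a$frr) - log(b$frr)) / sqrt(v)
  list(labels = c(a$label, b$label), statistic = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Nelson-Aalen cumulative hazard over attained age
#'
#' Standard left-truncated Nelson-Aalen estimator on the age axis: a
#' relative is at risk at age t if she entered follow-up before t and exited
#' at or after t; at each distinct event age the increment is d/n with
#' variance increment d/n^2 (simultaneous events are a single increment).
#'
#' @param intervals follow-up data.frame (`entry_age`, `exit_age`, `event`).
#' @return data.frame of class `cumhaz_curve` with columns `age`, `cumhaz`,
#'   `variance`; zero rows when there are no events.
#' @export
nelson_aalen <- function(intervals) {
  x <- as.data.frame(intervals)
  times <- sort(unique(x$exit_age[x$event]))
  if (!length(times)) {
    out <- data.frame(age = numeric(), cumhaz = numeric(), variance = numeric())
    class(out) <- c("cumhaz_curve", "data.frame")
    return(out)
  }
  entry_s <- sort(x$entry_age)
  exit_s <- sort(x$exit_age)
  # at risk at t: entry < t <= exit
  n_risk <- findInterval(times, entry_s, left.open = TRUE) -
    findInterval(times, exit_s, left.open = TRUE)
  d <- vapply(times, function(t) sum(x$event & x$exit_age == t), 0)
  out <- data.frame(age = times,
                    cumhaz = cumsum(d / n_risk),
                    variance = cumsum(d / n_risk^2))
  class(out) <- c("cumhaz_curve", "data.frame")
  out
}

#' Subtype-stratified familial relative risk report
#'
#' Runs the full analysis grid: for each relative role (all relatives,
#' mothers, sisters), each marker stratum of the chosen grouping, each
#' follow-up age window of the relative, and each index-case diagnosis-age
#' stratum, relatives inherit their proband's tumour classification and an
#' O/E estimate with cluster-robust CI is produced. Relatives of probands
#' with missing grouping markers are omitted from marker-specific strata but
#' retained in the `"all"` stratum (so `"all"` can exceed the sum of the
#' marker strata).
#'
#' @param cohort a `family_cohort` (birth dates imputed where missing).
#' @param table a [rate_table()].
#' @param grouping one of `"ER"`, `"PR"`, `"HER2"`, `"ERxPR"`, `"luminal"`.
#' @param windows relative-age follow-up windows to run, subset of
#'   `c("full", "under50", "from50")`.
#' @param index_age index-case diagnosis-age strata, subset of
#'   `c("any", "under50", "from50")`.
#' @param roles relative roles, subset of `c("all", "mother", "sister")`.
#' @param out_of_coverage see [clip_to_coverage()].
#' @return data.frame with one row per (role x stratum x window x index-age)
#'   cell: observed, expected, FRR, CI bounds, robust SE, family count.
#'   Empty strata are reported with `observed = 0` and `NA` FRR rather than
#'   an error.
#' @export
run_subtype_analysis <- function(cohort, table,
                                 grouping = c("ER", "PR", "HER2", "ERxPR", "luminal"),
                                 windows = "full", index_age = "any",
                                 roles = c("all", "mother", "sister"),
                                 out_of_coverage = c("error", "truncate")) {
  grouping <- match.arg(grouping)
  out_of_coverage <- match.arg(out_of_coverage)
  windows <- match.arg(windows, c("full", "under50", "from50"), several.ok = TRUE)
  index_age <- match.arg(index_age, c("any", "under50", "from50"), several.ok = TRUE)
  roles <- match.arg(roles, c("all", "mother", "sister"), several.ok = TRUE)

  pro <- cohort$probands
  strata <- switch(grouping,
    ER = list(all = rep(TRUE, nrow(pro)),
              "ER-negative" = pro$er == "negative",
              "ER-positive" = pro$er == "positive"),
    PR = list(all = rep(TRUE, nrow(pro)),
              "PR-negative" = pro$pr == "negative",
              "PR-positive" = pro$pr == "positive"),
    HER2 = list(all = rep(TRUE, nrow(pro)),
                "HER2-negative" = pro$her2 == "negative",
                "HER2-positive" = pro$her2 == "positive"),
    ERxPR = list(all = rep(TRUE, nrow(pro)),
                 "ER+PR+" = pro$er == "positive" & pro$pr == "positive",
                 "ER-PR+" = pro$er == "negative" & pro$pr == "positive",
                 "ER+PR-" = pro$er == "positive" & pro$pr == "negative",
                 "ER-PR-" = pro$er == "negative" & pro$pr == "negative"),
    luminal = {
      s <- as.character(pro$subtype)
      list(all = rep(TRUE, nrow(pro)),
           luminal = s %in% c("luminal", "luminal_her2pos", "luminal_her2neg"),
           "luminal HER2+" = s == "luminal_her2pos",
           "luminal HER2-" = s == "luminal_her2neg",
           "non-luminal HER2+" = s == "nonluminal_her2pos",
           "TN" = s == "triple_negative")
    })

  iv_full <- suppressMessages(derive_follow_up(cohort))
  rows <- list()
  for (ia in index_age) {
    fam_ia <- switch(ia,
      any = pro$family_id,
      under50 = pro$family_id[pro$age_at_diagnosis < 50],
      from50 = pro$family_id[pro$age_at_diagnosis >= 50])
    for (w in windows) {
      iv_w <- restrict_age_window(iv_full, w)
      for (s in names(strata)) {
        fams <- intersect(pro$family_id[strata[[s]]], fam_ia)
        for (r in roles) {
          iv <- iv_w[iv_w$family_id %in% fams, , drop = FALSE]
          if (r != "all") iv <- iv[iv$role == r, , drop = FALSE]
          base <- data.frame(role = r, stratum = s, window = w, index_age = ia)
          if (!nrow(iv)) {
            rows[[length(rows) + 1L]] <- cbind(base, observed = 0L, expected = NA_real_,
                                               frr = NA_real_, ci_lo = NA_real_,
                                               ci_hi = NA_real_, robust_se = NA_real_,
                                               n_families = 0L)
            next
          }
          est <- estimate_frr(iv, table, label = s, out_of_coverage = out_of_coverage)
          rows[[length(rows) + 1L]] <- cbind(base, as.data.frame(est)[-1])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
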