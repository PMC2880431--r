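test_that("O/E point estimates reproduce published worked examples", {
  # published observed/expected pairs and their 2-dp FRRs
  cases <- data.frame(
    O = c(1079, 121, 558, 663, 416, 48, 84, 37),
    E = c(606.06, 68.06, 306.17, 398.81, 207.25, 16.24, 45.09, 22.97),
    frr = c(1.78, 1.78, 1.82, 1.66, 2.01, 2.96, 1.86, 1.61)
  )
  for (i in seq_len(nrow(cases))) {
    expect_equal(round(frr_from_counts(cases$O[i], cases$E[i])$frr, 2), cases$frr[i])
  }
  expect_equal(frr_from_counts(50, 50)$frr, 1)
  expect_error(frr_from_counts(10, 0), "positive")
})

test_that("pooling mothers and sisters reproduces the all-relatives estimate", {
  mothers <- frr_from_counts(663, 398.81, "mothers")
  sisters <- frr_from_counts(416, 207.25, "sisters")
  all_rel <- pool_frr(mothers, sisters, label = "all")
  expect_equal(all_rel$observed, 1079)
  expect_equal(all_rel$expected, 606.06)
  expect_equal(round(all_rel$frr, 2), 1.78)
})

test_that("cluster-robust variance follows the per-family score form", {
  rt <- flat_table(1e-2, age_breaks = c(0, 85), period_breaks = c(1960, 2010))
  iv <- data.frame(
    family_id = c("f1", "f1", "f2", "f3"),
    person_id = c("a", "b", "c", "d"),
    entry_age = c(30, 32, 40, 50),
    exit_age = c(50, 40, 60, 70),
    entry_date = c(1970, 1972, 1970, 1970),
    event = c(TRUE, FALSE, TRUE, FALSE)
  )
  est <- estimate_frr(iv, rt)
  # hand computation: e_f = 0.01 * family person-years
  e_f <- c(f1 = 0.28, f2 = 0.20, f3 = 0.20)
  o_f <- c(f1 = 1, f2 = 1, f3 = 0)
  frr <- 2 / 0.68
  expect_equal(est$frr, frr)
  expect_equal(est$robust_se, sqrt(sum((o_f - frr * e_f)^2)) / 2)
  expect_equal(est$n_families, 3L)
  expect_equal(unname(est$ci_lo), exp(log(frr) - qnorm(0.975) * est$robust_se))

  # zero-event stratum: FRR 0 with the exact Poisson upper bound
  iv0 <- transform(iv, event = FALSE)
  est0 <- estimate_frr(iv0, rt)
  expect_equal(est0$frr, 0)
  expect_equal(est0$ci_hi, 3.69 / 0.68)
})

test_that("heterogeneity test is a two-sided Wald test on log FRRs", {
  a <- frr_from_counts(100, 60, "x", robust_se = 0.1)
  b <- frr_from_counts(120, 72, "y", robust_se = 0.15)
  expect_equal(test_frr_heterogeneity(a, b)$p_value, 1)  # identical FRRs
  c2 <- frr_from_counts(150, 60, "z", robust_se = 0.1)
  ht <- test_frr_heterogeneity(a, c2)
  expect_equal(ht$statistic, (log(100 / 60) - log(2.5)) / sqrt(0.01 + 0.01))
  expect_lt(ht$p_value, 1)
  a$robust_se <- NA_real_
  expect_error(test_frr_heterogeneity(a, b), "variance")
})

test_that("heterogeneity test attains nominal size and decent power", {
  rt <- default_rates()
  sim_est <- function(lambda, seed, n = 800) {
    cfg <- simulation_config(n, rates = rt, lambda = lambda, seed = seed)
    co <- impute_birth_dates(simulate_cohort(cfg)$cohort)
    estimate_frr(suppressMessages(derive_follow_up(co)), rt)
  }
  # size under the null of equal FRRs (modest replicate count keeps the suite
  # fast; the binomial band below is matched to it)
  reps <- 60
  pv <- vapply(seq_len(reps), function(i) {
    test_frr_heterogeneity(sim_est(1.5, 10000 + i), sim_est(1.5, 20000 + i))$p_value
  }, 0)
  size <- mean(pv < 0.05)
  expect_lt(abs(size - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
  # power for a 2x FRR difference with large cohorts
  pw <- vapply(1:10, function(i) {
    test_frr_heterogeneity(sim_est(1.5, 30000 + i, 2000),
                           sim_est(3.0, 40000 + i, 2000))$p_value < 0.05
  }, NA)
  expect_gt(mean(pw), 0.8)
})

test_that("Nelson-Aalen estimator honours left truncation and ties", {
  # hand-enumerated risk sets with staggered entry:
  # events at ages 50 (n at risk = 2: a entered 30, b entered 45; c enters 55)
  # and 60 (n = 2: b exited 52, c at risk, d at risk)
  iv <- data.frame(
    entry_age = c(30, 45, 55, 40),
    exit_age = c(50, 52, 60, 60),
    event = c(TRUE, FALSE, TRUE, TRUE)
  )
  na <- nelson_aalen(iv)
  expect_equal(na$age, c(50, 60))
  expect_equal(na$cumhaz, c(1 / 3, 1 / 3 + 2 / 2))  # at 50: a,b,d at risk
  expect_equal(na$variance, c(1 / 9, 1 / 9 + 2 / 4))

  # single subject, event at exit
  na1 <- nelson_aalen(data.frame(entry_age = 20, exit_age = 45, event = TRUE))
  expect_equal(na1$cumhaz, 1)
  # two at risk, one event
  na2 <- nelson_aalen(data.frame(entry_age = c(20, 20), exit_age = c(45, 50),
                                 event = c(TRUE, FALSE)))
  expect_equal(na2$cumhaz, 0.5)
  # no events: zero curve, not an error
  expect_equal(nrow(nelson_aalen(data.frame(entry_age = 20, exit_age = 45,
                                            event = FALSE))), 0)
  expect_true(all(diff(na$cumhaz) >= 0))
})

test_that("Nelson-Aalen agrees with the survival package on simulated data", {
  skip_if_not_installed("survival")
  rt <- default_rates()
  cfg <- simulation_config(300, rates = rt, lambda = 2, seed = 5)
  co <- impute_birth_dates(simulate_cohort(cfg)$cohort)
  iv <- suppressMessages(derive_follow_up(co))
  ours <- nelson_aalen(iv)
  sf <- survival::survfit(
    survival::Surv(iv$entry_age, iv$exit_age, iv$event) ~ 1,
    stype = 2, ctype = 1)
  theirs <- cumsum(sf$n.event / sf$n.risk)[sf$n.event > 0]
  expect_equal(ours$cumhaz, unname(theirs), tolerance = 1e-10)
})

test_that("the subtype report has the published layout and stratum logic", {
  rt <- default_rates()
  cfg <- simulation_config(400, rates = rt, lambda = 1.5, seed = 9)
  co <- impute_birth_dates(simulate_cohort(cfg)$cohort)
  rep <- run_subtype_analysis(co, rt, grouping = "ER")
  expect_equal(nrow(rep), 9L)  # 3 strata x 3 roles
  expect_setequal(unique(rep$stratum), c("all", "ER-negative", "ER-positive"))
  # mothers + sisters pool to the all-relatives row
  for (s in unique(rep$stratum)) {
    r <- rep[rep$stratum == s, ]
    expect_equal(r$observed[r$role == "all"],
                 r$observed[r$role == "mother"] + r$observed[r$role == "sister"])
    expect_equal(r$expected[r$role == "all"],
                 r$expected[r$role == "mother"] + r$expected[r$role == "sister"],
                 tolerance = 1e-9)
  }
  # relatives of unknown-ER probands count in "all" only
  all_row <- rep[rep$role == "all", ]
  expect_gt(all_row$expected[all_row$stratum == "all"],
            sum(all_row$expected[all_row$stratum != "all"]))
  # empty stratum reported, not an error
  df <- tiny_family_df()
  co2 <- impute_birth_dates(as_family_cohort(df))
  rep2 <- suppressMessages(run_subtype_analysis(co2, rt, grouping = "HER2",
                                                roles = "all"))
  her2pos <- rep2[rep2$stratum == "HER2-positive", ]
  expect_equal(her2pos$observed, 0L)
  expect_equal(her2pos$n_families, 0L)
})
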