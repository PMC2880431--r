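# independent truth table for the subtype taxonomy: the deciding rules are
# restated per-case rather than derived from the implementation
subtype_oracle <- function(er, pr, her2) {
  if (er == "positive" || pr == "positive") {          # luminal branch
    if (her2 == "positive") return("luminal_her2pos")
    if (her2 == "negative") return("luminal_her2neg")
    return("luminal")
  }
  if (er == "negative" && pr == "negative") {          # non-luminal branch
    if (her2 == "positive") return("nonluminal_her2pos")
    if (her2 == "negative") return("triple_negative")
    return("unclassifiable")
  }
  "unclassifiable"                                     # luminal status undecidable
}

test_that("subtype classification is total and matches the rule table on all 27 combinations", {
  lv <- c("positive", "negative", "unknown")
  grid <- expand.grid(er = lv, pr = lv, her2 = lv, stringsAsFactors = FALSE)
  got <- classify_subtype(grid$er, grid$pr, grid$her2)
  expect_false(anyNA(got))
  want <- mapply(subtype_oracle, grid$er, grid$pr, grid$her2)
  expect_equal(as.character(got), unname(want))
  # spot checks against the published taxonomy
  expect_equal(as.character(classify_subtype("negative", "negative", "negative")),
               "triple_negative")
  expect_equal(as.character(classify_subtype("positive", "negative", "unknown")),
               "luminal")
  expect_equal(as.character(classify_subtype("negative", "negative", "positive")),
               "nonluminal_her2pos")
})

test_that("family table reader validates structure and round-trips", {
  co <- tiny_cohort()
  expect_equal(nrow(co$probands), 3)
  expect_equal(nrow(co$relatives), 3)
  expect_equal(as.character(co$probands$subtype[co$probands$family_id == "A"]), "luminal")

  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_family_table(co, p1)
  co2 <- read_family_table(p1)
  write_family_table(co2, p2)
  expect_identical(readLines(p1), readLines(p2))

  df <- tiny_family_df()
  df$family_id[6] <- "Z"; df$role[6] <- "sister"; df$questionnaire_date[6] <- "2000-01-01"
  expect_error(as_family_cohort(df), "unknown family_id")
  df <- tiny_family_df(); df$person_id[2] <- "A_P"
  expect_error(as_family_cohort(df), "duplicate person_id")
  df <- tiny_family_df(); df$role[3] <- "proband"
  expect_error(as_family_cohort(df), "more than one proband")
  df <- tiny_family_df()[, -4]
  expect_error(as_family_cohort(df), "missing column")
})

test_that("birth-date imputation follows the relationship rule", {
  co <- impute_birth_dates(tiny_cohort())
  rel <- co$relatives
  pro <- co$probands
  # mother B_M had no birth date: proband birth minus 30 years
  b_pro <- pro$birth[pro$family_id == "B"]
  expect_equal(rel$birth[rel$person_id == "B_M"], b_pro - 30)
  expect_true(rel$birth_date_imputed[rel$person_id == "B_M"])
  # known birth dates untouched
  expect_equal(rel$birth[rel$person_id == "A_M"], decimal_year("1925-07-01"))
  expect_false(rel$birth_date_imputed[rel$person_id == "A_M"])

  # sister rule: same birth date as the proband
  df <- tiny_family_df()
  df$birth_date[3] <- ""
  co2 <- impute_birth_dates(as_family_cohort(df))
  expect_equal(co2$relatives$birth[co2$relatives$person_id == "A_S1"],
               co2$probands$birth[co2$probands$family_id == "A"])
})

test_that("follow-up derivation applies entry, censoring and exclusion rules", {
  mk <- function(birth, bc = "", oth = "", death = "", quest = "2000-07-01") {
    df <- tiny_family_df()[c(1, 2), ]
    df$birth_date[2] <- birth; df$breast_cancer_date[2] <- bc
    df$other_cancer_date[2] <- oth; df$death_date[2] <- death
    df$questionnaire_date[2] <- quest
    suppressMessages(derive_follow_up(as_family_cohort(df)))
  }
  # born 1940, no events: enters 1960 at age 20, exits at questionnaire
  iv <- mk("1940-07-01", death = "")
  expect_equal(iv$entry_age, 1960 - decimal_year("1940-07-01"))
  expect_equal(iv$exit_date, decimal_year("2000-07-01"))
  expect_false(iv$event)

  # pre-1890 birth excluded
  iv <- mk("1885-01-01")
  expect_equal(nrow(iv), 0)
  expect_equal(attr(iv, "exclusions")$reason, "pre_1890_birth")

  # breast cancer before cohort start: no at-risk time
  iv <- mk("1930-01-01", bc = "1955-01-01")
  expect_equal(nrow(iv), 0)
  expect_equal(attr(iv, "exclusions")$reason, "no_at_risk_time")

  # event censors follow-up and sets the flag; age-85 cap respected
  iv <- mk("1930-01-01", bc = "1980-01-01", death = "1990-01-01")
  expect_true(iv$event)
  expect_equal(iv$exit_date, 1980)
  iv <- mk("1900-01-01", quest = "1999-01-01")
  expect_equal(iv$exit_age, 85)

  # same-day tie: breast cancer beats death by default, not under censor_first
  df <- tiny_family_df()[c(1, 2), ]
  df$breast_cancer_date[2] <- "1990-05-01"; df$death_date[2] <- "1990-05-01"
  expect_true(suppressMessages(derive_follow_up(as_family_cohort(df)))$event)
  expect_false(suppressMessages(
    derive_follow_up(as_family_cohort(df), tie_break = "censor_first"))$event)
})

test_that("age windows partition person-time and keep the event exactly once", {
  iv <- data.frame(family_id = "A", person_id = "x", role = "sister",
                   entry_age = 20, exit_age = 60, entry_date = 1960,
                   exit_date = 2000, event = TRUE)
  u <- restrict_age_window(iv, "under50")
  f <- restrict_age_window(iv, "from50")
  expect_equal(u$exit_age, 50)
  expect_false(u$event)           # event at 60 is outside the under-50 window
  expect_equal(f$entry_age, 50)
  expect_true(f$event)
  expect_equal((u$exit_age - u$entry_age) + (f$exit_age - f$entry_age),
               iv$exit_age - iv$entry_age)
  expect_identical(restrict_age_window(iv, "full"), iv)

  # interval entirely below the cut: from50 yields nothing
  iv2 <- transform(iv, exit_age = 45, exit_date = 1985)
  expect_equal(nrow(restrict_age_window(iv2, "from50")), 0)

  # property over random intervals: person-time partition is exact and the
  # event lands in exactly one window
  set.seed(11)
  for (k in 1:50) {
    e <- runif(1, 0, 60); x <- e + runif(1, 0.1, 40)
    ivk <- data.frame(family_id = "A", person_id = "x", role = "sister",
                      entry_age = e, exit_age = x, entry_date = 1960 + e,
                      exit_date = 1960 + x, event = runif(1) < 0.5)
    u <- restrict_age_window(ivk, "under50"); f <- restrict_age_window(ivk, "from50")
    py <- sum(u$exit_age - u$entry_age) + sum(f$exit_age - f$entry_age)
    expect_equal(py, ivk$exit_age - ivk$entry_age, tolerance = 1e-12)
    expect_equal(sum(u$event) + sum(f$event), as.integer(ivk$event))
  }
})
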