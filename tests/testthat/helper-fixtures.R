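# shared fixtures, built in code

# one-cell and small rectangular rate tables
one_cell_table <- function(rate = 2.5e-3) {
  rate_table(data.frame(age_lo = 50, age_hi = 55, period_lo = 1990,
                        period_hi = 1995, rate = rate))
}

flat_table <- function(rate = 1e-3, age_breaks = seq(0, 85, 5),
                       period_breaks = seq(1960, 2010, 10)) {
  na <- length(age_breaks) - 1L; np <- length(period_breaks) - 1L
  rate_table(data.frame(
    age_lo = rep(age_breaks[-(na + 1L)], np),
    age_hi = rep(age_breaks[-1L], np),
    period_lo = rep(period_breaks[-(np + 1L)], each = na),
    period_hi = rep(period_breaks[-1L], each = na),
    rate = rate))
}

default_rates <- function() simulate_rate_table()

# a hand-written 3-family cohort covering the main record shapes
tiny_family_df <- function() {
  data.frame(
    family_id = c("A", "A", "A", "B", "B", "C"),
    person_id = c("A_P", "A_M", "A_S1", "B_P", "B_M", "C_P"),
    role = c("proband", "mother", "sister", "proband", "mother", "proband"),
    birth_date = c("1950-01-01", "1925-07-01", "1952-03-15",
                   "1948-06-01", "", "1960-01-01"),
    diagnosis_date = c("1998-01-01", "", "", "2000-06-01", "", "2001-01-01"),
    er = c("positive", "", "", "negative", "", "unknown"),
    pr = c("negative", "", "", "negative", "", "unknown"),
    her2 = c("unknown", "", "", "negative", "", "unknown"),
    breast_cancer_date = c("", "1990-05-01", "", "", "", ""),
    other_cancer_date = c("", "", "", "", "", ""),
    death_date = c("", "1995-01-01", "", "", "1985-03-01", ""),
    questionnaire_date = c("2000-01-01", "2000-01-01", "2000-01-01",
                           "2002-01-01", "2002-01-01", "2003-01-01")
  )
}

tiny_cohort <- function() as_family_cohort(tiny_family_df())

# independent 9-pair enumeration oracle for the locus FRR (kept deliberately
# naive: explicit loop over parent genotype, transmitted allele, population
# allele)
locus_frr_enum <- function(p, r1, r2) {
  q <- 1 - p
  g <- c(q^2, 2 * p * q, p^2)
  R <- c(1, r1, r2)
  mu <- sum(g * R)
  num <- 0
  for (k in 0:2) for (tr in 0:1) for (pop in 0:1) {
    ptr <- if (tr == 1) k / 2 else 1 - k / 2
    ppop <- if (pop == 1) p else q
    num <- num + g[k + 1] * ptr * ppop * R[k + 1] * R[tr + pop + 1]
  }
  num / mu^2
}

# sibling-kinship oracle via full enumeration over both parents' genotypes
# and the four ordered transmission patterns per child
locus_frr_sib_enum <- function(p, r1, r2) {
  q <- 1 - p
  g <- c(q^2, 2 * p * q, p^2)
  R <- c(1, r1, r2)
  mu <- sum(g * R)
  num <- 0
  for (kf in 0:2) for (km in 0:2) {
    pf <- c(1 - kf / 2, kf / 2)   # transmit 0 or 1 copies
    pm <- c(1 - km / 2, km / 2)
    for (a1 in 0:1) for (b1 in 0:1) for (a2 in 0:1) for (b2 in 0:1) {
      pr <- pf[a1 + 1] * pm[b1 + 1] * pf[a2 + 1] * pm[b2 + 1]
      num <- num + g[kf + 1] * g[km + 1] * pr * R[a1 + b1 + 1] * R[a2 + b2 + 1]
    }
  }
  num / mu^2
}

# the published 12-locus panel with per-subtype FRR* and %FRR reference values
published_locus_panel <- function() {
  loci <- read_locus_table()
  loci$frr_erneg <- c(1.0016, 1.0036, 1.0009, 1.0003, 1.0004, 1.0008,
                      1.0002, 1.0004, 1.0018, 1.0003, 1.0005, 1.0001)
  loci$pct_erneg <- c(0.28, 0.63, 0.16, 0.05, 0.07, 0.15, 0.03, 0.07,
                      0.31, 0.05, 0.09, 0.01)
  loci$frr_erpos <- c(1.0186, 1.0089, 1.0028, 1.0038, 1.0010, 1.0031,
                      1.0008, 1.0013, 1.0043, 1.0078, 1.0024, 1.0027)
  loci$pct_erpos <- c(3.08, 1.48, 0.46, 0.63, 0.17, 0.52, 0.13, 0.21,
                      0.72, 1.30, 0.40, 0.46)
  loci
}

# small gene spec used across major-gene tests: flat yearly hazards,
# two subtypes
toy_gene_spec <- function(f = 0.005, rr = 10, p_s_carrier = 0.8,
                          p_s_noncarrier = 0.2, base = 1e-3, ages = 20:79) {
  h_nc <- rep(base, length(ages))
  h_c <- rep(base * rr, length(ages))
  major_gene_spec(f, ages,
    hazard_carrier = cbind(s = h_c * p_s_carrier, other = h_c * (1 - p_s_carrier)),
    hazard_noncarrier = cbind(s = h_nc * p_s_noncarrier, other = h_nc * (1 - p_s_noncarrier)))
}

uniform_weights <- function(ages = 30:60) normalize_weights(ages, rep(1, length(ages)))
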