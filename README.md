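# frrcohort

Familial relative risk (FRR) of breast cancer by tumour subtype: cohort
estimation, and models for how much of the familial risk known susceptibility
variants explain.

First-degree relatives of breast-cancer patients have roughly twice the
breast-cancer incidence of the general population, but breast cancer is
heterogeneous: tumours split by estrogen receptor (ER), progesterone receptor
(PR) and HER2 status into luminal, HER2-positive and triple-negative
subtypes with different genetic architectures. `frrcohort` is for
genetic-epidemiology analyses that ask: *how does the FRR depend on the
subtype of the index case, and how much of it do known genes explain?* It
provides:

- **A person-years cohort FRR estimator.** Relatives' follow-up is derived
  from questionnaire family histories (entry at the 1960 cohort start,
  censoring at any cancer, death, questionnaire or age 85), split over an
  age × calendar-period reference incidence grid (Lexis expansion), and the
  FRR is estimated as the standardized incidence ratio FRR = O/E with
  family-clustered robust standard errors:
  Var(log FRR) = Σ_f (o_f − FRR·e_f)² / O².
- **A locus-contribution calculator.** For a biallelic variant with risk
  allele frequency *p* and genotypic relative risks *r₁*, *r₂*, the
  first-degree FRR attributable to the locus is
  λ\* = E[R_proband·R_relative] / E[R]² under Hardy–Weinberg genotype
  frequencies and Mendelian transmission, and its share of the overall FRR
  λ₀ is 100·log λ\*/log λ₀ (multiplicative model) or
  100·(λ\*−1)/(λ₀−1) (additive model).
- **A single-locus major-gene model** (dominant, BRCA-like): genotype- and
  subtype-specific penetrance curves give the age-specific FRR(t) as a
  ratio of carrier-weighted risks, age-averaged with case-incidence
  weights, including subtype-specific FRRs under genotype-driven pathology
  concordance.
- **A synthetic-cohort generator** with known ground truth (constant
  familial effect, explicit locus, or major gene) so the whole pipeline is
  testable closed-loop.

## Worked example

Estimate the FRR on a simulated cohort with a known two-fold familial
effect, then ask how much of an FRR of 1.82 the FGFR2 locus explains:

```r
library(frrcohort)

rates <- simulate_rate_table()                     # synthetic reference rates
cfg <- simulation_config(2000, rates = rates, lambda = 2, seed = 7)
cohort <- impute_birth_dates(simulate_cohort(cfg)$cohort)
intervals <- derive_follow_up(cohort)
estimate_frr(intervals, rates)
#> FRR [all]: O = 256, E = 124.42, FRR = 2.06 (95% CI 1.82 - 2.33), 1927 families

# subtype-stratified report (relatives inherit the proband's ER status)
head(run_subtype_analysis(cohort, rates, grouping = "ER"), 3)

# locus contribution: FGFR2, ER-positive disease
lam <- locus_frr(p = 0.38, r1 = 1.28, r2 = 1.74)
round(lam, 4)
#> [1] 1.0186
round(pct_frr_multiplicative(lam, lambda0 = 1.82), 2)
#> [1] 3.08     # percent of the ER-positive FRR explained by this locus

# the full 12-locus panel shipped with the package
tab <- build_locus_table(read_locus_table())
round(attr(tab, "totals")$add_erpos, 1)
#> [1] 7        # additive-model total, percent of the ER-positive excess FRR
```

So the single FGFR2 variant accounts for about 3% of the ER-positive
familial risk under the multiplicative model, and the whole 12-locus panel
for about 7% of the excess ER-positive FRR under the additive model.

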