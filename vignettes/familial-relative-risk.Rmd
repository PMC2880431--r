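---
title: "Familial relative risk by tumour subtype: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial relative risk by tumour subtype: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frrcohort)
```

`frrcohort` estimates the familial relative risk (FRR) of breast cancer to
first-degree relatives of index cases, stratified by the tumour subtype of
the index case, and models the contribution of genetic susceptibility to
that FRR. This vignette is the package's own account of the underlying
models, the choices we made where the methodology was genuinely open, and
what the tests do and do not demonstrate.

## The cohort estimator

The design is a retrospective cohort of relatives. Each index case
(proband) carries ER/PR/HER2 immunohistochemical marker status; her mother
and sisters are followed from the later of 1 January 1960 (registry rates
before then are unreliable) and their birth, to the earliest of: any cancer
diagnosis, death, completion of the family-history questionnaire, or age
85. Relatives born before 1890 are excluded. Missing relative birth dates
are imputed from the relationship: mothers are assigned a birth 30 years
before the proband's, sisters the proband's own birth date. Because subtype
is observed only in the proband, a "subtype-specific" FRR here means the
risk of breast cancer *of any type* to relatives of a proband with that
subtype.

The FRR is a standardized incidence ratio: follow-up is split at every
age-band and calendar-period boundary of a reference incidence table
(Lexis expansion along the 45° life line; person-years are conserved
exactly, which the tests assert to 1e-9 years), the expected count is
E = Σ person-years × rate, and FRR = O/E.

Dates are decimal years throughout (ISO dates via day-count/365.25; bare
years read as July 1), and all grid intervals are half-open `[lo, hi)`, so
person-years arithmetic has no boundary ambiguity. Out-of-coverage
follow-up is an error by default with an explicit `truncate` option —
silent truncation hides data problems.

### Variance and tests

Relatives of the same proband share unmodelled familial risk, so the
variance treats the family as the sampling unit. We use the cluster-score
(sandwich) form for the one-parameter Poisson SIR model: with per-family
observed and expected counts $o_f, e_f$,

$$\widehat{\mathrm{Var}}(\log \widehat{FRR}) = \frac{\sum_f (o_f -
\widehat{FRR}\, e_f)^2}{O^2},$$

with confidence limits computed on the log scale and exponentiated.
Published tables of this kind report near-symmetric intervals, suggesting
an identity-scale construction; the log scale is preferable for a ratio
bounded below by zero, and simulation shows 94–95% coverage at the study's
scale (200 null replicates of 5,000 families in the test suite), so we do
not attempt to reproduce printed confidence intervals digit-for-digit.
Strata with zero events report FRR 0 with the exact Poisson one-sided upper
bound 3.69/E rather than a degenerate log-scale interval. Heterogeneity
between two strata is a two-sided Wald test on the difference of log-FRRs
with the combined robust variance; it assumes the strata come from disjoint
families, which holds for marker-specific strata but not for comparisons
against the "all cases" row.

Ties at the censoring date are broken in favour of the breast-cancer event
(`tie_break = "event_first"`), the conservative convention for an O/E
numerator; it is configurable. In the age-window subanalyses (`under50`,
`from50`) an event at exactly age 50 belongs to the under-50 window, and
the two windows partition each relative's person-time exactly.

The Nelson–Aalen estimator on the age axis honours left truncation (a
relative is at risk at age *t* if she entered before *t* and exited at or
after *t*); simultaneous events at one age are a single d/n increment. It
is cross-checked in the tests against `survival::survfit`.

## The locus-contribution model

For a biallelic susceptibility variant with listed-allele frequency $p$
(taken as listed, whether or not it is truly minor) and genotypic relative
risks $r_1, r_2$ relative to the common homozygote, the FRR attributable to
the locus is defined constructively as

$$\lambda^* = \frac{E[R_{proband} R_{relative}]}{E[R]^2},$$

with genotypes in Hardy–Weinberg proportions $(q^2, 2pq, p^2)$ and the
proband–relative joint genotype distribution given by Mendelian
transmission: for the default `offspring` kinship the relative inherits one
allele drawn from the proband's pair and one from the population; `sibling`
kinship draws both children from the same two Hardy–Weinberg parents and
therefore adds a dominance-variance term ($\lambda^*_{sib} \ge
\lambda^*_{off}$, with equality iff risks are allele-additive). We apply the
offspring form to all first-degree relatives, as analyses of this kind
conventionally do. A Cauchy–Schwarz argument gives $\lambda^* \ge 1$ for
*any* risks — including protective alleles — with equality only for a null
locus; the tests verify this, the allele-relabelling invariance
$(p, r_1, r_2) \to (1-p, r_1/r_2, 1/r_2)$, and exact agreement (to 1e-12)
with an independent nine-pair transmission enumeration on 10⁴ random draws.

The percent of the overall FRR $\lambda_0$ attributed to the locus is
$100 \log\lambda^* / \log\lambda_0$ if susceptibility factors combine
multiplicatively on risk, or $100 (\lambda^*-1)/(\lambda_0-1)$ of the
excess FRR under an additive model. Natural logs; the ratio is base
invariant. `build_locus_table()` evaluates a panel of loci against
per-subtype $\lambda_0$ (defaults 1.78 for ER-negative, 1.82 for
ER-positive index cases, the cohort-scale estimates such panels are quoted
against). Its multiplicative "total" row follows the convention of
published tables — the sum of the per-locus percentages as displayed, i.e.
rounded to 2 dp — with the unrounded sum attached alongside; additive
totals are computed from unrounded $\lambda^*$. The packaged
`susceptibility_loci.csv` carries twelve published GWAS loci with
per-subtype heterozygote/homozygote odds ratios.

## The major-gene model

For rare, high-penetrance genes the multiplicative SNP machinery is
replaced by an explicit Mendelian model, deliberately reduced to one gene
at a time (no polygenic background, no second locus): a biallelic locus
with deleterious-allele frequency $f$, dominant carrier status, and yearly
penetrance hazards per genotype and tumour subtype. Cumulative incidence
uses the discrete product $F_s(t) = \sum_{u<t} h_s(u)\prod_{v<u}(1 -
h_{tot}(v))$, so subtype cumulative incidences sum to the genotype total by
construction. The proband–relative carrier joint distribution is the exact
biallelic enumeration collapsed to carrier status — not the rare-allele
half-kinship shortcut, which is only checked against it in tests (they
agree as $f \to 0$).

The age-specific FRR to a relative at age $t$ of a proband with subtype
$s$ is the likelihood ratio

$$FRR(t) = \frac{\sum_{g_p,g_r} P(g_p,g_r)\, A_s(g_p)\, F_{g_r}(t)}
{\sum_{g_p} P(g_p) A_s(g_p)\; \cdot\; \sum_g P(g) F_g(t)},$$

where $A_s(g)$ is the proband's probability of presenting with subtype $s$
given genotype $g$. By default $A_s$ averages the yearly diagnosis density
$h_{g,s}(a) S_g(a)$ over a case-age weight distribution (the incidence-shaped
weights from `case_age_weights()`, conventionally ages 20–70); a fixed
diagnosis age is available and is what the forward Monte-Carlo cross-check
uses. The overall FRR averages $FRR(t)$ over the *relative's* attained age
with the same case-incidence weights, renormalising over ages where the
population risk is positive (below the first hazard age the ratio is 0/0).
Weighting by the relative's attained age rather than the proband's
diagnosis age is a choice; the two coincide for the flat toy hazards used
in tests and differ little for incidence-shaped weights.

`subtype_specific_frr()` restricts both the proband's and the relative's
events to subtype $s$ — the FRR that would be observed if pathology
concordance between relatives were driven by genotype alone. When the
subtype mix is genotype-independent it collapses to the overall FRR
(asserted to 1e-10), and for a carrier-enriched subtype it exceeds the
any-subtype FRR, reproducing the qualitative ordering reported for
BRCA1-like genes and ER-negative disease. The packaged
`brca1_like_synthetic.json` is an illustrative configuration with
published-order-of-magnitude values (carrier frequency ~0.1%, carrier
hazards 8–15× population, carrier tumours 75% ER-negative); it is labelled
synthetic because the penetrance and frequency inputs used by fitted
pedigree models are not printed in the literature this package draws on,
so gene-attribution percentages computed from it are demonstrations, not
reproductions.

## The synthetic-data generator

Closed-loop testing needs cohorts with known truth. `simulate_cohort()`
emulates the study structure: probands diagnosed in a 1991–2004 recruitment
window (diagnosis ages drawn from the incidence-shaped case-age
distribution, 25–69), a mother and on average one sister per proband,
family questionnaires in 1996–2005, Gompertz mortality, and breast-cancer
event times drawn by exact inversion of the piecewise-constant cumulative
hazard along each relative's life line. Marker positivity and availability
default to the proportions of a large UK case series (81% ER+, observed in
62% of cases, etc.).

Three familial-effect models close different loops:

- `multiplicative`: every relative's hazard is λ × reference. The estimand
  is exactly the FRR the estimator targets; the acceptance tests require
  the mean over 200 null replicates (5,000 families each) to sit in
  1.00 ± 0.02 with 95% ± 3% CI coverage, and λ = 2 recovery within
  [1.9, 2.1].
- `locus`: parents' genotypes are Hardy–Weinberg, children Mendelian, and
  the family is accepted with probability proportional to the proband's
  genotypic risk (case ascertainment). Genotype hazards are normalised by
  the mean population relative risk so the reference table remains the
  population incidence; mothers then recover the offspring-kinship
  $\lambda^*$ and sisters the sibling $\lambda^*$ within Monte-Carlo error,
  closing the loop between the kinship formula and forward simulation.
- `major_gene`: as `locus` with a dominant carrier risk and
  genotype-dependent ER status, used for the qualitative age-by-subtype
  ordering checks.

Events are only simulated over the at-risk window (from 1960 entry to
censoring): pre-1960 incidence is neither simulated nor counted, matching
the estimator's window, so calibration is exact by design. What the
generator does *not* emulate — secular screening trends, reporting error in
family histories, marker misclassification, shared environment — bounds
what the passing tests show about real data: they validate the estimator's
arithmetic and sampling behaviour under the stated model, not robustness to
those biases.

Determinism: a fixed seed and configuration give byte-identical output
files (`families.tsv`, `rates.csv`, `truth.json` via `write_simulation()`).

## Numerical choices and problem sizes

- Half-open intervals everywhere; an age exactly on a band boundary belongs
  to the upper band.
- Lexis segments of zero length are dropped; conservation is exact because
  segment lengths telescope.
- The locus model is evaluated in closed vectorised form and tested against
  the naive enumeration at 1e-12; penetrance arithmetic is plain double
  precision with hazards required to be < 1/year.
- Simulation-based tests use 1,200–6,000 families per replicate and 6–200
  replicates depending on the property, sized so the whole suite runs in a
  few minutes on one CPU while keeping Monte-Carlo error well inside the
  asserted bands; the forward Monte-Carlo cross-check of the major-gene
  FRR uses 10⁶ proband–relative pairs per setting with a 3-standard-error
  criterion.

## Known limitations

- The robust-variance construction and CI scale are one defensible choice
  among several; printed intervals from other software will differ slightly.
- Probands contribute no person-time and daughters are not modelled as
  relatives (closed role set: mother, sister), matching the cohort
  definition this design mirrors.
- Relatives with unknown vital status are censored at the questionnaire
  date regardless; whether "any cancer" should include non-melanoma skin
  cancer is left to the data preparer.
- The locus model ignores linkage disequilibrium between panel loci and
  reports no interval for $\lambda^*$; the major-gene model handles one
  gene at a time and is not a pedigree-likelihood engine for arbitrary
  family structures.
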