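#' Specify a single-locus dominant major-gene model
#'
#' A deliberately reduced Mendelian model for a rare high-penetrance
#' susceptibility gene (BRCA1/BRCA2-like): one biallelic locus, dominant
#' carrier status (one or more copies of the deleterious allele), and
#' genotype-specific age- and subtype-specific penetrance supplied as yearly
#' hazards. Cumulative incidence is computed by the discrete product
#' \eqn{F_s(t) = \sum_{u < t} h_s(u) \prod_{v < u} (1 - h_{tot}(v))}, so the
#' subtype-specific cumulative incidences sum to the genotype's overall
#' cumulative incidence by construction.
#'
#' @param allele_frequency deleterious-allele frequency in (0, 0.5);
#'   realistically well below 0.01 for BRCA-like genes.
#' @param ages integer vector of consecutive year starts (e.g. `20:84`); the
#'   hazard in row k applies to the year `[ages[k], ages[k] + 1)`.
#' @param hazard_carrier,hazard_noncarrier yearly hazards per genotype:
#'   either a numeric vector (single unlabelled subtype) or a matrix with
#'   one column per tumour subtype (columns named, e.g. `ERneg`, `ERpos`);
#'   row sums are the genotype's total hazard and must stay below 1.
#' @return object of class `major_gene_spec` with precomputed survival and
#'   cumulative-incidence grids per genotype.
#' @export
major_gene_spec <- function(allele_frequency, ages, hazard_carrier, hazard_noncarrier) {
  f <- as.numeric(allele_frequency)
  if (length(f) != 1 || is.na(f) || f <= 0 || f >= 0.5) {
    stop("allele_frequency must be a single value in (0, 0.5)")
  }
  ages <- as.numeric(ages)
  if (length(ages) < 1 || any(diff(ages) != 1)) stop("ages must be consecutive year starts")
  as_mat <- function(h) {
    if (is.null(dim(h))) h <- matrix(as.numeric(h), ncol = 1, dimnames = list(NULL, "any"))
    h <- as.matrix(h)
    if (is.null(colnames(h))) colnames(h) <- paste0("subtype", seq_len(ncol(h)))
    if (nrow(h) != length(ages)) stop("hazard rows must match length(ages)")
    if (any(h < 0)) stop("negative hazard")
    if (any(rowSums(h) >= 1)) stop("total yearly hazard must be < 1")
    h
  }
  hc <- as_mat(hazard_carrier)
  hn <- as_mat(hazard_noncarrier)
  if (!identical(colnames(hc), colnames(hn))) stop("carrier and noncarrier subtype columns must match")
  cuminc <- function(h) {
    S <- cumprod(1 - rowSums(h))              # survival just after each year
    S_before <- c(1, S[-length(S)])           # survival entering each year
    Fb <- apply(h * S_before, 2, cumsum)      # cumulative incidence at year ends
    if (!is.matrix(Fb)) Fb <- matrix(Fb, nrow = 1, dimnames = list(NULL, colnames(h)))
    rbind(0, Fb)                              # boundary grid ages[1], ..., max+1
  }
  structure(list(
    f = f, ages = ages, boundaries = c(ages, ages[length(ages)] + 1),
    subtypes = colnames(hc),
    hazard = list(carrier = hc, noncarrier = hn),
    cuminc = list(carrier = cuminc(hc), noncarrier = cuminc(hn))
  ), class = "major_gene_spec")
}

#' @export
print.major_gene_spec <- function(x, ...) {
  ng <- length(x$boundaries)
  cat(sprintf("<major_gene_spec> f = %.4g (carrier freq %.4g), ages %g-%g, subtypes: %s\n",
              x$f, 2 * x$f * (1 - x$f) + x$f^2,
              min(x$ages), max(x$boundaries), paste(x$subtypes, collapse = ", ")))
  cat(sprintf("  cumulative incidence by %g: carrier %.3f, noncarrier %.3f\n",
              max(x$boundaries), sum(x$cuminc$carrier[ng, ]), sum(x$cuminc$noncarrier[ng, ])))
  invisible(x)
}

#' Read a major-gene specification from a JSON or YAML config
#'
#' Expected keys: `allele_frequency`, `ages`, and `hazard` with `carrier`
#' and `noncarrier` sub-maps of subtype-named yearly hazard arrays. The
#' packaged `brca1_like_synthetic.json` is an illustrative configuration
#' with published-order-of-magnitude values; it is synthetic and does not
#' reproduce any fitted pedigree-model inputs.
#'
#' @param path `.json` or `.yaml`/`.yml` file.
#' @return a [major_gene_spec()].
#' @export
read_gene_spec <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  to_mat <- function(lst) do.call(cbind, lapply(lst, as.numeric))
  major_gene_spec(cfg$allele_frequency, cfg$ages,
                  to_mat(cfg$hazard$carrier), to_mat(cfg$hazard$noncarrier))
}

#' Joint carrier-status distribution for a proband-relative pair
#'
#' Exact biallelic parent-offspring (or sibling) joint genotype
#' probabilities under Hardy-Weinberg and Mendelian transmission, collapsed
#' to carrier status (no rare-allele approximation). Rows are the proband,
#' columns the relative; margins equal the Hardy-Weinberg carrier frequency
#' \eqn{2f(1-f) + f^2}.
#'
#' @param f deleterious-allele frequency, or a `major_gene_spec`.
#' @param kinship `"offspring"` (default, = any first-degree parent/child
#'   pair) or `"sibling"`.
#' @return 2x2 matrix with dimnames `noncarrier`/`carrier`.
#' @export
genotype_joint <- function(f, kinship = c("offspring", "sibling")) {
  kinship <- match.arg(kinship)
  if (inherits(f, "major_gene_spec")) f <- f$f
  q <- 1 - f
  G <- c(q^2, 2 * f * q, f^2)
  J3 <- matrix(0, 3, 3)
  if (kinship == "offspring") {
    for (k in 0:2) {
      tr <- k / 2
      J3[k + 1L, ] <- G[k + 1L] * c((1 - tr) * q, (1 - tr) * f + tr * q, tr * f)
    }
  } else {
    for (kf in 0:2) for (km in 0:2) {
      tf <- kf / 2; tm <- km / 2
      child <- c((1 - tf) * (1 - tm), tf * (1 - tm) + (1 - tf) * tm, tf * tm)
      J3 <- J3 + G[kf + 1L] * G[km + 1L] * outer(child, child)
    }
  }
  carrier <- c(FALSE, TRUE, TRUE)
  J <- matrix(0, 2, 2, dimnames = list(proband = c("noncarrier", "carrier"),
                                       relative = c("noncarrier", "carrier")))
  for (i in 1:3) for (j in 1:3) {
    J[carrier[i] + 1L, carrier[j] + 1L] <- J[carrier[i] + 1L, carrier[j] + 1L] + J3[i, j]
  }
  J
}

.cuminc_at <- function(spec, genotype, subtype, t) {
  b <- spec$boundaries
  if (any(t < b[1] | t > b[length(b)])) {
    stop(sprintf("age outside penetrance grid [%g, %g]", b[1], b[length(b)]))
  }
  Fb <- spec$cuminc[[genotype]]
  col <- if (identical(subtype, "any")) rowSums(Fb) else {
    if (!subtype %in% spec$subtypes) stop("unknown subtype: ", subtype)
    Fb[, subtype]
  }
  stats::approx(b, col, xout = t, method = "linear")$y
}

#' Genotype-specific cumulative risk of (subtype-restricted) breast cancer
#'
#' @param spec a [major_gene_spec()].
#' @param genotype `"carrier"` or `"noncarrier"`.
#' @param subtype a subtype name from the spec, or `"any"`.
#' @param t attained age(s) within the penetrance grid.
#' @return cumulative incidence by age `t` (monotone in `t`, 0 at the grid
#'   start).
#' @export
prob_affected_by <- function(spec, genotype = c("carrier", "noncarrier"),
                             subtype = "any", t) {
  stopifnot(inherits(spec, "major_gene_spec"))
  genotype <- match.arg(genotype)
  .cuminc_at(spec, genotype, subtype, t)
}

# P(proband affected with subtype s | genotype), either by a fixed diagnosis
# age or averaged over a case-age weight distribution (yearly diagnosis
# probability h_s(a) * S(a)).
.proband_affection <- function(spec, proband_subtype, weights, proband_age) {
  sapply(c("noncarrier", "carrier"), function(g) {
    if (!is.null(proband_age)) {
      .cuminc_at(spec, g, proband_subtype, proband_age)
    } else {
      h <- spec$hazard[[g]]
      dens_s <- if (identical(proband_subtype, "any")) rowSums(h) else h[, proband_subtype]
      S_before <- c(1, cumprod(1 - rowSums(h))[-nrow(h)])
      k <- match(weights$age, spec$ages)
      if (anyNA(k)) stop("weight ages outside the penetrance hazard grid")
      sum(weights$weight * dens_s[k] * S_before[k])
    }
  })
}

#' Age-specific familial relative risk from a major-gene model
#'
#' The FRR at relative's age t is the likelihood ratio
#' \deqn{FRR(t) = P(\text{relative affected by } t \mid \text{proband
#' affected, subtype } s) / P(\text{woman affected by } t),}
#' with the numerator summed over the exact joint carrier distribution:
#' \eqn{\sum_{g_p, g_r} P(g_p, g_r) A_s(g_p) F_{g_r}(t) / \sum_{g_p} P(g_p)
#' A_s(g_p)} and denominator \eqn{\sum_g P(g) F_g(t)}, where
#' \eqn{A_s(g)} is the proband's probability of being affected with subtype
#' s given genotype g. The proband's affection is conditioned either on a
#' fixed diagnosis age (`proband_age`) or averaged over a case-age weight
#' distribution (`weights`, the default mechanism).
#'
#' @param spec a [major_gene_spec()].
#' @param proband_subtype subtype of the index case, or `"any"`.
#' @param t relative's attained age(s).
#' @param weights an `age_weights` object over proband diagnosis ages
#'   (required unless `proband_age` is given).
#' @param proband_age optional fixed proband diagnosis age.
#' @param kinship passed to [genotype_joint()].
#' @return numeric vector FRR(t); `NA` where the population risk is still
#'   zero.
#' @export
age_specific_frr <- function(spec, proband_subtype = "any", t, weights = NULL,
                             proband_age = NULL, kinship = "offspring") {
  stopifnot(inherits(spec, "major_gene_spec"))
  if (is.null(weights) && is.null(proband_age)) stop("supply weights or proband_age")
  A <- .proband_affection(spec, proband_subtype, weights, proband_age)
  if (sum(A) <= 0) stop("proband subtype has zero probability under this spec")
  J <- genotype_joint(spec$f, kinship)
  M <- rowSums(J)
  Fr <- rbind(noncarrier = .cuminc_at(spec, "noncarrier", "any", t),
              carrier = .cuminc_at(spec, "carrier", "any", t))
  num <- as.vector(t(A) %*% J %*% Fr) / sum(M * A)
  den <- as.vector(M %*% Fr)
  ifelse(den > 0, num / den, NA_real_)
}

#' Age-averaged overall familial relative risk
#'
#' Averages FRR(t) over the relative's attained age with case-incidence
#' weights (conventionally ages 20 to 70): \eqn{\sum_t w(t) FRR(t)}. Ages
#' where the population risk is still zero are dropped and the weights
#' renormalised.
#'
#' @param spec a [major_gene_spec()].
#' @param proband_subtype subtype of the index case, or `"any"`.
#' @param weights `age_weights` over the relative's attained age; also used
#'   for the proband's diagnosis-age distribution unless `proband_age` is
#'   given.
#' @param proband_age optional fixed proband diagnosis age.
#' @param kinship passed to [genotype_joint()].
#' @return scalar FRR.
#' @export
overall_frr <- function(spec, proband_subtype = "any", weights,
                        proband_age = NULL, kinship = "offspring") {
  frr_t <- age_specific_frr(spec, proband_subtype, weights$age, weights,
                            proband_age, kinship)
  ok <- !is.na(frr_t) & weights$weight > 0
  if (!any(ok)) stop("FRR undefined at every weighted age")
  sum(weights$weight[ok] * frr_t[ok]) / sum(weights$weight[ok])
}

#' Percent of the familial relative risk attributable to a major gene
#'
#' Multiplicative attribution `100 * log(frr_gene) / log(lambda0)`, with
#' `lambda0` the overall FRR of the subtype.
#'
#' @param frr_gene gene-attributable FRR (e.g. from [overall_frr()]).
#' @param lambda0 overall FRR (> 1).
#' @return percent.
#' @export
gene_pct_frr <- function(frr_gene, lambda0) {
  if (any(lambda0 <= 1)) stop("lambda0 must exceed 1")
  100 * log(frr_gene) / log(lambda0)
}

#' Subtype-specific familial relative risk under genotype-driven concordance
#'
#' As [age_specific_frr()] but with both the proband's and the relative's
#' events restricted to subtype s and the denominator the population risk of
#' subtype s — the FRR that would be observed if concordance in tumour
#' pathology between index case and relative were due to genotype alone.
#' Averaged over the relative's attained age with `weights`.
#'
#' @inheritParams overall_frr
#' @param subtype the tumour subtype (must have positive mass).
#' @return scalar subtype-specific FRR.
#' @export
subtype_specific_frr <- function(spec, subtype, weights, proband_age = NULL,
                                 kinship = "offspring") {
  stopifnot(inherits(spec, "major_gene_spec"))
  A <- .proband_affection(spec, subtype, weights, proband_age)
  if (sum(A) <= 0) stop("subtype has zero probability under this spec")
  J <- genotype_joint(spec$f, kinship)
  M <- rowSums(J)
  t <- weights$age
  Fr <- rbind(noncarrier = .cuminc_at(spec, "noncarrier", subtype, t),
              carrier = .cuminc_at(spec, "carrier", subtype, t))
  num <- as.vector(t(A) %*% J %*% Fr) / sum(M * A)
  den <- as.vector(M %*% Fr)
  frr_t <- ifelse(den > 0, num / den, NA_real_)
  ok <- !is.na(frr_t) & weights$weight > 0
  if (!any(ok)) stop("subtype-specific FRR undefined at every weighted age")
  sum(weights$weight[ok] * frr_t[ok]) / sum(weights$weight[ok])
}
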