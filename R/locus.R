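#' Familial relative risk attributable to a biallelic susceptibility locus
#'
#' For a locus with risk-allele frequency `p` and genotypic relative risks
#' `r1` (heterozygote) and `r2` (homozygote for the listed allele, relative
#' to the common homozygote), the first-degree FRR attributable to the locus
#' is the kinship-induced risk correlation
#' \deqn{\lambda^* = E[R_{proband} R_{relative}] / E[R]^2,}
#' with genotypes in Hardy-Weinberg proportions \eqn{(q^2, 2pq, p^2)} and
#' risks \eqn{(1, r_1, r_2)}. For `kinship = "offspring"` (the default; a
#' mother-daughter pair) the relative inherits one allele from the proband's
#' pair at random and one from the population; for `"sibling"` both
#' individuals receive independent Mendelian transmissions from the same two
#' Hardy-Weinberg parents, which adds a dominance-variance term. By
#' Cauchy-Schwarz \eqn{\lambda^* \ge 1}, with equality iff the risks are
#' constant across genotypes.
#'
#' The frequency `p` is taken as the listed allele's frequency whether or
#' not it is truly minor; no reordering is applied.
#'
#' @param p risk-allele frequency in (0, 1); vectorised.
#' @param r1,r2 heterozygote and homozygote relative risks (> 0); vectorised.
#' @param kinship `"offspring"` (first-degree parent-offspring, the default)
#'   or `"sibling"`.
#' @return numeric vector of locus FRRs (>= 1).
#' @examples
#' locus_frr(0.38, 1.28, 1.74)  # 1.0186
#' @export
locus_frr <- function(p, r1, r2, kinship = c("offspring", "sibling")) {
  kinship <- match.arg(kinship)
  n <- max(length(p), length(r1), length(r2))
  p <- rep_len(as.numeric(p), n); r1 <- rep_len(as.numeric(r1), n)
  r2 <- rep_len(as.numeric(r2), n)
  if (any(p <= 0 | p >= 1)) stop("allele frequency must be in (0, 1)")
  if (any(r1 <= 0 | r2 <= 0)) stop("genotypic relative risks must be positive")
  q <- 1 - p
  G <- cbind(q^2, 2 * p * q, p^2)      # genotype = copies of listed allele
  R <- cbind(1, r1, r2)
  mu <- rowSums(G * R)
  if (kinship == "offspring") {
    # E[R_p R_o] = sum_k g_k R_k sum_j P(offspring = j | parent = k) R_j,
    # offspring = one transmitted parental allele + one population allele
    num <- 0
    for (k in 0:2) {
      tr <- k / 2                      # P(transmit listed allele)
      po <- cbind((1 - tr) * q, (1 - tr) * p + tr * q, tr * p)
      num <- num + G[, k + 1L] * R[, k + 1L] * rowSums(po * R)
    }
  } else {
    # siblings: sum over parental genotype pairs; child dist is the
    # convolution of the two independent transmissions
    num <- 0
    for (kf in 0:2) for (km in 0:2) {
      tf <- kf / 2; tm <- km / 2
      child <- c((1 - tf) * (1 - tm),
                 tf * (1 - tm) + (1 - tf) * tm,
                 tf * tm)
      m <- as.vector(R %*% child)      # mean child risk given these parents
      num <- num + G[, kf + 1L] * G[, km + 1L] * m^2
    }
  }
  unname(num / mu^2)
}

#' Percent of the familial relative risk attributable to a locus
#'
#' Under the multiplicative joint-effect model (the susceptibility locus and
#' all other familial factors multiply on risk), the locus accounts for
#' `100 * log(lambda_star) / log(lambda0)` percent of the overall FRR
#' `lambda0`; under the additive model the share of the excess FRR is
#' `100 * (lambda_star - 1) / (lambda0 - 1)`.
#'
#' @param lambda_star locus FRR from [locus_frr()]; vectorised.
#' @param lambda0 overall FRR of the subtype (> 1).
#' @return percent (numeric vector).
#' @export
pct_frr_multiplicative <- function(lambda_star, lambda0) {
  if (any(lambda0 <= 1)) stop("lambda0 must exceed 1")
  100 * log(lambda_star) / log(lambda0)
}

#' @rdname pct_frr_multiplicative
#' @export
pct_frr_additive <- function(lambda_star, lambda0) {
  if (any(lambda0 <= 1)) stop("lambda0 must exceed 1")
  100 * (lambda_star - 1) / (lambda0 - 1)
}

#' Read a locus specification table
#'
#' CSV with columns `name, rsid, maf, r1_erneg, r2_erneg, r1_erpos,
#' r2_erpos`: the published allele frequency and per-subtype heterozygote /
#' homozygote odds ratios for each susceptibility variant. The packaged
#' fixture `susceptibility_loci.csv` carries the 12 loci with published
#' subtype-specific risks.
#'
#' @param path CSV path; defaults to the packaged 12-locus table.
#' @return data.frame of locus specifications.
#' @export
read_locus_table <- function(path = system.file("extdata", "susceptibility_loci.csv",
                                                package = "frrcohort")) {
  df <- utils::read.csv(path, check.names = TRUE)
  req <- c("name", "rsid", "maf", "r1_erneg", "r2_erneg", "r1_erpos", "r2_erpos")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("locus CSV missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Per-locus and total contribution of susceptibility loci to the FRR
#'
#' For each locus computes the ER-negative and ER-positive locus FRR and its
#' percent contribution to the corresponding overall FRR under both the
#' multiplicative and additive joint-effect models. Column totals follow the
#' convention of published tables: the multiplicative total is the sum of
#' the per-locus percentages rounded to `digits` decimal places (the sum of
#' the unrounded percentages is attached as attribute
#' `total_mult_unrounded`); additive totals are computed from unrounded
#' locus FRRs.
#'
#' @param loci data.frame from [read_locus_table()]. Loci with missing
#'   subtype risks are skipped with a warning.
#' @param lambda0 named vector `c(erneg = ..., erpos = ...)` of overall FRRs;
#'   defaults to the cohort estimates 1.78 and 1.82.
#' @param kinship passed to [locus_frr()].
#' @param digits rounding used for display and for the multiplicative total
#'   convention (default 2).
#' @return data.frame with one row per locus (`lambda_erneg`, `pct_erneg`,
#'   `lambda_erpos`, `pct_erpos`, unrounded) plus attributes
#'   `totals` (list with `mult_erneg`, `mult_erpos`, `add_erneg`,
#'   `add_erpos`, `mult_erneg_unrounded`, `mult_erpos_unrounded`).
#' @export
build_locus_table <- function(loci, lambda0 = c(erneg = 1.78, erpos = 1.82),
                              kinship = "offspring", digits = 2) {
  stopifnot(all(c("erneg", "erpos") %in% names(lambda0)))
  ok <- stats::complete.cases(loci[, c("maf", "r1_erneg", "r2_erneg", "r1_erpos", "r2_erpos")])
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " locus/loci with missing subtype risks: ",
            paste(loci$name[!ok], collapse = ", "))
    loci <- loci[ok, , drop = FALSE]
  }
  if (!nrow(loci)) {
    out <- data.frame(name = character(), rsid = character(), maf = numeric(),
                      lambda_erneg = numeric(), pct_erneg = numeric(),
                      lambda_erpos = numeric(), pct_erpos = numeric())
    attr(out, "totals") <- list(mult_erneg = 0, mult_erpos = 0,
                                mult_erneg_unrounded = 0, mult_erpos_unrounded = 0,
                                add_erneg = 0, add_erpos = 0)
    return(out)
  }
  ln <- locus_frr(loci$maf, loci$r1_erneg, loci$r2_erneg, kinship)
  lp <- locus_frr(loci$maf, loci$r1_erpos, loci$r2_erpos, kinship)
  pn <- pct_frr_multiplicative(ln, lambda0[["erneg"]])
  pp <- pct_frr_multiplicative(lp, lambda0[["erpos"]])
  out <- data.frame(name = loci$name, rsid = loci$rsid, maf = loci$maf,
                    lambda_erneg = ln, pct_erneg = pn,
                    lambda_erpos = lp, pct_erpos = pp)
  attr(out, "totals") <- list(
    mult_erneg = sum(round(pn, digits)),
    mult_erpos = sum(round(pp, digits)),
    mult_erneg_unrounded = sum(pn),
    mult_erpos_unrounded = sum(pp),
    add_erneg = sum(pct_frr_additive(ln, lambda0[["erneg"]])),
    add_erpos = sum(pct_frr_additive(lp, lambda0[["erpos"]]))
  )
  out
}
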