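logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, numerically stable
logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimate with standard error `se` and a normal prior with
#' standard deviation `prior_sd` on the true effect:
#' `lABF = 0.5 * (log(1 - r) + z^2 * r)` with
#' `r = prior_sd^2 / (prior_sd^2 + se^2)` and `z = beta / se`.
#'
#' @param beta,se estimate and standard error (vectorized, `se > 0`).
#' @param prior_sd prior effect standard deviation (`> 0`).
#' @return log approximate Bayes factor(s).
#' @export
wakefield_labf <- function(beta, se, prior_sd) {
  stopifnot(all(se > 0), prior_sd > 0)
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  z <- beta / se
  0.5 * (log1p(-r) + z^2 * r)
}

#' Enumeration-based Bayesian colocalization
#'
#' Tests whether two traits share a causal variant in a region, assuming
#' at most one causal variant per trait. Per-SNP Wakefield log Bayes
#' factors (prior effect sd 0.2 for quantitative traits, 0.15 for binary)
#' are combined over the five hypotheses — H0 no association, H1/H2 one
#' trait only, H3 two distinct variants, H4 one shared variant — with
#' per-SNP priors `p1`, `p2` and `p12`, entirely in log space.
#'
#' @param region1,region2 `region_panel`s; intersected on shared SNP ids
#'   (alleles assumed harmonized).
#' @param p1,p2 prior probability a SNP is causal for trait 1 / 2 only
#'   (default 1e-4 each).
#' @param p12 prior probability a SNP is causal for both (default 1e-5).
#' @param prior_sd_quant,prior_sd_binary prior effect standard deviations.
#' @return list with `pp` (named `h0..h4`, summing to 1), `n_snps`,
#'   `top_shared_snp` (argmax of the per-SNP H4 contribution), and
#'   `snp_h4` (normalized per-SNP posteriors under H4).
#' @export
coloc_abf <- function(region1, region2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd_quant = 0.2, prior_sd_binary = 0.15) {
  shared <- intersect(region1$data$snp, region2$data$snp)
  if (length(shared) == 0) stop("no common SNPs between regions", call. = FALSE)
  if (length(shared) < 50) {
    warning("fewer than 50 common SNPs; colocalization may be underpowered",
      call. = FALSE
    )
  }
  i1 <- match(shared, region1$data$snp)
  i2 <- match(shared, region2$data$snp)
  sd1 <- if (region1$trait_type == "binary") prior_sd_binary else prior_sd_quant
  sd2 <- if (region2$trait_type == "binary") prior_sd_binary else prior_sd_quant
  l1 <- wakefield_labf(region1$data$beta[i1], region1$data$se[i1], sd1)
  l2 <- wakefield_labf(region2$data$beta[i2], region2$data$se[i2], sd2)

  s1 <- logsumexp(l1) # sum over single-variant configurations, trait 1
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2) # same variant in both
  # sum over i != j of exp(l1_i + l2_j)
  s3 <- logdiff(s1 + s2, s12)

  lh <- c(
    h0 = 0,
    h1 = log(p1) + s1,
    h2 = log(p2) + s2,
    h3 = log(p1) + log(p2) + s3,
    h4 = log(p12) + s12
  )
  pp <- exp(lh - logsumexp(lh))
  snp_h4 <- exp((l1 + l2) - s12)
  list(
    pp = pp, n_snps = length(shared),
    top_shared_snp = shared[which.max(l1 + l2)],
    snp_h4 = setNames(snp_h4, shared)
  )
}

#' Colocalization region predicate
#'
#' A closed-interval window around a gene or variant, defaulting to
#' 100 kb on either side.
#'
#' @param chrom chromosome.
#' @param start,end feature coordinates (`end` defaults to `start` for a
#'   single variant).
#' @param flank_bp flank size in bp (default 1e5).
#' @return predicate function of `(chr, pos)`, as [cis_window()].
#' @export
define_coloc_region <- function(chrom, start, end = start, flank_bp = 1e5) {
  cis_window(chrom, start, end, flank_bp)
}
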