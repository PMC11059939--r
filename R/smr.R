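#' Region panel: one trait's statistics over a cis-region
#'
#' Carries a region's SNP ids, per-SNP effects, SEs, allele frequencies and
#' the study sample size for one trait — the working unit of SMR, HEIDI
#' and colocalization.
#'
#' @param snp SNP ids (ordered).
#' @param beta,se per-SNP effects and standard errors (`se > 0`).
#' @param eaf effect-allele frequencies (optional).
#' @param n sample size.
#' @param trait_id trait label.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param pos,chr optional genomic coordinates.
#' @return object of class `region_panel`.
#' @export
region_panel <- function(snp, beta, se, eaf = NA_real_, n = NA_real_,
                         trait_id = "trait", trait_type = c("quantitative", "binary"),
                         pos = NA_real_, chr = NA_character_) {
  trait_type <- match.arg(trait_type)
  k <- length(snp)
  stopifnot(length(beta) == k, length(se) == k, all(se > 0))
  structure(
    list(
      trait_id = trait_id, trait_type = trait_type, n = n,
      data = data.frame(
        snp = as.character(snp), beta = beta, se = se,
        eaf = rep_len(eaf, k), pos = rep_len(pos, k), chr = rep_len(chr, k)
      )
    ),
    class = "region_panel"
  )
}

#' @export
print.region_panel <- function(x, ...) {
  cat(sprintf(
    "<region_panel> trait '%s' (%s), %d SNPs, n = %s\n",
    x$trait_id, x$trait_type, nrow(x$data), format(x$n)
  ))
  invisible(x)
}

#' Build a region panel from a sumstats table
#'
#' @param table a `sumstats` table.
#' @param predicate optional region predicate from [cis_window()] /
#'   [define_coloc_region()]; rows failing it are excluded.
#' @return a `region_panel`.
#' @export
region_from_sumstats <- function(table, predicate = NULL) {
  df <- as.data.frame(table)
  if (!is.null(predicate)) df <- df[predicate(df$chr, df$pos), , drop = FALSE]
  region_panel(df$snp, df$beta, df$se,
    eaf = df$eaf, n = if (all(is.na(df$n))) NA_real_ else max(df$n, na.rm = TRUE),
    trait_id = attr(table, "trait_id"), trait_type = attr(table, "trait_type"),
    pos = df$pos, chr = df$chr
  )
}

region_z <- function(panel) panel$data$beta / panel$data$se

#' SMR test of gene expression on an outcome
#'
#' Uses the top cis-eQTL (largest |z| in the eQTL panel) as the instrument:
#' `b_xy = beta_gwas / beta_eqtl` at that SNP, and the SMR statistic
#' `T_SMR = z_gwas^2 * z_eqtl^2 / (z_gwas^2 + z_eqtl^2)` referred to
#' chi-square with 1 df; `se_xy = |b_xy| / sqrt(T_SMR)`.
#'
#' @param eqtl_region `region_panel` of cis-eQTL statistics for one gene.
#' @param gwas_region `region_panel` of outcome statistics over the same
#'   region (harmonized to the same effect alleles).
#' @param p_instrument minimum eQTL significance for the instrument
#'   (default 5e-8); failing it skips the gene.
#' @return list with `top_snp`, `b_xy`, `se_xy`, `p_smr`, `z_eqtl`,
#'   `z_gwas`, and `status` (`"ok"` or `"no valid instrument"`).
#' @export
smr_test <- function(eqtl_region, gwas_region, p_instrument = 5e-8) {
  z_e <- region_z(eqtl_region)
  top <- which.max(abs(z_e))
  top_snp <- eqtl_region$data$snp[top]
  p_top <- 2 * pnorm(-abs(z_e[top]))
  j <- match(top_snp, gwas_region$data$snp)
  if (length(top) == 0 || p_top >= p_instrument || is.na(j)) {
    return(list(
      top_snp = if (length(top)) top_snp else NA_character_,
      b_xy = NA_real_, se_xy = NA_real_, p_smr = NA_real_,
      z_eqtl = NA_real_, z_gwas = NA_real_, status = "no valid instrument"
    ))
  }
  z_g <- gwas_region$data$beta[j] / gwas_region$data$se[j]
  b_xy <- gwas_region$data$beta[j] / eqtl_region$data$beta[top]
  t_smr <- if (z_g == 0 && z_e[top] == 0) 0 else {
    (z_g^2 * z_e[top]^2) / (z_g^2 + z_e[top]^2)
  }
  list(
    top_snp = top_snp, b_xy = b_xy,
    se_xy = if (t_smr > 0) abs(b_xy) / sqrt(t_smr) else Inf,
    p_smr = pchisq(t_smr, df = 1, lower.tail = FALSE),
    z_eqtl = z_e[top], z_gwas = z_g, status = "ok"
  )
}

#' Select the SNPs entering the HEIDI test
#'
#' cis-SNPs with eQTL `p < p_eqtl_max` whose squared correlation with the
#' top eQTL SNP lies in `[r2_min, r2_max]`; if more than `max_snps`
#' qualify, the `max_snps` with smallest eQTL p are kept. The top SNP is
#' always included. Defaults follow common SMR practice: p threshold
#' 1.57e-3 (chi-square > 10), r-squared in \[0.05, 0.9\], at most 20 SNPs.
#'
#' @param eqtl_region `region_panel` of eQTL statistics.
#' @param ld LD matrix covering the region.
#' @param p_eqtl_max,r2_min,r2_max,max_snps selection parameters.
#' @return character vector of SNP ids, top SNP first.
#' @export
select_heidi_snps <- function(eqtl_region, ld, p_eqtl_max = 1.57e-3,
                              r2_min = 0.05, r2_max = 0.9, max_snps = 20) {
  z <- region_z(eqtl_region)
  top <- which.max(abs(z))
  top_snp <- eqtl_region$data$snp[top]
  p <- 2 * pnorm(-abs(z))
  cand <- eqtl_region$data$snp[p < p_eqtl_max]
  cand <- setdiff(intersect(cand, rownames(ld)), top_snp)
  if (!top_snp %in% rownames(ld)) {
    return(top_snp)
  }
  r2 <- ld[cand, top_snp]^2
  cand <- cand[r2 >= r2_min & r2 <= r2_max]
  if (length(cand) > max_snps - 1) {
    pc <- p[match(cand, eqtl_region$data$snp)]
    cand <- cand[order(pc)][seq_len(max_snps - 1)]
  }
  c(top_snp, cand)
}

#' Tail probability of a weighted sum of chi-squares (Imhof's method)
#'
#' `P(sum_k lambda_k * X_k > q)` for independent 1-df chi-squares, by
#' numerical inversion of the characteristic function. Falls back to a
#' Satterthwaite scaled-chi-square approximation if the quadrature fails.
#'
#' @param q observed statistic.
#' @param lambda eigenvalue weights (non-negative).
#' @param method `"imhof"` (default) or `"satterthwaite"`.
#' @return upper-tail probability in \[0, 1\].
#' @export
weighted_chisq_pvalue <- function(q, lambda, method = c("imhof", "satterthwaite")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 1e-12]
  if (length(lambda) == 0) return(1)
  satter <- function() {
    a <- sum(lambda^2) / sum(lambda)
    nu <- sum(lambda)^2 / sum(lambda^2)
    pchisq(q / a, df = nu, lower.tail = FALSE)
  }
  if (method == "satterthwaite") return(satter())
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - q * u / 2
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  p <- tryCatch(
    {
      int <- integrate(integrand,
        lower = 0, upper = Inf,
        subdivisions = 1000L, rel.tol = 1e-9, abs.tol = 1e-12
      )
      0.5 + int$value / pi
    },
    error = function(e) satter()
  )
  min(max(p, 0), 1)
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Tests whether the expression-outcome effect `b_xy` is homogeneous
#' across SNPs in LD with the top eQTL — the signature of a single shared
#' causal variant — against the linkage alternative of distinct causal
#' variants. For each selected non-top SNP `i`,
#' `d_i = b_xy(i) - b_xy(top)`; the covariance of `d` comes from the
#' first-order delta method with within-trait `cov(beta_i, beta_j) = r_ij
#' * se_i * se_j` and independence across the (non-overlapping) studies.
#' `T_HEIDI = sum(z_d^2)` is referred to a weighted sum of 1-df
#' chi-squares with weights the eigenvalues of the correlation matrix of
#' `d` (Imhof integration; Satterthwaite fallback). A small p suggests
#' linkage rather than a shared variant.
#'
#' @param eqtl_region,gwas_region harmonized `region_panel`s.
#' @param ld LD matrix covering the region.
#' @param p_eqtl_max,r2_min,r2_max,max_snps passed to [select_heidi_snps()].
#' @param method p-value method, see [weighted_chisq_pvalue()].
#' @return list with `p_heidi` (`NA` when fewer than 3 eligible SNPs),
#'   `n_heidi_snps`, `t_heidi`, `snps`.
#' @export
heidi_test <- function(eqtl_region, gwas_region, ld, p_eqtl_max = 1.57e-3,
                       r2_min = 0.05, r2_max = 0.9, max_snps = 20,
                       method = "imhof") {
  snps <- select_heidi_snps(eqtl_region, ld, p_eqtl_max, r2_min, r2_max, max_snps)
  snps <- snps[snps %in% gwas_region$data$snp]
  if (length(snps) < 3) {
    return(list(
      p_heidi = NA_real_, n_heidi_snps = length(snps),
      t_heidi = NA_real_, snps = snps
    ))
  }
  ie <- match(snps, eqtl_region$data$snp)
  ig <- match(snps, gwas_region$data$snp)
  be <- eqtl_region$data$beta[ie]
  se_e <- eqtl_region$data$se[ie]
  bg <- gwas_region$data$beta[ig]
  se_g <- gwas_region$data$se[ig]
  r <- ld[snps, snps]

  b_xy <- bg / be
  k <- length(snps)
  # cov(b_i, b_j) by the delta method; traits independent
  cov_b <- r * outer(se_g, se_g) / outer(be, be) +
    outer(bg, bg) * r * outer(se_e, se_e) / outer(be^2, be^2)
  # d_i = b_i - b_top for i = 2..k (top SNP is first)
  idx <- 2:k
  v_d <- cov_b[idx, idx, drop = FALSE] -
    outer(cov_b[idx, 1], rep(1, k - 1)) -
    outer(rep(1, k - 1), cov_b[1, idx]) + cov_b[1, 1]
  d <- b_xy[idx] - b_xy[1]
  sd_d <- sqrt(diag(v_d))
  z_d <- d / sd_d
  t_heidi <- sum(z_d^2)
  corr_d <- v_d / outer(sd_d, sd_d)
  lambda <- eigen(corr_d, symmetric = TRUE, only.values = TRUE)$values
  p <- if (t_heidi <= 0) 1 else weighted_chisq_pvalue(t_heidi, lambda, method)
  list(p_heidi = p, n_heidi_snps = k, t_heidi = t_heidi, snps = snps)
}

#' Combined SMR + HEIDI result for one gene and tissue
#'
#' @param eqtl_region,gwas_region harmonized `region_panel`s.
#' @param ld LD matrix for the region.
#' @param gene_id,tissue labels carried into the result row.
#' @param p_instrument eQTL instrument threshold (default 5e-8).
#' @param ... HEIDI selection parameters passed to [heidi_test()].
#' @return one-row data frame: `gene, tissue, top_snp, b_xy, se_xy, p_smr,
#'   p_heidi, n_heidi_snps, or, or_ci_low, or_ci_high, status`.
#' @export
smr_heidi <- function(eqtl_region, gwas_region, ld, gene_id = "gene",
                      tissue = "tissue", p_instrument = 5e-8, ...) {
  s <- smr_test(eqtl_region, gwas_region, p_instrument)
  h <- if (s$status == "ok") {
    heidi_test(eqtl_region, gwas_region, ld, ...)
  } else {
    list(p_heidi = NA_real_, n_heidi_snps = 0L)
  }
  ci <- if (s$status == "ok" && is.finite(s$se_xy)) {
    c(s$b_xy - 1.96 * s$se_xy, s$b_xy + 1.96 * s$se_xy)
  } else {
    c(NA_real_, NA_real_)
  }
  data.frame(
    gene = gene_id, tissue = tissue, top_snp = s$top_snp,
    b_xy = s$b_xy, se_xy = s$se_xy, p_smr = s$p_smr,
    p_heidi = h$p_heidi, n_heidi_snps = h$n_heidi_snps,
    or = exp(s$b_xy), or_ci_low = exp(ci[1]), or_ci_high = exp(ci[2]),
    status = s$status
  )
}
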