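#' Simulate an AR(1) linkage-disequilibrium matrix
#'
#' `r_ij = rho^|i - j|` — a one-parameter correlation structure that is
#' positive definite for any `rho` in \[0, 1) and produces the graded decay
#' of LD with distance needed to contrast shared-variant and linkage
#' architectures. SNPs are labelled `snp_1..snp_n` with 1 kb spacing
#' (attributes `pos` and `chr`).
#'
#' @param n_snps number of SNPs.
#' @param rho AR(1) correlation parameter in \[0, 1).
#' @param chrom chromosome label (default `"1"`).
#' @param start_pos position of the first SNP (default 1e6).
#' @return LD matrix (see [ld_matrix()]) with `pos`/`chr` attributes.
#' @export
simulate_ld <- function(n_snps, rho, chrom = "1", start_pos = 1e6) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  idx <- seq_len(n_snps)
  r <- rho^abs(outer(idx, idx, "-"))
  m <- ld_matrix(r, paste0("snp_", idx))
  attr(m, "pos") <- start_pos + (idx - 1) * 1000
  attr(m, "chr") <- chrom
  m
}

#' Two-sample MR scenario configuration
#'
#' Describes the generative model for [simulate_two_sample()]: independent
#' instruments with half-normal exposure effects scaled so their expected
#' total variance explained equals `h2_exposure`, outcome effects
#' `theta * beta_x + alpha` with per-instrument pleiotropy `alpha`
#' (`none`: 0; `balanced`: mean-zero normal; `directional`: mean-shifted
#' normal) applied to a fraction `prop_invalid` of instruments, and
#' observed statistics perturbed by sampling noise with
#' `se = (2 * maf * (1 - maf) * n)^(-1/2)`.
#'
#' Default sample sizes mirror large smoking-phenotype GWAS
#' (`n_exposure = 337334`) and a case-control outcome GWAS of 7495 cases
#' and 71934 controls (`n_outcome = 27157`, the effective sample size
#' `4 / (1/cases + 1/controls)` appropriate for log-odds summary
#' statistics).
#'
#' @param n_instruments number of independent instruments.
#' @param theta true causal effect of exposure on outcome.
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_mean,pleiotropy_sd mean and sd of the pleiotropic
#'   effects (mean only used in directional mode).
#' @param prop_invalid fraction of instruments receiving a pleiotropic
#'   effect (default 1 when pleiotropy is on).
#' @param maf_range range the minor-allele frequencies are drawn from.
#' @param h2_exposure total exposure variance explained by the instruments.
#' @param n_exposure,n_outcome GWAS sample sizes (effective, for binary).
#' @param outcome_type `"binary"` (betas are log-odds) or `"quantitative"`.
#' @param seed RNG seed.
#' @return list of class `mr_scenario_config`.
#' @export
mr_scenario_config <- function(n_instruments = 40, theta = 0,
                               pleiotropy = c("none", "balanced", "directional"),
                               pleiotropy_mean = 0.02, pleiotropy_sd = 0.01,
                               prop_invalid = 1,
                               maf_range = c(0.05, 0.5), h2_exposure = 0.05,
                               n_exposure = 337334, n_outcome = 27157,
                               outcome_type = "binary", seed = 1) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(
    n_instruments >= 1, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2], n_exposure > 0, n_outcome > 0,
    prop_invalid >= 0, prop_invalid <= 1, h2_exposure > 0
  )
  structure(as.list(environment()), class = "mr_scenario_config")
}

#' Simulate two-sample GWAS summary statistics
#'
#' Draws instrument MAFs and true effects per the scenario, adds
#' independent sampling noise in the exposure and outcome studies, and
#' returns both studies as [sumstats_table()]s (alleles A/G so no
#' palindromes arise; instruments oriented to the exposure-increasing
#' allele; positions spaced 20 Mb so instruments are physically
#' independent) plus a truth record of every latent quantity.
#'
#' @param config an [mr_scenario_config()].
#' @return list with `exposure`, `outcome` (`sumstats`) and `truth`
#'   (data frame: `snp, maf, beta_x_true, alpha, beta_y_true, invalid`).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "mr_scenario_config"))
  k <- config$n_instruments
  withr_seed(config$seed, {
    maf <- runif(k, config$maf_range[1], config$maf_range[2])
    var_g <- 2 * maf * (1 - maf)
    # half-normal, oriented to the exposure-increasing allele; expected
    # total variance explained = h2_exposure
    bx_true <- abs(rnorm(k, 0, sqrt(config$h2_exposure / (k * var_g))))
    invalid <- rep(FALSE, k)
    alpha <- numeric(k)
    if (config$pleiotropy != "none" && config$prop_invalid > 0) {
      n_inv <- round(config$prop_invalid * k)
      invalid[sample.int(k, n_inv)] <- TRUE
      mu <- if (config$pleiotropy == "directional") config$pleiotropy_mean else 0
      alpha[invalid] <- rnorm(n_inv, mu, config$pleiotropy_sd)
    }
    by_true <- config$theta * bx_true + alpha
    se_x <- 1 / sqrt(var_g * config$n_exposure)
    se_y <- 1 / sqrt(var_g * config$n_outcome)
    bx_obs <- rnorm(k, bx_true, se_x)
    by_obs <- rnorm(k, by_true, se_y)
  })
  chr <- as.character(rep_len(1:22, k))
  pos <- 1e6 + (seq_len(k) - 1) %/% 22 * 2e7
  snp <- paste0("iv_", seq_len(k))
  mk <- function(beta, se, n, id, type) {
    sumstats_table(
      data.frame(
        snp = snp, chr = chr, pos = pos, a1 = "A", a2 = "G", eaf = maf,
        beta = beta, se = se,
        p = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin), n = n
      ),
      trait_id = id, trait_type = type, validate = FALSE
    )
  }
  list(
    exposure = mk(bx_obs, se_x, config$n_exposure, "exposure", "quantitative"),
    outcome = mk(by_obs, se_y, config$n_outcome, "outcome", config$outcome_type),
    truth = data.frame(
      snp = snp, maf = maf, beta_x_true = bx_true, alpha = alpha,
      beta_y_true = by_true, invalid = invalid
    )
  )
}

#' Region-pair scenario configuration
#'
#' Describes a cis-region simulated for two traits under an explicit
#' causal architecture: `null` (no causal variant), `trait1_only` /
#' `trait2_only` (one trait has a causal variant), `shared_variant` (both
#' traits driven by the same variant — the colocalization H4 /
#' SMR-causality scenario) or `distinct_variants` (each trait has its own
#' variant, in LD — the linkage scenario HEIDI is designed to flag).
#'
#' Effects are on the standardized-genotype scale: marginal true betas are
#' `R %*% b_joint` and observed betas are multivariate normal around them
#' with covariance `R / n`, so `se = n^(-1/2)` exactly.
#'
#' @param n_snps SNPs in the region.
#' @param ld_rho AR(1) LD parameter.
#' @param architecture one of the five architectures above.
#' @param causal_idx causal SNP index (two indices for
#'   `distinct_variants`); defaults to the region centre, with the second
#'   variant offset to give LD ~0.4 between the two.
#' @param effect_sizes length-2 z-score targets at the causal variant for
#'   trait 1 and trait 2 (default `c(12, 8)`).
#' @param n1,n2 sample sizes (defaults mirror a large blood eQTL study and
#'   an effective case-control GWAS size).
#' @param trait_types trait types for the two panels.
#' @param seed RNG seed.
#' @return list of class `region_scenario_config`.
#' @export
region_scenario_config <- function(n_snps = 200, ld_rho = 0.9,
                                   architecture = c(
                                     "shared_variant", "distinct_variants",
                                     "null", "trait1_only", "trait2_only"
                                   ),
                                   causal_idx = NULL,
                                   effect_sizes = c(12, 8),
                                   n1 = 31684, n2 = 27157,
                                   trait_types = c("quantitative", "binary"),
                                   seed = 1) {
  architecture <- match.arg(architecture)
  if (is.null(causal_idx)) {
    centre <- ceiling(n_snps / 2)
    causal_idx <- if (architecture == "distinct_variants") {
      # offset chosen so LD between the two causal variants is ~0.4
      off <- max(1, round(log(0.4) / log(max(ld_rho, 1e-6))))
      c(centre, min(n_snps, centre + off))
    } else {
      centre
    }
  }
  if (architecture == "distinct_variants") {
    stopifnot(length(causal_idx) == 2, causal_idx[1] != causal_idx[2])
  } else if (architecture != "null") {
    stopifnot(length(causal_idx) >= 1)
  }
  if (any(causal_idx < 1 | causal_idx > n_snps)) {
    stop("causal_idx out of range", call. = FALSE)
  }
  structure(as.list(environment())[c(
    "n_snps", "ld_rho", "architecture", "causal_idx", "effect_sizes",
    "n1", "n2", "trait_types", "seed"
  )], class = "region_scenario_config")
}

#' Simulate a pair of region panels under a causal architecture
#'
#' @param config a [region_scenario_config()].
#' @param ld optional pre-built LD matrix (from [simulate_ld()]); its
#'   Cholesky factor may be supplied via `chol_ld` to amortize repeated
#'   simulation from the same LD structure.
#' @param chol_ld optional upper-triangular Cholesky factor of `ld`.
#' @return list with `panel1`, `panel2` ([region_panel()]s), `ld`, and
#'   `truth` (causal indices and joint effects per trait).
#' @export
simulate_region_pair <- function(config, ld = NULL, chol_ld = NULL) {
  stopifnot(inherits(config, "region_scenario_config"))
  if (is.null(ld)) ld <- simulate_ld(config$n_snps, config$ld_rho)
  m <- config$n_snps
  stopifnot(nrow(ld) == m)
  if (is.null(chol_ld)) chol_ld <- chol(unclass(ld)[seq_len(m), seq_len(m)])

  joint <- list(numeric(m), numeric(m))
  z_at <- function(trait, idx) {
    joint[[trait]][idx] <<- config$effect_sizes[trait] /
      sqrt(c(config$n1, config$n2)[trait])
  }
  switch(config$architecture,
    null = NULL,
    trait1_only = z_at(1, config$causal_idx[1]),
    trait2_only = z_at(2, config$causal_idx[1]),
    shared_variant = {
      z_at(1, config$causal_idx[1])
      z_at(2, config$causal_idx[1])
    },
    distinct_variants = {
      z_at(1, config$causal_idx[1])
      z_at(2, config$causal_idx[2])
    }
  )
  r <- unclass(ld)
  panels <- withr_seed(config$seed, {
    lapply(1:2, function(t) {
      n <- c(config$n1, config$n2)[t]
      marginal <- drop(r %*% joint[[t]])
      obs <- marginal + drop(crossprod(chol_ld, rnorm(m))) / sqrt(n)
      region_panel(
        snp = rownames(ld), beta = obs, se = rep(1 / sqrt(n), m),
        eaf = 0.5, n = n, trait_id = paste0("trait", t),
        trait_type = config$trait_types[t],
        pos = attr(ld, "pos") %||% (seq_len(m) * 1000),
        chr = attr(ld, "chr") %||% "1"
      )
    })
  })
  list(
    panel1 = panels[[1]], panel2 = panels[[2]], ld = ld,
    truth = list(causal_idx = config$causal_idx, joint = joint)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full drug-target screening study
#'
#' A desk-scale analogue of a multi-gene drug-target screen: each gene
#' gets its own cis-region (AR(1) LD, one chromosome per gene). Causal
#' genes follow the `shared_variant` architecture linking expression and
#' outcome; other genes with eQTL data follow `trait1_only` (an eQTL
#' signal with no outcome effect); a fraction of genes has no eQTL data at
#' all, exercising the exclusion path. Connectivity scores are drawn so
#' the screened genes pass `|score| > 90` and a set of distractor genes
#' does not.
#'
#' @param n_genes number of screened genes.
#' @param n_causal number of genes with a true shared-variant effect.
#' @param fraction_no_eqtl expected fraction of genes without eQTL data
#'   (default 0.15, i.e. ~13 of 88).
#' @param n_snps,ld_rho region size and LD parameter per gene.
#' @param z_eqtl,z_gwas causal-variant z-score targets for expression and
#'   outcome.
#' @param n_eqtl,n_gwas sample sizes.
#' @param b_xy_sign sign of the causal genes' expression-on-outcome effect
#'   (default -1: higher expression lowers risk).
#' @param seed RNG seed.
#' @return list with `genes` (data frame: `gene_id, chrom, start, end,
#'   causal, has_eqtl, tissue`), `eqtl`/`gwas` (named lists of
#'   [region_panel()]s; eQTL entries absent for no-eQTL genes), `ld`
#'   (named list), `connectivity` and `interaction` tables, `truth`.
#' @export
simulate_target_study <- function(n_genes = 10, n_causal = 1,
                                  fraction_no_eqtl = 0.15,
                                  n_snps = 100, ld_rho = 0.9,
                                  z_eqtl = 12, z_gwas = 8,
                                  n_eqtl = 31684, n_gwas = 27157,
                                  b_xy_sign = -1, seed = 1) {
  stopifnot(n_causal <= n_genes, fraction_no_eqtl >= 0, fraction_no_eqtl < 1)
  gene_ids <- sprintf("GENE%02d", seq_len(n_genes))
  assign_roles <- withr_seed(seed, {
    role <- rep("eqtl_only", n_genes)
    role[sample.int(n_genes, n_causal)] <- "causal"
    non_causal <- which(role != "causal")
    n_no <- rbinom(1, length(non_causal), fraction_no_eqtl)
    if (n_no > 0) role[sample(non_causal, n_no)] <- "no_eqtl"
    role
  })

  eqtl <- list()
  gwas <- list()
  lds <- list()
  for (g in seq_len(n_genes)) {
    ld_g <- simulate_ld(n_snps, ld_rho, chrom = as.character(g), start_pos = 1e6)
    rownames(ld_g) <- colnames(ld_g) <- paste0("g", g, "_", rownames(ld_g))
    arch <- switch(assign_roles[g],
      causal = "shared_variant",
      eqtl_only = "trait1_only",
      no_eqtl = "null"
    )
    cfg <- region_scenario_config(
      n_snps = n_snps, ld_rho = ld_rho, architecture = arch,
      effect_sizes = c(z_eqtl, sign(b_xy_sign) * z_gwas),
      n1 = n_eqtl, n2 = n_gwas,
      trait_types = c("quantitative", "binary"),
      seed = seed * 1000L + g
    )
    pair <- simulate_region_pair(cfg, ld = ld_g)
    pair$panel1$trait_id <- paste0(gene_ids[g], "_expression")
    pair$panel2$trait_id <- "outcome"
    if (assign_roles[g] != "no_eqtl") eqtl[[gene_ids[g]]] <- pair$panel1
    gwas[[gene_ids[g]]] <- pair$panel2
    lds[[gene_ids[g]]] <- ld_g
  }

  centre_pos <- 1e6 + (ceiling(n_snps / 2) - 1) * 1000
  genes <- data.frame(
    gene_id = gene_ids, chrom = as.character(seq_len(n_genes)),
    start = centre_pos - 5000, end = centre_pos + 5000,
    causal = assign_roles == "causal",
    has_eqtl = assign_roles != "no_eqtl",
    tissue = "blood"
  )

  withr_seed(seed + 7L, {
    score <- runif(n_genes, 91, 100) * sample(c(-1, 1), n_genes, replace = TRUE)
    distract <- sprintf("DIST%02d", 1:5)
    connectivity <- data.frame(
      gene_id = c(gene_ids, distract),
      drug = "cessation_drug",
      score = c(score, runif(5, -89, 89))
    )
    interaction <- data.frame(
      gene_id = gene_ids[seq_len(min(3, n_genes))],
      drug = "cessation_drug", source = "interaction_db"
    )
  })

  list(
    genes = genes, eqtl = eqtl, gwas = gwas, ld = lds,
    connectivity = connectivity, interaction = interaction,
    truth = list(roles = setNames(assign_roles, gene_ids), seed = seed)
  )
}
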