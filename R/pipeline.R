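#' Select drug-target genes from interaction and connectivity tables
#'
#' Union of genes listed in the drug-gene interaction table and genes
#' whose absolute connectivity score exceeds `score_threshold`, capped at
#' `cap_per_direction` genes per direction (positive / negative) by
#' absolute-score rank. Duplicates collapse to one entry with source
#' precedence `interaction_db` over connectivity.
#'
#' @param interaction_table data frame with a `gene_id` column.
#' @param connectivity_table data frame with `gene_id` and `score`
#'   (percent, in \[-100, 100\]).
#' @param score_threshold absolute connectivity-score cutoff (default 90).
#' @param cap_per_direction maximum genes kept per score direction
#'   (default 20).
#' @return data frame: `gene_id, source, connectivity_score`.
#' @export
select_drug_targets <- function(interaction_table, connectivity_table,
                                score_threshold = 90, cap_per_direction = 20) {
  up <- connectivity_table[connectivity_table$score > score_threshold, , drop = FALSE]
  dn <- connectivity_table[connectivity_table$score < -score_threshold, , drop = FALSE]
  cap <- function(d, src) {
    d <- d[order(-abs(d$score)), , drop = FALSE]
    d <- head(d, cap_per_direction)
    if (nrow(d) == 0) {
      return(data.frame(
        gene_id = character(0), source = character(0),
        connectivity_score = numeric(0)
      ))
    }
    data.frame(gene_id = d$gene_id, source = src, connectivity_score = d$score)
  }
  out <- rbind(
    if (nrow(interaction_table) > 0) {
      data.frame(
        gene_id = unique(interaction_table$gene_id),
        source = "interaction_db", connectivity_score = NA_real_
      )
    },
    cap(up, "connectivity_up"),
    cap(dn, "connectivity_down")
  )
  out <- out[!duplicated(out$gene_id), , drop = FALSE] # interaction_db first
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m_tests number of tests (>= 1).
#' @return `alpha / m_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m_tests) {
  stopifnot(alpha > 0, alpha < 1)
  if (m_tests < 1) stop("m_tests must be at least 1", call. = FALSE)
  thr <- alpha / m_tests
  message(sprintf("Bonferroni threshold: %.3g (%g tests)", thr, m_tests))
  thr
}

#' Phenotype-level MR driver
#'
#' The smoking-phenotype arm of the workflow: select genome-wide
#' significant common instruments, clump them to independence, harmonize
#' against the outcome, and run the full MR estimator suite.
#'
#' @param exposure_table,outcome_table `sumstats` tables.
#' @param ld LD matrix for clumping (SNPs absent from it are treated as
#'   independent); an empty panel is allowed.
#' @param p_threshold,maf_threshold instrument filters (defaults 5e-8, 0.01).
#' @param clump_r2,clump_kb clumping parameters (defaults 0.001, 10000).
#' @param exclude_snps SNPs removed before clumping (used by the
#'   locus-exclusion dependence analysis).
#' @param seed,n_boot,n_presso passed to [run_mr_suite()].
#' @return [run_mr_suite()] output plus `instruments` (the harmonized set).
#' @export
run_phenotype_mr <- function(exposure_table, outcome_table,
                             ld = ld_matrix(matrix(1), "none"),
                             p_threshold = 5e-8, maf_threshold = 0.01,
                             clump_r2 = 0.001, clump_kb = 10000,
                             exclude_snps = character(0),
                             seed = 1, n_boot = 1000, n_presso = 1000) {
  sel <- select_instruments(exposure_table, p_threshold, maf_threshold)
  sel <- setdiff(sel, exclude_snps)
  if (length(sel) == 0) stop("no instruments pass selection", call. = FALSE)
  tab <- exposure_table[exposure_table$snp %in% sel, , drop = FALSE]
  kept <- clump(tab, ld, clump_r2, clump_kb)
  set <- harmonize(exposure_table, outcome_table, snps = as.character(kept))
  if (nrow(set$instruments) == 0) {
    stop("no instruments survive harmonization", call. = FALSE)
  }
  out <- run_mr_suite(set, n_boot = n_boot, n_presso = n_presso, seed = seed)
  out$instruments <- set
  out
}

#' Screen drug-target genes through SMR, HEIDI and colocalization
#'
#' For each gene with eQTL data, runs the SMR test of expression on the
#' outcome; genes passing the Bonferroni-corrected SMR threshold proceed
#' to the HEIDI test and Bayesian colocalization over the gene's +/-100 kb
#' region. A *hit* requires `p_smr` below the threshold, `p_heidi >= 0.05`
#' (no evidence of linkage) and `PP.H4 > pph4_min`. Every gene appears in
#' the report with an explicit status.
#'
#' @param genes data frame with `gene_id`, `has_eqtl`, `tissue` columns
#'   (as produced by [simulate_target_study()] or built from
#'   [select_drug_targets()] output).
#' @param eqtl_panels named list of eQTL [region_panel()]s by gene id.
#' @param gwas_panels named list of outcome panels by gene id (or a single
#'   panel reused for all).
#' @param ld named list of LD matrices by gene id.
#' @param alpha family-wise level for the SMR gate (default 0.05).
#' @param m_tests Bonferroni denominator; default the full gene count
#'   including genes without eQTL data (set
#'   `m_tests = sum(genes$has_eqtl)` for the testable-only convention).
#' @param pph4_min colocalization gate (default 0.9).
#' @param heidi_alpha HEIDI gate (default 0.05).
#' @param p_instrument eQTL instrument threshold (default 5e-8).
#' @param coloc_flank_bp colocalization window flank (default 1e5).
#' @return data frame: per gene, the [smr_heidi()] columns plus
#'   `pp_h0..pp_h4`, `top_shared_snp`, `status` and `hit`.
#' @export
screen_targets <- function(genes, eqtl_panels, gwas_panels, ld,
                           alpha = 0.05, m_tests = nrow(genes),
                           pph4_min = 0.9, heidi_alpha = 0.05,
                           p_instrument = 5e-8, coloc_flank_bp = 1e5) {
  p_thr <- suppressMessages(bonferroni_threshold(alpha, m_tests))
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes$gene_id[i]
    tissue <- if ("tissue" %in% names(genes)) genes$tissue[i] else "unknown"
    base <- data.frame(
      gene = g, tissue = tissue, top_snp = NA_character_,
      b_xy = NA_real_, se_xy = NA_real_, p_smr = NA_real_,
      p_heidi = NA_real_, n_heidi_snps = 0L,
      or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
      pp_h0 = NA_real_, pp_h1 = NA_real_, pp_h2 = NA_real_,
      pp_h3 = NA_real_, pp_h4 = NA_real_, top_shared_snp = NA_character_,
      status = NA_character_, hit = FALSE
    )
    if (!isTRUE(genes$has_eqtl[i]) || is.null(eqtl_panels[[g]])) {
      base$status <- "no-eQTL-data"
      return(base)
    }
    gw <- if (inherits(gwas_panels, "region_panel")) gwas_panels else gwas_panels[[g]]
    res <- tryCatch(
      smr_heidi(eqtl_panels[[g]], gw, ld[[g]],
        gene_id = g, tissue = tissue, p_instrument = p_instrument
      ),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      base$status <- paste0("failed (", res, ")")
      return(base)
    }
    base[names(res)[names(res) != "status"]] <- res[names(res) != "status"]
    if (res$status != "ok") {
      base$status <- "no-valid-instrument"
      return(base)
    }
    if (is.na(res$p_smr) || res$p_smr >= p_thr) {
      base$status <- "failed-gate-smr"
      return(base)
    }
    if (!is.na(res$p_heidi) && res$p_heidi < heidi_alpha) {
      base$status <- "failed-gate-heidi"
      return(base)
    }
    cl <- tryCatch(
      {
        gene_pred <- if (all(c("chrom", "start", "end") %in% names(genes))) {
          define_coloc_region(genes$chrom[i], genes$start[i], genes$end[i],
            flank_bp = coloc_flank_bp
          )
        } else {
          NULL
        }
        e <- eqtl_panels[[g]]
        g2 <- gw
        if (!is.null(gene_pred)) {
          keep_e <- gene_pred(e$data$chr, e$data$pos)
          keep_g <- gene_pred(g2$data$chr, g2$data$pos)
          e$data <- e$data[keep_e, , drop = FALSE]
          g2$data <- g2$data[keep_g, , drop = FALSE]
        }
        suppressWarnings(coloc_abf(e, g2))
      },
      error = function(e) conditionMessage(e)
    )
    if (is.character(cl)) {
      base$status <- paste0("failed (", cl, ")")
      return(base)
    }
    base[c("pp_h0", "pp_h1", "pp_h2", "pp_h3", "pp_h4")] <- as.list(cl$pp)
    base$top_shared_snp <- cl$top_shared_snp
    if (cl$pp["h4"] <= pph4_min) {
      base$status <- "failed-gate-coloc"
      return(base)
    }
    base$status <- "hit"
    base$hit <- TRUE
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "p_smr_threshold") <- p_thr
  out
}

#' Locus-dependence mediation test
#'
#' Contrasts the mediator-on-outcome effect proxied by a single focal
#' variant (Wald ratio) with the effect estimated from all other
#' instruments after excluding every SNP within the gene region plus
#' flank. If the locus acts on the outcome only through the mediator, the
#' two estimates should agree; a focal estimate well above the
#' locus-excluded one indicates an additional direct pathway. Both the
#' 95%-CI overlap and the effect ratio are reported; no verdict is
#' hard-coded.
#'
#' @param mediator_gwas,outcome_gwas `sumstats` tables.
#' @param focal_snp the variant proxying the locus.
#' @param gene_region list with `chrom`, `start`, `end`.
#' @param flank_bp exclusion flank (default 1e5).
#' @param ld LD matrix for clumping.
#' @param ... passed to [run_phenotype_mr()].
#' @return list with `estimate_focal`, `estimate_excluding`
#'   ([mr_estimate()]s), `ci_overlap`, `ratio_of_effects`.
#' @export
dependence_test <- function(mediator_gwas, outcome_gwas, focal_snp,
                            gene_region, flank_bp = 1e5,
                            ld = ld_matrix(matrix(1), "none"), ...) {
  i_m <- match(focal_snp, mediator_gwas$snp)
  i_o <- match(focal_snp, outcome_gwas$snp)
  if (is.na(i_m) || is.na(i_o)) {
    stop("focal SNP absent from mediator or outcome", call. = FALSE)
  }
  focal_set <- harmonize(mediator_gwas, outcome_gwas, snps = focal_snp)
  if (nrow(focal_set$instruments) == 0) {
    stop("focal SNP could not be harmonized", call. = FALSE)
  }
  fi <- focal_set$instruments
  est_focal <- wald_ratio(fi$beta_exposure, fi$se_exposure, fi$beta_outcome, fi$se_outcome)

  excl_pred <- cis_window(gene_region$chrom, gene_region$start, gene_region$end,
    flank_bp = flank_bp
  )
  in_locus <- mediator_gwas$snp[excl_pred(mediator_gwas$chr, mediator_gwas$pos)]
  fit <- run_phenotype_mr(mediator_gwas, outcome_gwas,
    ld = ld,
    exclude_snps = union(in_locus, focal_snp), ...
  )
  est_excl <- fit$estimates[fit$estimates$method == "ivw", ]
  if (nrow(fit$instruments$instruments) < 2) {
    stop("fewer than 2 instruments remain after locus exclusion", call. = FALSE)
  }
  ci_overlap <- est_focal$ci_low <= est_excl$ci_high &&
    est_excl$ci_low <= est_focal$ci_high
  list(
    focal_snp = focal_snp,
    estimate_focal = est_focal,
    estimate_excluding = mr_estimate("ivw_excluding_locus", est_excl$beta,
      est_excl$se,
      pval = est_excl$pval, n_snp = est_excl$nsnp
    ),
    ci_overlap = ci_overlap,
    ratio_of_effects = est_focal$beta / est_excl$beta
  )
}

#' Single-instrument MR of expression and mediator on the outcome
#'
#' Runs two Wald-ratio analyses sharing one genetic instrument: gene
#' expression on the outcome, and the mediator phenotype on the outcome —
#' the pattern used to probe a pharmacologically flagged variant.
#'
#' @param eqtl_panel [region_panel()] of cis-eQTL statistics.
#' @param mediator_gwas,outcome_gwas `sumstats` tables.
#' @param snp the shared instrument.
#' @return list with `expression_on_outcome` and `mediator_on_outcome`
#'   ([mr_estimate()]s, odds-ratio columns via `as.data.frame`).
#' @export
single_instrument_mode <- function(eqtl_panel, mediator_gwas, outcome_gwas, snp) {
  ie <- match(snp, eqtl_panel$data$snp)
  im <- match(snp, mediator_gwas$snp)
  io <- match(snp, outcome_gwas$snp)
  if (any(is.na(c(ie, im, io)))) {
    stop("SNP absent from one of the datasets", call. = FALSE)
  }
  if (eqtl_panel$data$beta[ie] == 0) stop("null instrument", call. = FALSE)
  expr_est <- wald_ratio(
    eqtl_panel$data$beta[ie], eqtl_panel$data$se[ie],
    outcome_gwas$beta[io], outcome_gwas$se[io]
  )
  med_set <- harmonize(mediator_gwas, outcome_gwas, snps = snp)
  if (nrow(med_set$instruments) == 0) {
    stop("SNP could not be harmonized between mediator and outcome", call. = FALSE)
  }
  mi <- med_set$instruments
  med_est <- wald_ratio(mi$beta_exposure, mi$se_exposure, mi$beta_outcome, mi$se_outcome)
  list(expression_on_outcome = expr_est, mediator_on_outcome = med_est)
}

#' Confounder / mediator assessment at a gene locus
#'
#' For each candidate confounder phenotype: colocalization with the
#' outcome at the locus, colocalization with the gene's expression,
#' SMR of expression on the confounder, and IVW MR of the confounder on
#' the outcome. A confounder qualifies as a candidate mediator iff both
#' colocalizations give `PP.H4 > pph4_min` and the IVW p-value is below
#' `alpha`.
#'
#' @param eqtl_panel gene expression [region_panel()] at the locus.
#' @param confounders named list; each element a list with `region`
#'   (the confounder's [region_panel()] at the locus), `gwas`
#'   (genome-wide `sumstats` for the IVW arm) and optionally `ld`.
#' @param outcome_region outcome [region_panel()] at the locus.
#' @param outcome_gwas genome-wide outcome `sumstats`.
#' @param ld LD matrix at the locus.
#' @param pph4_min,alpha gate parameters.
#' @param ... passed to [run_phenotype_mr()] for the IVW arm.
#' @return data frame: per confounder, `pp_h4_outcome`, `pp_h4_gene`,
#'   `p_smr_gene_on_conf`, `ivw_beta`, `ivw_p`, `candidate_mediator`.
#' @export
run_confounder_analysis <- function(eqtl_panel, confounders, outcome_region,
                                    outcome_gwas, ld,
                                    pph4_min = 0.9, alpha = 0.05, ...) {
  rows <- lapply(names(confounders), function(nm) {
    cf <- confounders[[nm]]
    res <- tryCatch(
      {
        cl_out <- suppressWarnings(coloc_abf(cf$region, outcome_region))
        cl_gene <- suppressWarnings(coloc_abf(eqtl_panel, cf$region))
        smr <- smr_test(eqtl_panel, cf$region)
        fit <- run_phenotype_mr(cf$gwas, outcome_gwas, ld = cf$ld %||% ld, ...)
        iv <- fit$estimates[fit$estimates$method == "ivw", ]
        data.frame(
          confounder = nm,
          pp_h4_outcome = unname(cl_out$pp["h4"]),
          pp_h4_gene = unname(cl_gene$pp["h4"]),
          p_smr_gene_on_conf = smr$p_smr,
          ivw_beta = iv$beta, ivw_p = iv$pval,
          candidate_mediator = cl_out$pp["h4"] > pph4_min &&
            cl_gene$pp["h4"] > pph4_min && iv$pval < alpha,
          status = "ok"
        )
      },
      error = function(e) {
        data.frame(
          confounder = nm, pp_h4_outcome = NA_real_, pp_h4_gene = NA_real_,
          p_smr_gene_on_conf = NA_real_, ivw_beta = NA_real_, ivw_p = NA_real_,
          candidate_mediator = FALSE,
          status = paste0("failed (", conditionMessage(e), ")")
        )
      }
    )
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
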