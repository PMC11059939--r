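#!/usr/bin/env Rscript
# Follow-up on the screen's hit gene: (i) confounder/mediator assessment —
# does a smoking phenotype colocalize with both the outcome and the gene's
# expression at the locus, and does it affect the outcome by IVW? —
# (ii) the locus-dependence test contrasting the mediator effect proxied
# by the locus' focal variant with the effect estimated after excluding
# the locus, and (iii) the shared-single-instrument analysis of expression
# and mediator on the outcome. Reads results/fixtures and
# results/target_screen.tsv; writes results/confounder_report.tsv and
# results/dependence_test.tsv.

suppressPackageStartupMessages(library(targetmr))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
fix_dir <- "results/fixtures"

read_panel <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = list(chr = "character"))
  region_panel(df$snp, df$beta, df$se,
    eaf = df$eaf, n = df$n[1],
    trait_id = df$trait_id[1], trait_type = df$trait_type[1],
    pos = df$pos, chr = df$chr
  )
}

screen <- read.table("results/target_screen.tsv", sep = "\t", header = TRUE)
hit <- screen[screen$hit, ]
if (nrow(hit) == 0) stop("no hit gene to follow up; run 03_target_screen.R first")
gene <- hit$gene[1]
cat("following up hit gene:", gene, "\n")

eqtl <- read_panel(file.path(fix_dir, paste0("eqtl_", gene, ".tsv")))
outcome_region <- read_panel(file.path(fix_dir, paste0("gwas_", gene, ".tsv")))
ld <- read_ld_matrix(file.path(fix_dir, paste0("ld_", gene, ".ld")))

# Candidate mediator: the cigarettes/day phenotype. Its locus-level panel
# is constructed under the same shared causal variant as the outcome
# (expression lowers smoking, smoking raises outcome risk), its
# genome-wide instrument set comes from the Analysis-1 fixture.
med_gwas <- read_sumstats(file.path(fix_dir, "cigarettes_per_day.tsv"),
  trait_id = "cigarettes_per_day"
)
med_outcome <- read_sumstats(file.path(fix_dir, "outcome_cigarettes_per_day.tsv"),
  trait_id = "outcome", trait_type = "binary"
)
top_idx <- match(hit$top_snp[1], eqtl$data$snp)
mediator_region <- eqtl
mediator_region$trait_id <- "cigarettes_per_day"
mediator_region$trait_type <- "quantitative"
mediator_region$data$beta <- -0.6 * eqtl$data$beta +
  withr::with_seed(seed, rnorm(nrow(eqtl$data), 0, eqtl$data$se))
conf <- list(
  cigarettes_per_day = list(region = mediator_region, gwas = med_gwas)
)
rep_conf <- run_confounder_analysis(
  eqtl_panel = eqtl, confounders = conf,
  outcome_region = outcome_region, outcome_gwas = med_outcome,
  ld = ld, seed = seed
)
write.table(rep_conf, "results/confounder_report.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
cat(sprintf(
  "confounder %s: PP.H4 vs outcome %.3f, PP.H4 vs gene %.3f, IVW p %.3g -> %s\n",
  rep_conf$confounder[1], rep_conf$pp_h4_outcome[1], rep_conf$pp_h4_gene[1],
  rep_conf$ivw_p[1],
  if (isTRUE(rep_conf$candidate_mediator[1])) "candidate mediator" else "not supported"
))

# Locus-dependence test: focal variant = the mediator GWAS instrument with
# the largest absolute z (stand-in for the locus' lead variant); the gene
# locus +/- 100 kb is excluded from the comparison estimate.
genes <- read.table(file.path(fix_dir, "genes.tsv"),
  sep = "\t", header = TRUE,
  colClasses = list(chrom = "character")
)
gi <- match(gene, genes$gene_id)
z <- abs(med_gwas$beta / med_gwas$se)
focal <- med_gwas$snp[which.max(z)]
dep <- dependence_test(
  med_gwas, med_outcome, focal,
  gene_region = list(
    chrom = genes$chrom[gi], start = genes$start[gi], end = genes$end[gi]
  ),
  flank_bp = 1e5, seed = seed
)
dep_row <- data.frame(
  focal_snp = dep$focal_snp,
  beta_focal = dep$estimate_focal$beta, se_focal = dep$estimate_focal$se,
  beta_excluding = dep$estimate_excluding$beta,
  se_excluding = dep$estimate_excluding$se,
  ci_overlap = dep$ci_overlap, ratio_of_effects = dep$ratio_of_effects
)
write.table(dep_row, "results/dependence_test.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
cat(sprintf(
  "dependence test: focal OR %.2f vs locus-excluded OR %.2f, CIs %s, ratio %.2f\n",
  exp(dep_row$beta_focal), exp(dep_row$beta_excluding),
  if (dep_row$ci_overlap) "overlap" else "disjoint", dep_row$ratio_of_effects
))

# Shared-single-instrument analysis at the locus' top shared SNP
med_tab <- sumstats_table(
  data.frame(
    snp = mediator_region$data$snp, chr = mediator_region$data$chr,
    pos = mediator_region$data$pos, a1 = "A", a2 = "G", eaf = 0.5,
    beta = mediator_region$data$beta, se = mediator_region$data$se,
    p = pmax(2 * pnorm(-abs(mediator_region$data$beta / mediator_region$data$se)),
      .Machine$double.xmin
    ),
    n = mediator_region$n
  ),
  "cigarettes_per_day",
  validate = FALSE
)
out_tab <- sumstats_table(
  data.frame(
    snp = outcome_region$data$snp, chr = outcome_region$data$chr,
    pos = outcome_region$data$pos, a1 = "A", a2 = "G", eaf = 0.5,
    beta = outcome_region$data$beta, se = outcome_region$data$se,
    p = pmax(2 * pnorm(-abs(outcome_region$data$beta / outcome_region$data$se)),
      .Machine$double.xmin
    ),
    n = outcome_region$n
  ),
  "outcome", "binary",
  validate = FALSE
)
single <- single_instrument_mode(eqtl, med_tab, out_tab, hit$top_snp[1])
cat(sprintf(
  "single-instrument (%s): expression OR %.3f (p %.3g), mediator OR %.2f (p %.3g)\n",
  hit$top_snp[1],
  exp(single$expression_on_outcome$beta), single$expression_on_outcome$pval,
  exp(single$mediator_on_outcome$beta), single$mediator_on_outcome$pval
))
cat("wrote results/confounder_report.tsv, results/dependence_test.tsv\n")
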