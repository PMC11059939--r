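#!/usr/bin/env Rscript
# Build the synthetic study: summary statistics for four smoking-behaviour
# phenotypes against a case-control outcome, plus a 10-gene drug-target
# screening fixture (cis-eQTL and outcome panels, LD, drug-gene tables).
# Everything downstream (02-04) reads the files written here.

suppressPackageStartupMessages(library(targetmr))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
fix_dir <- "results/fixtures"
dir.create(fix_dir, recursive = TRUE, showWarnings = FALSE)

# Four exposure phenotypes: two with a real effect on the outcome (odds
# ratios 2.89 and 4.64 on the log-odds scale), two null. Instrument counts
# are desk-scale stand-ins for the genome-wide instrument sets such
# phenotypes typically yield.
phenos <- list(
  cigarettes_per_day = list(theta = log(2.89), k = 40),
  smoking_initiation = list(theta = log(4.64), k = 80),
  age_of_initiation  = list(theta = 0, k = 30),
  smoking_cessation  = list(theta = 0, k = 20)
)

for (nm in names(phenos)) {
  p <- phenos[[nm]]
  sim <- simulate_two_sample(mr_scenario_config(
    n_instruments = p$k, theta = p$theta,
    seed = seed + match(nm, names(phenos))
  ))
  write_sumstats(sim$exposure, file.path(fix_dir, paste0(nm, ".tsv")))
  write_sumstats(sim$outcome, file.path(fix_dir, paste0("outcome_", nm, ".tsv")))
  write.table(sim$truth, file.path(fix_dir, paste0("truth_", nm, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  cat(sprintf(
    "%-20s %2d instruments, true log-OR %.3f -> %s\n",
    nm, p$k, p$theta, paste0(nm, ".tsv")
  ))
}

# Drug-target screen fixture: 10 genes, 1 with a genuine shared causal
# variant between its expression and the outcome.
fx <- simulate_target_study(n_genes = 10, n_causal = 1, seed = seed)
write.table(fx$genes, file.path(fix_dir, "genes.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
write.table(fx$connectivity, file.path(fix_dir, "connectivity.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
write.table(fx$interaction, file.path(fix_dir, "interaction.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
write_panel <- function(panel, path) {
  df <- panel$data
  df$trait_id <- panel$trait_id
  df$trait_type <- panel$trait_type
  df$n <- panel$n
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
for (g in names(fx$ld)) {
  write_ld_matrix(fx$ld[[g]], file.path(fix_dir, paste0("ld_", g, ".ld")))
  if (!is.null(fx$eqtl[[g]])) {
    write_panel(fx$eqtl[[g]], file.path(fix_dir, paste0("eqtl_", g, ".tsv")))
  }
  write_panel(fx$gwas[[g]], file.path(fix_dir, paste0("gwas_", g, ".tsv")))
}
manifest <- data.frame(gene_id = names(fx$truth$roles), role = fx$truth$roles)
write.table(manifest, file.path(fix_dir, "truth_genes.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
cat(sprintf(
  "target study: %d genes (%s causal, %d without eQTL data) -> %s\n",
  nrow(fx$genes), manifest$gene_id[manifest$role == "causal"],
  sum(!fx$genes$has_eqtl), fix_dir
))
cat("seed:", seed, "\n")
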