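test_that("reading a summary-statistics file is header-driven and round-trips", {
  df <- make_sumstats_df()
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

  tab <- read_sumstats(path, trait_id = "t")
  expect_s3_class(tab, "sumstats")
  expect_equal(nrow(tab), 3)
  expect_equal(nrow(attr(tab, "dropped")), 0)

  # permuted column order with named header parses identically
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df[, rev(names(df))], path2, sep = "\t", quote = FALSE, row.names = FALSE)
  tab2 <- read_sumstats(path2, trait_id = "t")
  expect_equal(as.data.frame(tab), as.data.frame(tab2))

  # write -> read round-trip is identity
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path3)
  tab3 <- read_sumstats(path3, trait_id = "t")
  expect_equal(as.data.frame(tab), as.data.frame(tab3))

  # dialect map renames a GCTA-COJO-style header
  ma <- df
  names(ma) <- c("SNP", "chrom", "bp", "A1", "A2", "freq", "b", "SE", "P", "N")
  path4 <- withr::local_tempfile(fileext = ".ma")
  write.table(ma, path4, sep = "\t", quote = FALSE, row.names = FALSE)
  tab4 <- read_sumstats(path4,
    trait_id = "t",
    dialect = c(
      SNP = "snp", chrom = "chr", bp = "pos", A1 = "a1", A2 = "a2",
      freq = "eaf", b = "beta", SE = "se", P = "p", N = "n"
    )
  )
  expect_equal(as.data.frame(tab), as.data.frame(tab4))
})

test_that("missing mandatory columns and malformed rows are handled", {
  df <- make_sumstats_df()
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df[setdiff(names(df), "se")], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path), "missing column: se")

  bad <- make_sumstats_df(snp = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs1"))
  bad$se[2] <- -1        # nonpositive se
  bad$eaf[3] <- 1.2      # out of range
  bad$p[4] <- bad$p[4] * 100 # inconsistent with beta/se
  tab <- sumstats_table(bad, "t")
  dropped <- attr(tab, "dropped")
  expect_equal(nrow(tab), 2)
  expect_setequal(
    dropped$reason,
    c("nonpositive-se", "eaf-out-of-range", "pval-inconsistent", "duplicate-snp")
  )
})

test_that("instrument selection applies strict p and MAF thresholds", {
  df <- make_sumstats_df(
    snp = c("rs1", "rs2", "rs3"),
    beta = c(0.1, 0.1, 0.1), se = c(0.0164, 0.0188, 0.0164)
  )
  # engineered p-values: rs1 ~1e-9, rs2 ~1e-7, rs3 ~1e-9 but rare
  df$eaf <- c(0.3, 0.3, 0.005)
  tab <- sumstats_table(df, "t")
  expect_lt(tab$p[1], 5e-8)
  expect_gt(tab$p[2], 5e-8)
  expect_equal(select_instruments(tab, 5e-8, 0.01), "rs1")
  # no SNP passes -> empty, no error
  expect_equal(select_instruments(tab, 1e-20, 0.01), character(0))
  # threshold is strict: eaf exactly at the MAF bound is excluded
  df2 <- make_sumstats_df(snp = "rs9", beta = 0.2, se = 0.02, eaf = 0.01)
  expect_equal(select_instruments(sumstats_table(df2, "t")), character(0))
})

test_that("greedy clumping follows the p-value, window and r2 rules", {
  ld <- ld_matrix(matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2), c("rs1", "rs2"))
  near <- make_table(
    snp = c("rs1", "rs2"), pos = c(1e6, 1e6 + 5000),
    beta = c(0.12, 0.1), se = 0.02
  )
  expect_equal(as.character(clump(near, ld, 0.001, 10000)), "rs1")

  far <- make_table(
    snp = c("rs1", "rs2"), pos = c(1e6, 1e6 + 15e6),
    beta = c(0.12, 0.1), se = 0.02
  )
  expect_setequal(as.character(clump(far, ld, 0.001, 10000)), c("rs1", "rs2"))

  # r2 threshold 1 keeps everything (r2 > 1 never true)
  expect_setequal(as.character(clump(near, ld, 1, 10000)), c("rs1", "rs2"))
  # window 0 keeps everything regardless of LD
  expect_setequal(as.character(clump(near, ld, 0.001, 0)), c("rs1", "rs2"))
  # r2 threshold 0: one SNP per window-connected LD component
  ld3 <- ld_matrix(diag(3) * 0.9 + 0.1, c("rs1", "rs2", "rs3"))
  trio <- make_table(
    snp = c("rs1", "rs2", "rs3"), pos = c(1e6, 1.1e6, 1.2e6),
    beta = c(0.1, 0.1, 0.12), se = 0.02
  )
  expect_equal(as.character(clump(trio, ld3, 0, 10000)), "rs3")

  # ties broken by (chrom, pos, snp_id); SNPs absent from LD treated independent
  tie <- make_table(
    snp = c("rsB", "rsA"), pos = c(2e6, 1e6),
    beta = c(0.1, 0.1), se = 0.02
  )
  kept <- clump(tie, ld_matrix(matrix(1), "zz"), 0.001, 10000)
  expect_equal(as.character(kept), c("rsA", "rsB"))
  expect_setequal(attr(kept, "no_ld"), c("rsA", "rsB"))
})

test_that("cis-window predicate uses closed 1-based intervals", {
  pred <- cis_window("1", 1000, 2000, flank_bp = 1e6)
  expect_true(pred("1", 500000))
  expect_false(pred("1", 1200000)) # 2000 + 1e6 = 1,002,000 < 1,200,000
  expect_true(pred("1", 1002000)) # boundary included
  expect_false(pred("2", 500000)) # wrong chromosome
  expect_error(cis_window("1", 1000, 2000, flank_bp = -1), "non-negative")
})

test_that("harmonization aligns alleles, flips swapped strands, drops ambiguity", {
  exp_tab <- make_table(snp = c("rs1", "rs2", "rs3"), a1 = "A", a2 = "G", beta = 0.1)
  out_df <- make_sumstats_df(
    snp = c("rs1", "rs2", "rs3"),
    a1 = c("G", "T", "A"), a2 = c("A", "C", "C"),
    beta = c(0.2, 0.15, 0.1), eaf = 0.7
  )
  out_tab <- sumstats_table(out_df, "out")
  h <- harmonize(exp_tab, out_tab)
  ins <- h$instruments
  # rs1: swapped alleles -> beta negated
  expect_equal(ins$beta_outcome[ins$snp == "rs1"], -0.2)
  # rs2: T/C is the complement strand of A/G, aligned -> unchanged
  expect_equal(ins$beta_outcome[ins$snp == "rs2"], 0.15)
  # rs3: A/C irreconcilable with A/G
  expect_equal(h$dropped$reason[h$dropped$snp == "rs3"], "allele-mismatch")
})

test_that("palindromic SNPs are resolved by allele frequency or dropped", {
  amb <- make_table(snp = "rs1", a1 = "A", a2 = "T", eaf = 0.50)
  out <- make_table(snp = "rs1", a1 = "A", a2 = "T", eaf = 0.50)
  h <- harmonize(amb, out, palindrome_eaf_band = 0.08)
  expect_equal(h$dropped$reason, "palindromic-ambiguous")

  clear <- make_table(snp = "rs1", a1 = "A", a2 = "T", eaf = 0.2, beta = 0.1)
  out2 <- make_table(snp = "rs1", a1 = "A", a2 = "T", eaf = 0.25, beta = 0.3)
  h2 <- harmonize(clear, out2)
  expect_equal(h2$instruments$beta_outcome, 0.3)

  # discordant frequency sides -> dropped, not silently flipped
  out3 <- make_table(snp = "rs1", a1 = "A", a2 = "T", eaf = 0.8, beta = 0.3)
  h3 <- harmonize(clear, out3)
  expect_equal(h3$dropped$reason, "palindromic-ambiguous")
})

test_that("harmonization is idempotent and invariant to outcome allele flips", {
  withr::local_seed(42)
  k <- 12
  exp_tab <- make_table(
    snp = paste0("rs", 1:k), pos = seq(1e6, by = 1e6, length.out = k),
    beta = rnorm(k, 0, 0.05), se = 0.01, eaf = runif(k, 0.1, 0.45)
  )
  out_df <- make_sumstats_df(
    snp = paste0("rs", 1:k), pos = seq(1e6, by = 1e6, length.out = k),
    beta = rnorm(k, 0, 0.05), se = 0.01, eaf = runif(k, 0.1, 0.45)
  )
  out_tab <- sumstats_table(out_df, "out")
  h1 <- harmonize(exp_tab, out_tab)

  # flip effect/other alleles and negate beta in the raw outcome: no change
  flipped <- out_df
  flipped$a1 <- out_df$a2
  flipped$a2 <- out_df$a1
  flipped$beta <- -out_df$beta
  flipped$eaf <- 1 - out_df$eaf
  h2 <- harmonize(exp_tab, sumstats_table(flipped, "out"))
  expect_equal(h1$instruments, h2$instruments)

  # idempotence: re-expressing the harmonized outcome as a table and
  # harmonizing again changes nothing
  out_harm <- out_df
  out_harm$a1 <- "A"
  out_harm$a2 <- "G"
  out_harm$beta <- h1$instruments$beta_outcome
  out_harm$eaf <- 0.3
  h3 <- harmonize(exp_tab, sumstats_table(out_harm, "out"))
  expect_equal(h3$instruments$beta_outcome, h1$instruments$beta_outcome)
  expect_equal(nrow(h3$dropped), 0)
})

test_that("LD matrix construction validates and file round-trips", {
  r <- matrix(c(1, 0.5, 0.5, 1), 2)
  m <- ld_matrix(r, c("a", "b"))
  expect_equal(rownames(m), c("a", "b"))
  expect_error(ld_matrix(r, "a"), "dimensions")
  expect_error(ld_matrix(matrix(c(1, 2, 2, 1), 2), c("a", "b")), "\\[-1, 1\\]")

  path <- withr::local_tempfile(fileext = ".ld")
  write_ld_matrix(m, path)
  m2 <- read_ld_matrix(path)
  expect_equal(m, m2)
})
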