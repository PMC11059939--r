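# shared fixture builders; everything generated in code, no stored data

# minimal valid sumstats data frame, p consistent with beta/se
make_sumstats_df <- function(snp = c("rs1", "rs2", "rs3"),
                             chr = "1",
                             pos = c(1e6, 2e6, 3e6),
                             a1 = "A", a2 = "G",
                             eaf = 0.3,
                             beta = c(0.1, -0.05, 0.02),
                             se = 0.02,
                             n = 1e4) {
  k <- length(snp)
  beta <- rep_len(beta, k)
  se <- rep_len(se, k)
  data.frame(
    snp = snp, chr = rep_len(chr, k), pos = rep_len(pos, k),
    a1 = rep_len(a1, k), a2 = rep_len(a2, k), eaf = rep_len(eaf, k),
    beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)), n = rep_len(n, k)
  )
}

make_table <- function(...) sumstats_table(make_sumstats_df(...), "trait")

# the hand-computed two-instrument worked example:
# (bx, by, se_y) = (0.1, 0.2, 0.1), (0.2, 0.3, 0.1)
# ratios 2.0 and 1.5 with weights bx^2/se_y^2 = 1 and 4
# -> ivw beta = (1*2 + 4*1.5)/5 = 1.6, fixed se = (0.01*100+0.04*100)^-0.5
# -> Q = 1*(2-1.6)^2 + 4*(1.5-1.6)^2 = 0.2
two_instrument_set <- function() {
  harmonized_set(
    beta_exposure = c(0.1, 0.2), se_exposure = c(0.02, 0.02),
    beta_outcome = c(0.2, 0.3), se_outcome = c(0.1, 0.1)
  )
}

# exact-fit instruments: by = slope * bx, heterogeneity-free
exact_line_set <- function(slope = 1.5, k = 5) {
  bx <- seq(0.05, 0.25, length.out = k)
  harmonized_set(bx, rep(0.01, k), slope * bx, rep(0.05, k))
}
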