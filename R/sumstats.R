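#' @title Summary-statistics tables
#' @description A `sumstats` object is a data frame of per-SNP marginal
#'   association statistics for one trait, with canonical columns
#'   `snp, chr, pos, a1, a2, eaf, beta, se, p, n` (`a1` is the effect
#'   allele) and attributes `trait_id` and `trait_type`
#'   (`"binary"` or `"quantitative"`; betas are log-odds for binary traits).
#' @name sumstats
NULL

SUMSTATS_COLS <- c("snp", "chr", "pos", "a1", "a2", "eaf", "beta", "se", "p", "n")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a summary-statistics table
#'
#' Validates per-SNP records and drops rows violating the data model:
#' identical alleles, non-ACGT alleles, `se <= 0`, `eaf` outside (0,1),
#' `p` outside (0,1], duplicated SNP ids, or a p-value inconsistent with
#' `|beta/se|` under a two-sided normal test (checked to 10% relative
#' tolerance on the -log10 scale when both are finite and p is not
#' underflowed).
#'
#' @param df data frame with the canonical columns (`n` optional).
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param validate if `FALSE`, skip row screening (trusted input).
#' @return A `sumstats` data frame; dropped rows are recorded in
#'   `attr(x, "dropped")` as a data frame of `(snp, reason)`.
#' @export
sumstats_table <- function(df, trait_id, trait_type = c("quantitative", "binary"),
                           validate = TRUE) {
  trait_type <- match.arg(trait_type)
  if (!"n" %in% names(df)) df$n <- NA_real_
  missing <- setdiff(setdiff(SUMSTATS_COLS, "n"), names(df))
  if (length(missing) > 0) {
    stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[SUMSTATS_COLS]
  df$snp <- as.character(df$snp)
  df$chr <- as.character(df$chr)
  df$a1 <- toupper(as.character(df$a1))
  df$a2 <- toupper(as.character(df$a2))
  for (col in c("pos", "eaf", "beta", "se", "p", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  dropped <- data.frame(snp = character(0), reason = character(0))
  if (validate && nrow(df) > 0) {
    reason <- rep(NA_character_, nrow(df))
    num_ok <- complete.cases(df[c("pos", "eaf", "beta", "se", "p")])
    reason[!num_ok] <- "unparseable-numeric"
    bad_allele <- !(df$a1 %in% VALID_ALLELES) | !(df$a2 %in% VALID_ALLELES) |
      df$a1 == df$a2
    reason[is.na(reason) & bad_allele] <- "invalid-alleles"
    with_num <- is.na(reason)
    reason[with_num & df$se <= 0] <- "nonpositive-se"
    with_num <- is.na(reason)
    reason[with_num & (df$eaf <= 0 | df$eaf >= 1)] <- "eaf-out-of-range"
    with_num <- is.na(reason)
    reason[with_num & (df$p <= 0 | df$p > 1)] <- "pval-out-of-range"
    with_num <- is.na(reason)
    if (any(with_num)) {
      p_imp <- 2 * pnorm(-abs(df$beta[with_num] / df$se[with_num]))
      # compare on -log10 scale; skip where either underflows to 0
      ok <- p_imp > 0 & df$p[with_num] > 0
      rel <- abs(log10(df$p[with_num]) - log10(p_imp)) /
        pmax(1, abs(log10(p_imp)))
      inconsistent <- ok & rel > 0.1
      reason[which(with_num)[inconsistent]] <- "pval-inconsistent"
    }
    dup <- duplicated(df$snp) & is.na(reason)
    reason[dup] <- "duplicate-snp"
    keep <- is.na(reason)
    dropped <- data.frame(snp = df$snp[!keep], reason = reason[!keep])
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df,
    trait_id = trait_id, trait_type = trait_type, dropped = dropped,
    class = c("sumstats", "data.frame")
  )
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf(
    "<sumstats> trait '%s' (%s), %d SNPs\n",
    attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)
  ))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read a summary-statistics file
#'
#' Tab-separated with a header; a `dialect` map translates non-canonical
#' column names, e.g. `c(SNP = "snp", A1 = "a1", b = "beta")` for a
#' GCTA-COJO `.ma` layout. Gzipped files are accepted transparently.
#'
#' @param path file path.
#' @param trait_id trait name; defaults to the file name.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param dialect named character vector mapping file column names to
#'   canonical names; unmapped canonical names are used as-is.
#' @return A [sumstats_table()]; malformed rows are dropped and recorded in
#'   `attr(x, "dropped")`.
#' @export
read_sumstats <- function(path, trait_id = NULL,
                          trait_type = c("quantitative", "binary"),
                          dialect = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(trait_id)) trait_id <- sub("\\.(tsv|txt|ma)(\\.gz)?$", "", basename(path))
  df <- read.table(path,
    header = TRUE, sep = "\t", colClasses = "character",
    check.names = FALSE, stringsAsFactors = FALSE, comment.char = ""
  )
  if (!is.null(dialect)) {
    hit <- names(df) %in% names(dialect)
    names(df)[hit] <- unname(dialect[names(df)[hit]])
  }
  mandatory <- c("snp", "a1", "a2", "beta", "se", "p")
  absent <- setdiff(mandatory, names(df))
  if (length(absent) > 0) {
    stop("missing column: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  sumstats_table(df, trait_id = trait_id, trait_type = trait_type)
}

#' Write a summary-statistics table
#'
#' Inverse of [read_sumstats()]: tab-separated, canonical header.
#' @param x a `sumstats` table.
#' @param path output path (`.gz` suffix writes gzipped).
#' @export
write_sumstats <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(as.data.frame(x)[SUMSTATS_COLS], con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Construct an LD correlation matrix
#'
#' @param r square numeric matrix of pairwise correlations in \[-1, 1\].
#' @param snp_ids SNP identifiers, one per row/column.
#' @return A symmetric matrix with unit diagonal and `snp_ids` as dimnames.
#'   Eigenvalues below `-1e-8` raise an error; tiny negative eigenvalues are
#'   clipped to zero by symmetric reconstruction.
#' @export
ld_matrix <- function(r, snp_ids) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r) || nrow(r) != length(snp_ids)) {
    stop("LD matrix dimensions do not match snp_ids", call. = FALSE)
  }
  if (any(abs(r) > 1 + 1e-8)) stop("LD correlations must lie in [-1, 1]", call. = FALSE)
  r <- (r + t(r)) / 2
  ev <- eigen(r, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    r <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    r <- (r + t(r)) / 2
  }
  diag(r) <- 1
  dimnames(r) <- list(snp_ids, snp_ids)
  r
}

#' Read / write an LD matrix file
#'
#' Format: first line the whitespace-separated SNP ids, then the square
#' correlation matrix row-major, whitespace-separated.
#' @param path file path.
#' @return the LD matrix with SNP ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  vals <- scan(text = paste(lines[-1], collapse = "\n"), quiet = TRUE)
  r <- matrix(vals, nrow = length(ids), byrow = TRUE)
  ld_matrix(r, ids)
}

#' @rdname read_ld_matrix
#' @param r LD matrix with dimnames.
#' @export
write_ld_matrix <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(r), collapse = " "), con)
  write.table(unname(r), con,
    sep = " ", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Select genetic instruments by significance and frequency
#'
#' Keeps SNPs with `p < p_threshold` (strict) and minor-allele frequency
#' `min(eaf, 1 - eaf) > maf_threshold` (strict).
#'
#' @param table a `sumstats` table.
#' @param p_threshold genome-wide significance cutoff (default 5e-8).
#' @param maf_threshold minor-allele-frequency cutoff (default 0.01).
#' @return character vector of SNP ids (possibly empty).
#' @export
select_instruments <- function(table, p_threshold = 5e-8, maf_threshold = 0.01) {
  stopifnot(p_threshold > 0, p_threshold < 1, maf_threshold > 0, maf_threshold < 1)
  maf <- pmin(table$eaf, 1 - table$eaf)
  table$snp[table$p < p_threshold & maf > maf_threshold]
}

#' Greedy LD clumping
#'
#' Sorts SNPs by ascending p-value (ties broken by chromosome, position,
#' SNP id) and accepts each SNP unless an already-accepted SNP on the same
#' chromosome lies within `window_kb` kilobases *and* has squared
#' correlation above `r2_threshold` with it. SNPs absent from the LD matrix
#' are treated as independent of everything and recorded in
#' `attr(result, "no_ld")`.
#'
#' @param table a `sumstats` table with positions.
#' @param ld LD matrix covering (a subset of) the table's SNPs.
#' @param r2_threshold squared-correlation cutoff (default 0.001).
#' @param window_kb clumping window in kb (default 10000).
#' @return SNP ids in acceptance order.
#' @export
clump <- function(table, ld, r2_threshold = 0.001, window_kb = 10000) {
  if (nrow(table) == 0) return(character(0))
  ord <- order(table$p, table$chr, table$pos, table$snp)
  df <- table[ord, , drop = FALSE]
  in_ld <- df$snp %in% rownames(ld)
  kept <- integer(0)
  for (i in seq_len(nrow(df))) {
    conflict <- FALSE
    for (k in kept) {
      if (df$chr[i] != df$chr[k]) next
      if (abs(df$pos[i] - df$pos[k]) > window_kb * 1000) next
      r2 <- if (in_ld[i] && in_ld[k]) ld[df$snp[i], df$snp[k]]^2 else 0
      if (r2 > r2_threshold) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) kept <- c(kept, i)
  }
  out <- df$snp[kept]
  attr(out, "no_ld") <- df$snp[!in_ld]
  out
}

#' Cis-window region predicate
#'
#' Builds a predicate that is `TRUE` for SNPs on the gene's chromosome with
#' position in the closed interval `[start - flank_bp, end + flank_bp]`
#' (1-based coordinates).
#'
#' @param chrom,start,end gene coordinates, `start <= end`.
#' @param flank_bp non-negative flank in base pairs (default 1 Mb, the
#'   conventional cis-eQTL window).
#' @return function of `(chr, pos)` vectors returning a logical vector.
#' @export
cis_window <- function(chrom, start, end, flank_bp = 1e6) {
  if (flank_bp < 0) stop("flank_bp must be non-negative", call. = FALSE)
  if (start > end) stop("start must not exceed end", call. = FALSE)
  chrom <- as.character(chrom)
  lo <- start - flank_bp
  hi <- end + flank_bp
  function(chr, pos) as.character(chr) == chrom & pos >= lo & pos <= hi
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) unname(COMPLEMENT[a1] == a2)

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome's effects to the exposure's effect allele for each
#' requested SNP. Swapped alleles flip the outcome beta's sign and replace
#' eaf by 1 - eaf; alleles matching only after strand complementation
#' (A<->T, C<->G) are complemented first, then the swap rule applied.
#' Palindromic SNPs (A/T or C/G) are kept only when both traits' effect
#' allele frequencies fall outside `0.5 +/- palindrome_eaf_band` and on the
#' same side of 0.5; otherwise they are dropped as `palindromic-ambiguous`.
#' Irreconcilable alleles and SNPs absent from the outcome are dropped with
#' reasons.
#'
#' @param exposure,outcome `sumstats` tables.
#' @param snps SNP ids to harmonize (must be present in `exposure`);
#'   defaults to all exposure SNPs.
#' @param palindrome_eaf_band half-width of the ambiguity band around an
#'   eaf of 0.5 (default 0.08, i.e. drop when either eaf is in
#'   \[0.42, 0.58\]).
#' @return A `harmonized_set`: list with `exposure_id`, `outcome_id`,
#'   `instruments` (data frame `snp, beta_exposure, se_exposure,
#'   beta_outcome, se_outcome, eaf`) and `dropped` (`snp, reason`).
#' @export
harmonize <- function(exposure, outcome, snps = NULL, palindrome_eaf_band = 0.08) {
  stopifnot(palindrome_eaf_band >= 0, palindrome_eaf_band < 0.5)
  if (is.null(snps)) snps <- exposure$snp
  missing_exp <- setdiff(snps, exposure$snp)
  if (length(missing_exp) > 0) {
    stop("SNPs absent from exposure: ", paste(missing_exp, collapse = ", "),
      call. = FALSE
    )
  }
  ex <- exposure[match(snps, exposure$snp), , drop = FALSE]
  out_idx <- match(snps, outcome$snp)

  keep <- data.frame(
    snp = character(0), beta_exposure = numeric(0), se_exposure = numeric(0),
    beta_outcome = numeric(0), se_outcome = numeric(0), eaf = numeric(0)
  )
  dropped <- data.frame(snp = character(0), reason = character(0))
  drop <- function(s, why) {
    dropped[nrow(dropped) + 1L, ] <<- list(s, why)
  }

  for (i in seq_along(snps)) {
    s <- snps[i]
    j <- out_idx[i]
    if (is.na(j)) {
      drop(s, "absent-from-outcome")
      next
    }
    ea1 <- ex$a1[i]; ea2 <- ex$a2[i]
    oa1 <- outcome$a1[j]; oa2 <- outcome$a2[j]
    b_out <- outcome$beta[j]
    eaf_out <- outcome$eaf[j]

    pal <- is_palindromic(ea1, ea2)
    if (pal) {
      if (!((oa1 == ea1 && oa2 == ea2) || (oa1 == ea2 && oa2 == ea1))) {
        drop(s, "allele-mismatch")
        next
      }
      # align by label first (strand itself is unresolvable for A/T, C/G)
      if (oa1 == ea2) {
        b_out <- -b_out
        eaf_out <- 1 - eaf_out
      }
      band_lo <- 0.5 - palindrome_eaf_band
      band_hi <- 0.5 + palindrome_eaf_band
      ambiguous <-
        (ex$eaf[i] >= band_lo && ex$eaf[i] <= band_hi) ||
        (eaf_out >= band_lo && eaf_out <= band_hi) ||
        ((ex$eaf[i] < 0.5) != (eaf_out < 0.5))
      if (ambiguous) {
        drop(s, "palindromic-ambiguous")
        next
      }
    } else {
      if (oa1 == ea1 && oa2 == ea2) {
        # aligned
      } else if (oa1 == ea2 && oa2 == ea1) {
        b_out <- -b_out
        eaf_out <- 1 - eaf_out
      } else {
        c1 <- unname(COMPLEMENT[oa1]); c2 <- unname(COMPLEMENT[oa2])
        if (identical(c1, ea1) && identical(c2, ea2)) {
          # other strand, aligned
        } else if (identical(c1, ea2) && identical(c2, ea1)) {
          b_out <- -b_out
          eaf_out <- 1 - eaf_out
        } else {
          drop(s, "allele-mismatch")
          next
        }
      }
    }
    if (ex$se[i] <= 0 || outcome$se[j] <= 0) {
      drop(s, "nonpositive-se")
      next
    }
    keep[nrow(keep) + 1L, ] <- list(
      s, ex$beta[i], ex$se[i], b_out, outcome$se[j], ex$eaf[i]
    )
  }
  structure(
    list(
      exposure_id = attr(exposure, "trait_id"),
      outcome_id = attr(outcome, "trait_id"),
      instruments = keep, dropped = dropped
    ),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf(
    "<harmonized_set> %s -> %s: %d instruments, %d dropped\n",
    x$exposure_id, x$outcome_id, nrow(x$instruments), nrow(x$dropped)
  ))
  invisible(x)
}

#' Build a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor for simulation studies where exposure and
#' outcome effects are already expressed on a common effect allele.
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome numeric vectors.
#' @param snp SNP ids; defaults to `snp_1..snp_k`.
#' @param eaf effect-allele frequencies (optional).
#' @param exposure_id,outcome_id trait labels.
#' @return a `harmonized_set`.
#' @export
harmonized_set <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                           snp = NULL, eaf = NA_real_,
                           exposure_id = "exposure", outcome_id = "outcome") {
  k <- length(beta_exposure)
  stopifnot(
    length(se_exposure) == k, length(beta_outcome) == k,
    length(se_outcome) == k, all(se_exposure > 0), all(se_outcome > 0)
  )
  if (is.null(snp)) snp <- paste0("snp_", seq_len(k))
  structure(
    list(
      exposure_id = exposure_id, outcome_id = outcome_id,
      instruments = data.frame(
        snp = snp, beta_exposure = beta_exposure, se_exposure = se_exposure,
        beta_outcome = beta_outcome, se_outcome = se_outcome,
        eaf = rep_len(eaf, k)
      ),
      dropped = data.frame(snp = character(0), reason = character(0))
    ),
    class = "harmonized_set"
  )
}
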