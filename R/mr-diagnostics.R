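#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j * (b_j - b_ivw)^2)` over per-instrument Wald ratios `b_j`
#' with weights `w_j = beta_x_j^2 / se_y_j^2`, compared against the
#' fixed-effect IVW estimate; p-value from the chi-square distribution with
#' `k - 1` degrees of freedom.
#'
#' @param set a `harmonized_set` with at least 2 instruments.
#' @return list with `q`, `df`, `pval`.
#' @export
cochran_q <- function(set) {
  ins <- instruments_of(set)
  k <- nrow(ins)
  if (k < 2) stop("Cochran's Q requires at least 2 instruments", call. = FALSE)
  b <- ins$beta_outcome / ins$beta_exposure
  w <- ins$beta_exposure^2 / ins$se_outcome^2
  b_ivw <- sum(w * b) / sum(w)
  q <- sum(w * (b - b_ivw)^2)
  list(q = q, df = k - 1L, pval = pchisq(q, df = k - 1, lower.tail = FALSE))
}

#' MR-PRESSO global and outlier tests
#'
#' Global test: the observed weighted residual sum of squares, where each
#' instrument's outcome beta is predicted from the leave-one-out
#' fixed-effect IVW slope, is compared with its null distribution from
#' `n_sim` parametric simulations under the fitted IVW model
#' (outcome betas redrawn as normal around the leave-one-out predictions
#' with their reported SEs). `global_p = (1 + #[sim RSS >= obs]) /
#' (n_sim + 1)`. Outlier test: per-instrument simulated squared-residual
#' exceedance probabilities, Bonferroni-corrected at `outlier_alpha`.
#' The distortion test is not implemented.
#'
#' @param set a `harmonized_set` with at least 4 instruments.
#' @param n_sim parametric simulations (default 1000).
#' @param seed RNG seed.
#' @param outlier_alpha family-wise level for outlier flagging (default 0.05).
#' @return list with `global_p`, `outliers` (SNP ids), `outlier_p`
#'   (per-SNP Bonferroni-adjusted exceedance p-values), `rss_obs`.
#' @export
mr_presso <- function(set, n_sim = 1000, seed = 1, outlier_alpha = 0.05) {
  ins <- instruments_of(set)
  k <- nrow(ins)
  if (k < 4) stop("insufficient instruments for MR-PRESSO", call. = FALSE)
  w <- 1 / ins$se_outcome^2
  bx <- ins$beta_exposure
  by <- ins$beta_outcome

  loo_slope <- function(by_vec) {
    num <- sum(bx * by_vec * w)
    den <- sum(bx^2 * w)
    vapply(seq_len(k), function(j) {
      (num - bx[j] * by_vec[j] * w[j]) / (den - bx[j]^2 * w[j])
    }, numeric(1))
  }
  rss_of <- function(by_vec) {
    pred <- loo_slope(by_vec) * bx
    w * (by_vec - pred)^2
  }

  res_obs <- rss_of(by)
  rss_obs <- sum(res_obs)
  pred0 <- loo_slope(by) * bx

  withr_seed(seed, {
    exceed_global <- 0L
    exceed_snp <- numeric(k)
    for (s in seq_len(n_sim)) {
      by_sim <- rnorm(k, pred0, ins$se_outcome)
      res_sim <- rss_of(by_sim)
      if (sum(res_sim) >= rss_obs) exceed_global <- exceed_global + 1L
      exceed_snp <- exceed_snp + (res_sim >= res_obs)
    }
  })
  global_p <- (1 + exceed_global) / (n_sim + 1)
  p_snp <- pmin(1, k * (1 + exceed_snp) / (n_sim + 1)) # Bonferroni
  list(
    global_p = global_p,
    outliers = ins$snp[p_snp < outlier_alpha],
    outlier_p = setNames(p_snp, ins$snp),
    rss_obs = rss_obs
  )
}

#' Run the full two-sample MR estimator suite
#'
#' Applies IVW (the primary estimator), MR-Egger slope and intercept,
#' weighted median, simple and weighted mode, plus Cochran's Q and
#' MR-PRESSO, degrading gracefully when too few instruments are available
#' (a single instrument yields the Wald ratio only). Per-method failures
#' are reported, never propagated.
#'
#' @param set a `harmonized_set`.
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param n_presso MR-PRESSO simulations.
#' @param seed RNG seed shared by the stochastic members.
#' @param ivw_mode passed to [ivw()].
#' @return list with `estimates` (data frame: one row per method, `status`
#'   column `"ok"`/`"not computed"`), `heterogeneity` (Q and MR-PRESSO
#'   results or `NULL`), `direction_concordant` (`TRUE` iff all computed
#'   point estimates share the IVW sign).
#' @export
run_mr_suite <- function(set, n_boot = 1000, n_presso = 1000, seed = 1,
                         ivw_mode = "multiplicative_random") {
  ins <- instruments_of(set)
  k <- nrow(ins)
  if (k < 1) stop("no instruments", call. = FALSE)

  run <- function(fn) {
    tryCatch(fn(), error = function(e) conditionMessage(e))
  }
  fits <- list()
  if (k == 1) {
    fits$wald <- run(function() {
      wald_ratio(
        ins$beta_exposure, ins$se_exposure,
        ins$beta_outcome, ins$se_outcome
      )
    })
  }
  fits$ivw <- run(function() ivw(set, mode = ivw_mode))
  fits$egger <- run(function() mr_egger(set))
  fits$weighted_median <- run(function() weighted_median(set, n_boot, seed))
  fits$simple_mode <- run(function() mode_estimate(set, "simple", n_boot = n_boot, seed = seed))
  fits$weighted_mode <- run(function() mode_estimate(set, "weighted", n_boot = n_boot, seed = seed))

  rows <- list()
  add <- function(est, label) {
    if (inherits(est, "mr_estimate")) {
      d <- as.data.frame(est)
      d$status <- "ok"
    } else {
      d <- data.frame(
        method = label, nsnp = k, beta = NA_real_, se = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
        or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
        status = paste0("not computed (", est, ")")
      )
    }
    rows[[length(rows) + 1L]] <<- d
  }
  if (!is.null(fits$wald)) add(fits$wald, "wald")
  add(fits$ivw, "ivw")
  if (is.list(fits$egger) && !inherits(fits$egger, "mr_estimate")) {
    add(fits$egger$slope, "egger_slope")
    add(fits$egger$intercept, "egger_intercept")
  } else {
    add(fits$egger, "egger_slope")
  }
  add(fits$weighted_median, "weighted_median")
  add(fits$simple_mode, "simple_mode")
  add(fits$weighted_mode, "weighted_mode")
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL

  het <- NULL
  if (k >= 2) {
    het <- list(q = run(function() cochran_q(set)))
    if (k >= 4) {
      het$presso <- run(function() mr_presso(set, n_sim = n_presso, seed = seed))
    }
  }

  causal <- estimates[estimates$method %in%
    c("wald", "ivw", "egger_slope", "weighted_median", "simple_mode", "weighted_mode") &
    estimates$status == "ok", ]
  ivw_row <- estimates[estimates$method %in% c("ivw", "wald") & estimates$status == "ok", ]
  concordant <- nrow(ivw_row) > 0 &&
    all(sign(causal$beta) == sign(ivw_row$beta[1]))

  list(
    estimates = estimates, heterogeneity = het,
    direction_concordant = concordant
  )
}
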