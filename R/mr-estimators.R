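#' Causal-estimate container
#'
#' Every estimator returns an `mr_estimate`: method label, causal effect
#' `beta` on the outcome scale (log-odds for a binary outcome), its
#' standard error, 95% confidence bounds `beta -/+ 1.96 * se`, two-sided
#' p-value, and the instrument count. `as.data.frame()` adds odds-ratio
#' columns (exp of the beta-scale triple) for binary outcomes.
#'
#' @param method estimator label.
#' @param beta,se effect and standard error (`se > 0`).
#' @param pval two-sided p-value; computed from the normal distribution if
#'   omitted (or from Student's t when `df` is given).
#' @param n_snp number of instruments used.
#' @param df t-distribution degrees of freedom, or `NULL` for normal.
#' @return object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, pval = NULL, n_snp = 1L, df = NULL) {
  stopifnot(is.finite(beta), is.finite(se), se > 0)
  if (is.null(pval)) {
    pval <- if (is.null(df)) {
      2 * pnorm(-abs(beta / se))
    } else {
      2 * pt(-abs(beta / se), df = df)
    }
  }
  structure(
    list(
      method = method, beta = beta, se = se,
      ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
      pval = max(pval, .Machine$double.xmin), n_snp = as.integer(n_snp)
    ),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "%s: beta = %.4g (se %.4g, 95%% CI %.4g to %.4g), p = %.3g, nsnp = %d\n",
    x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snp
  ))
  invisible(x)
}

#' @rdname mr_estimate
#' @param x an `mr_estimate`.
#' @param or_scale add odds-ratio columns (`exp` of beta and CI bounds).
#' @param ... unused.
#' @export
as.data.frame.mr_estimate <- function(x, or_scale = TRUE, ...) {
  d <- data.frame(
    method = x$method, nsnp = x$n_snp, beta = x$beta, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval
  )
  if (or_scale) {
    d$or <- exp(x$beta)
    d$or_ci_low <- exp(x$ci_low)
    d$or_ci_high <- exp(x$ci_high)
  }
  d
}

instruments_of <- function(set) {
  if (inherits(set, "harmonized_set")) set$instruments else as.data.frame(set)
}

ratio_estimates <- function(ins) {
  list(
    b = ins$beta_outcome / ins$beta_exposure,
    # first-order delta method; exposure uncertainty ignored (NOME)
    se = abs(ins$se_outcome / ins$beta_exposure)
  )
}

#' Wald ratio for a single instrument
#'
#' `beta = beta_y / beta_x` with first-order delta-method standard error
#' `|se_y / beta_x|`; two-sided normal p-value.
#'
#' @param beta_x,se_x exposure association and its SE.
#' @param beta_y,se_y outcome association and its SE.
#' @return an [mr_estimate()] with method `"wald"`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (beta_x == 0) stop("null instrument", call. = FALSE)
  mr_estimate("wald", beta_y / beta_x, abs(se_y / beta_x), n_snp = 1L)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights `se_outcome^-2`:
#' `beta = sum(bx * by * w) / sum(bx^2 * w)`. The fixed-effect SE is
#' `sum(bx^2 * w)^-1/2`; the multiplicative random-effects model (the
#' default) inflates it by `max(1, sqrt(Q / (k - 1)))`.
#'
#' @param set a `harmonized_set` (or its instruments data frame).
#' @param mode `"multiplicative_random"` (default) or `"fixed"`.
#' @return an [mr_estimate()] with method `"ivw"`.
#' @export
ivw <- function(set, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  ins <- instruments_of(set)
  k <- nrow(ins)
  if (k < 1) stop("no instruments", call. = FALSE)
  w <- 1 / ins$se_outcome^2
  denom <- sum(ins$beta_exposure^2 * w)
  beta <- sum(ins$beta_exposure * ins$beta_outcome * w) / denom
  se <- sqrt(1 / denom)
  if (mode == "multiplicative_random" && k >= 2) {
    q <- sum(w * (ins$beta_outcome - beta * ins$beta_exposure)^2)
    se <- se * max(1, sqrt(q / (k - 1)))
  }
  mr_estimate("ivw", beta, se, n_snp = k)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas *with*
#' intercept, weights `se_outcome^-2`, after orienting all instruments to
#' non-negative exposure effects (the |beta_x| convention: pairs with
#' negative exposure beta have both betas negated). Standard errors use a
#' multiplicative overdispersion factor floored at 1; p-values use
#' Student's t with `k - 2` df. The intercept is the directional-pleiotropy
#' test.
#'
#' @param set a `harmonized_set`.
#' @return list with elements `slope` and `intercept`, both [mr_estimate()].
#' @export
mr_egger <- function(set) {
  ins <- instruments_of(set)
  k <- nrow(ins)
  if (k < 3) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  flip <- sign(ins$beta_exposure)
  flip[flip == 0] <- 1
  bx <- ins$beta_exposure * flip
  by <- ins$beta_outcome * flip
  w <- 1 / ins$se_outcome^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coef <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% coef
  sigma2 <- sum(w * resid^2) / (k - 2)
  vc <- solve(XtWX) * max(1, sigma2)
  list(
    intercept = mr_estimate("egger_intercept", coef[1], sqrt(vc[1, 1]),
      n_snp = k, df = k - 2
    ),
    slope = mr_estimate("egger_slope", coef[2], sqrt(vc[2, 2]),
      n_snp = k, df = k - 2
    )
  )
}

weighted_percentile <- function(x, w, prob = 0.5) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (prob <= cw[1]) return(x[1])
  if (prob >= cw[length(cw)]) return(x[length(x)])
  i <- findInterval(prob, cw)
  x[i] + (x[i + 1] - x[i]) * (prob - cw[i]) / (cw[i + 1] - cw[i])
}

boot_resample <- function(ins, stat_fn, n_boot, seed) {
  k <- nrow(ins)
  reps <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(r) {
      bx <- rnorm(k, ins$beta_exposure, ins$se_exposure)
      by <- rnorm(k, ins$beta_outcome, ins$se_outcome)
      stat_fn(bx, by, ins$se_outcome)
    }, numeric(1))
  })
  sd(reps)
}

# evaluate `code` under a temporary RNG seed, restoring the caller's stream
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Weighted-median estimator
#'
#' The weighted 50th percentile of the per-instrument Wald ratios with
#' inverse-variance weights (delta-method ratio variances), interpolating
#' linearly between bracketing order statistics. Consistent when
#' instruments carrying at least half the weight are valid. The SE comes
#' from a parametric bootstrap (exposure and outcome betas resampled from
#' normal distributions with their reported SEs).
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return an [mr_estimate()] with method `"weighted_median"`.
#' @export
weighted_median <- function(set, n_boot = 1000, seed = 1) {
  ins <- instruments_of(set)
  k <- nrow(ins)
  if (k < 3) stop("weighted median requires at least 3 instruments", call. = FALSE)
  stat <- function(bx, by, se_y) {
    b <- by / bx
    weighted_percentile(b, bx^2 / se_y^2)
  }
  beta <- stat(ins$beta_exposure, ins$beta_outcome, ins$se_outcome)
  se <- boot_resample(ins, stat, n_boot, seed)
  mr_estimate("weighted_median", beta, se, n_snp = k)
}

mode_stat <- function(b, w, bandwidth_factor) {
  s <- min(sd(b), IQR(b) / 1.349)
  h <- bandwidth_factor * 0.9 * s * length(b)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(b[1]) # all ratios identical
  d <- density(b,
    bw = h, weights = w / sum(w), n = 512,
    from = min(b) - 3 * h, to = max(b) + 3 * h
  )
  d$x[which.max(d$y)]
}

#' Mode-based estimators
#'
#' The argmax of a normal-kernel density over the per-instrument Wald
#' ratios — unweighted for the simple mode, inverse-variance-weighted for
#' the weighted mode. Bandwidth is
#' `bandwidth_factor * 0.9 * min(sd, IQR/1.349) * k^(-1/5)`; the density is
#' evaluated on a 512-point grid spanning the ratios plus/minus three
#' bandwidths. SE by parametric bootstrap.
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @param kind `"weighted"` (default) or `"simple"`.
#' @param bandwidth_factor kernel bandwidth multiplier (default 1).
#' @param n_boot,seed bootstrap controls.
#' @return an [mr_estimate()].
#' @export
mode_estimate <- function(set, kind = c("weighted", "simple"),
                          bandwidth_factor = 1, n_boot = 1000, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(bandwidth_factor > 0)
  ins <- instruments_of(set)
  k <- nrow(ins)
  if (k < 3) stop("mode estimators require at least 3 instruments", call. = FALSE)
  stat <- function(bx, by, se_y) {
    b <- by / bx
    w <- if (kind == "weighted") bx^2 / se_y^2 else rep(1, length(b))
    mode_stat(b, w, bandwidth_factor)
  }
  beta <- stat(ins$beta_exposure, ins$beta_outcome, ins$se_outcome)
  se <- boot_resample(ins, stat, n_boot, seed)
  mr_estimate(paste0(kind, "_mode"), beta, se, n_snp = k)
}
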