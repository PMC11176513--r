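# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards; with seed = NULL the global stream is used.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

new_mr_estimate <- function(method, nsnp, beta, se, pval,
                            intercept = NULL, intercept_se = NULL,
                            intercept_pval = NULL, q = NULL) {
  est <- list(method = method, nsnp = nsnp, beta = beta, se = se,
              pval = pval, or = exp(beta),
              ci_low = exp(beta - 1.96 * se),
              ci_high = exp(beta + 1.96 * se),
              intercept = intercept, intercept_se = intercept_se,
              intercept_pval = intercept_pval, q = q)
  structure(est, class = "mr_estimate")
}

# Placeholder for a method that cannot run on the given table
# (e.g. too few variants): reported as missing, never as an error.
na_mr_estimate <- function(method, nsnp) {
  structure(list(method = method, nsnp = nsnp, beta = NA_real_,
                 se = NA_real_, pval = NA_real_, or = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 intercept = NULL, intercept_se = NULL,
                 intercept_pval = NULL, q = NULL),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: nsnp=%d", x$method, x$nsnp))
  if (is.na(x$beta)) {
    cat(" (inapplicable)\n")
    return(invisible(x))
  }
  cat(sprintf(", beta=%.4g (se %.4g), OR=%.4g [%.4g, %.4g], p=%.3g\n",
              x$beta, x$se, x$or, x$ci_low, x$ci_high, x$pval))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept=%.4g (se %.4g), p=%.3g\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$nsnp, beta = x$beta, se = x$se,
             or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
             pval = x$pval,
             egger_intercept = x$intercept %||% NA_real_,
             egger_intercept_pval = x$intercept_pval %||% NA_real_,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

#' Per-variant Wald ratios
#'
#' The ratio estimate for each variant is the variant-outcome effect
#' divided by the variant-exposure effect; its standard error is the
#' first-order delta approximation `se_outcome / |beta_exposure|` (the
#' exposure-side uncertainty is ignored, the usual convention). Variants
#' with a zero exposure effect are dropped with a warning.
#'
#' @param h A [harmonize()]d table.
#' @return Data frame with `snp`, `ratio`, `se_ratio`.
#' @export
wald_ratios <- function(h) {
  stopifnot(inherits(h, "harmonized_table"))
  if (nrow(h) == 0) stop("no variants to compute ratios for", call. = FALSE)
  zero <- h$beta_exposure == 0
  if (any(zero)) {
    warning(sum(zero), " variant(s) with zero exposure effect dropped",
            call. = FALSE)
    h <- subset_harmonized(h, !zero)
  }
  if (nrow(h) == 0) stop("no variants with nonzero exposure effect", call. = FALSE)
  data.frame(snp = h$snp,
             ratio = h$beta_outcome / h$beta_exposure,
             se_ratio = h$se_outcome / abs(h$beta_exposure),
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted causal estimate
#'
#' Meta-analysis of the per-variant Wald ratios with weights
#' `1/se_ratio^2`; algebraically the weighted regression of the outcome
#' effects on the exposure effects through the origin with weights
#' `1/se_outcome^2`. The default multiplicative random-effects model
#' inflates the fixed-effect standard error by
#' `max(1, sqrt(Q/(J-1)))`, where Q is Cochran's heterogeneity statistic.
#'
#' @param h A [harmonize()]d table with at least one variant.
#' @param model `"random_multiplicative"` (default) or `"fixed"`.
#' @return An `mr_estimate` (method `"ivw"`); with a single variant the
#'   estimate is that variant's Wald ratio.
#' @export
mr_ivw <- function(h, model = c("random_multiplicative", "fixed")) {
  model <- match.arg(model)
  wr <- wald_ratios(h)
  j <- nrow(wr)
  w <- 1 / wr$se_ratio^2
  beta <- sum(w * wr$ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (wr$ratio - beta)^2)
  if (model == "random_multiplicative" && j >= 2) {
    se <- se * max(1, sqrt(q / (j - 1)))
  }
  new_mr_estimate("ivw", j, beta, se, two_sided_p(beta / se), q = q)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects with an intercept (weights `1/se_outcome^2`), after orienting
#' every exposure effect positive. The slope is the causal estimate; a
#' nonzero intercept indicates directional horizontal pleiotropy.
#' Standard errors carry a multiplicative overdispersion factor
#' `max(1, residual scale)`.
#'
#' @param h A [harmonize()]d table.
#' @param p_dist `"normal"` (default, consistent with the other
#'   estimators) or `"t"` with J-2 degrees of freedom.
#' @return An `mr_estimate` (method `"egger"`) carrying `intercept`,
#'   `intercept_se`, `intercept_pval`; missing when fewer than 3 variants.
#' @export
mr_egger <- function(h, p_dist = c("normal", "t")) {
  p_dist <- match.arg(p_dist)
  stopifnot(inherits(h, "harmonized_table"))
  h <- subset_harmonized(h, h$beta_exposure != 0)
  j <- nrow(h)
  if (j < 3) return(na_mr_estimate("egger", j))
  flip <- sign(h$beta_exposure)
  x <- h$beta_exposure * flip
  y <- h$beta_outcome * flip
  w <- 1 / h$se_outcome^2
  fit <- weighted_line_fit(x, y, w)
  infl <- max(1, fit$sigma)
  se_slope <- fit$se_slope_unit * infl
  se_inter <- fit$se_inter_unit * infl
  pv <- function(est, se) {
    if (p_dist == "normal") two_sided_p(est / se)
    else 2 * stats::pt(-abs(est / se), df = j - 2)
  }
  new_mr_estimate("egger", j, fit$slope, se_slope, pv(fit$slope, se_slope),
                  intercept = fit$inter, intercept_se = se_inter,
                  intercept_pval = pv(fit$inter, se_inter))
}

# Weighted straight-line fit by the normal equations; returns the slope,
# intercept, their unit-dispersion standard errors and the residual scale
# sqrt(RSS_w/(J-2)).
weighted_line_fit <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  d <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / d
  inter <- (swy * swxx - swx * swxy) / d
  res <- y - inter - slope * x
  j <- length(x)
  sigma <- if (j > 2) sqrt(sum(w * res^2) / (j - 2)) else NA_real_
  list(slope = slope, inter = inter,
       se_slope_unit = sqrt(sw / d),
       se_inter_unit = sqrt(swxx / d),
       sigma = sigma)
}

# Weighted median of `values` under weights `w`: linear interpolation of
# the weighted empirical CDF evaluated at cumulative-weight midpoints.
weighted_median_est <- function(values, w) {
  ord <- order(values)
  v <- values[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  stats::approx(p, v, xout = 0.5, rule = 2, ties = "ordered")$y
}

# One parametric-bootstrap standard error for a ratio-based estimator:
# resample per-variant exposure and outcome effects from normals centred
# at the observed values, recompute the estimate, take the SD.
bootstrap_se <- function(h, estimator, n_boot, seed) {
  with_seed(seed, {
    j <- nrow(h)
    ests <- vapply(seq_len(n_boot), function(b) {
      g <- stats::rnorm(j, h$beta_exposure, h$se_exposure)
      G <- stats::rnorm(j, h$beta_outcome, h$se_outcome)
      ok <- g != 0
      estimator(G[ok] / g[ok], h$se_outcome[ok] / abs(g[ok]))
    }, numeric(1))
    stats::sd(ests)
  })
}

#' Weighted-median causal estimate
#'
#' The weighted median of the Wald ratios (inverse-variance weights),
#' consistent when at least half the total weight comes from valid
#' instruments. The standard error is a seeded parametric bootstrap.
#'
#' @param h A [harmonize()]d table.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap; given the seed the result is
#'   reproducible.
#' @return An `mr_estimate` (method `"weighted_median"`); missing when
#'   fewer than 3 variants.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(h, "harmonized_table"))
  h <- subset_harmonized(h, h$beta_exposure != 0)
  if (nrow(h) < 3) return(na_mr_estimate("weighted_median", nrow(h)))
  wr <- wald_ratios(h)
  beta <- weighted_median_est(wr$ratio, 1 / wr$se_ratio^2)
  se <- bootstrap_se(h, function(r, s) weighted_median_est(r, 1 / s^2),
                     n_boot, seed)
  new_mr_estimate("weighted_median", nrow(h), beta, se,
                  two_sided_p(beta / se))
}

# Kernel-density mode of the ratios: normal kernel, bandwidth from the
# modified Silverman rule s = 0.9 min(sd, mad) J^{-1/5} scaled by phi.
mode_est <- function(values, w, bandwidth_factor) {
  if (max(values) - min(values) < .Machine$double.eps^0.5) {
    return(values[1])
  }
  s <- 0.9 * min(stats::sd(values), stats::mad(values)) /
    length(values)^(1 / 5)
  bw <- max(1e-8, s * bandwidth_factor)
  d <- stats::density(values, weights = w / sum(w), bw = bw, n = 2048)
  d$x[which.max(d$y)]
}

#' Mode-based causal estimates
#'
#' The mode of the smoothed Wald-ratio distribution: the largest group of
#' variants with consistent ratios drives the estimate, so a minority of
#' pleiotropic variants is tolerated. `mr_weighted_mode()` weights each
#' ratio by its inverse variance, `mr_simple_mode()` weights equally.
#' Bandwidth is the modified Silverman rule scaled by
#' `bandwidth_factor`; the standard error is a seeded parametric
#' bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the Silverman bandwidth
#'   (default 1).
#' @return An `mr_estimate`; missing when fewer than 3 variants.
#' @export
mr_weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000,
                             seed = NULL) {
  mode_mr(h, "weighted_mode", bandwidth_factor, n_boot, seed,
          weighted = TRUE)
}

#' @rdname mr_weighted_mode
#' @export
mr_simple_mode <- function(h, bandwidth_factor = 1, n_boot = 1000,
                           seed = NULL) {
  mode_mr(h, "simple_mode", bandwidth_factor, n_boot, seed,
          weighted = FALSE)
}

mode_mr <- function(h, method, bandwidth_factor, n_boot, seed, weighted) {
  stopifnot(inherits(h, "harmonized_table"))
  h <- subset_harmonized(h, h$beta_exposure != 0)
  if (nrow(h) < 3) return(na_mr_estimate(method, nrow(h)))
  wr <- wald_ratios(h)
  wfun <- function(s) if (weighted) 1 / s^2 else rep(1, length(s))
  beta <- mode_est(wr$ratio, wfun(wr$se_ratio), bandwidth_factor)
  se <- bootstrap_se(h, function(r, s) mode_est(r, wfun(s), bandwidth_factor),
                     n_boot, seed)
  new_mr_estimate(method, nrow(h), beta, se, two_sided_p(beta / se))
}

#' Run all five causal-effect estimators
#'
#' IVW (the primary method), MR-Egger, weighted median, weighted mode and
#' simple mode on one harmonized exposure-outcome table. Methods below
#' their minimum variant count (1 for IVW, 3 for the rest) are reported
#' with missing estimates rather than raising an error.
#'
#' @inheritParams mr_weighted_median
#' @param ivw_model Passed to [mr_ivw()].
#' @return A list of `mr_estimate` objects named by method, with the
#'   `"primary"` attribute set to `"ivw"`. Use `as.data.frame()` /
#'   [screen_table()] on the enclosing screen for a flat view.
#' @export
mr_all <- function(h, n_boot = 1000, seed = NULL,
                   ivw_model = "random_multiplicative") {
  stopifnot(inherits(h, "harmonized_table"))
  ests <- list(
    ivw = mr_ivw(h, model = ivw_model),
    egger = mr_egger(h),
    weighted_median = mr_weighted_median(h, n_boot = n_boot, seed = seed),
    weighted_mode = mr_weighted_mode(h, n_boot = n_boot, seed = seed),
    simple_mode = mr_simple_mode(h, n_boot = n_boot, seed = seed)
  )
  structure(ests, primary = "ivw", class = "mr_estimate_list")
}

#' @export
print.mr_estimate_list <- function(x, ...) {
  for (e in x) print(e)
  invisible(x)
}

#' @export
as.data.frame.mr_estimate_list <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), as.data.frame))
}
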