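#' Cochran's Q heterogeneity test
#'
#' Q is the inverse-variance-weighted sum of squared deviations of the
#' per-variant Wald ratios from the fixed-effect IVW estimate; under
#' homogeneity it is chi-square with J-1 degrees of freedom. Large Q
#' signals heterogeneous instruments, often a symptom of pleiotropy.
#'
#' @param h A [harmonize()]d table with at least 2 usable variants.
#' @return A list of class `heterogeneity_result` with `q`, `df`, `pval`
#'   (all `NA` with a warning below 2 variants).
#' @export
cochran_q <- function(h) {
  stopifnot(inherits(h, "harmonized_table"))
  h <- subset_harmonized(h, h$beta_exposure != 0)
  j <- nrow(h)
  if (j < 2) {
    warning("Cochran's Q needs at least 2 variants", call. = FALSE)
    return(structure(list(q = NA_real_, df = NA_integer_, pval = NA_real_),
                     class = "heterogeneity_result"))
  }
  wr <- wald_ratios(h)
  w <- 1 / wr$se_ratio^2
  pooled <- sum(w * wr$ratio) / sum(w)
  q <- sum(w * (wr$ratio - pooled)^2)
  structure(list(q = q, df = j - 1L,
                 pval = stats::pchisq(q, df = j - 1, lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g\n", x$q, x$df, x$pval))
  invisible(x)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' @param h A [harmonize()]d table with at least 3 usable variants.
#' @return A list with `intercept`, `se`, `pval` (all `NA` below 3
#'   variants).
#' @export
egger_intercept_test <- function(h) {
  fit <- mr_egger(h)
  if (is.na(fit$beta)) {
    return(list(intercept = NA_real_, se = NA_real_, pval = NA_real_))
  }
  list(intercept = fit$intercept, se = fit$intercept_se,
       pval = fit$intercept_pval)
}

#' MR-PRESSO-style global, outlier and distortion tests
#'
#' Residual-sum-of-squares test for horizontal pleiotropy. The observed
#' statistic sums, over variants, the weighted squared leave-one-out
#' residual: each variant's outcome effect minus its prediction from the
#' fixed-effect IVW slope fitted without that variant (weights
#' `1/se_outcome^2`). The null distribution is simulated by redrawing
#' every outcome effect from `Normal(beta_exposure * slope_loo,
#' se_outcome)` and recomputing the statistic, giving
#' `global_pval = (1 + #[RSS* >= RSS_obs]) / (n_sim + 1)` (never exactly
#' zero). Per-variant outliers are flagged when the observed squared
#' residual is extreme against its simulated distribution at a
#' Bonferroni-adjusted `outlier_alpha`. When outliers are found, the
#' distortion test compares the change in the IVW estimate after removing
#' them with the change after removing random variant subsets of the same
#' size.
#'
#' @param h A [harmonize()]d table with at least 4 usable variants.
#' @param n_sim Simulated null datasets (default 1000; below 100 a
#'   warning is given).
#' @param outlier_alpha Familywise level for the outlier test
#'   (default 0.05, Bonferroni over variants).
#' @param seed Seed; results are reproducible given the seed.
#' @return A list of class `presso_result`: `rss_obs`, `global_pval`,
#'   `n_sim`, `outliers` (data frame of flagged variants and p-values),
#'   `distortion_pval`, `beta_raw`, `beta_corrected`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = NULL) {
  stopifnot(inherits(h, "harmonized_table"))
  h <- subset_harmonized(h, h$beta_exposure != 0)
  j <- nrow(h)
  if (j < 4) {
    warning("MR-PRESSO needs at least 4 variants", call. = FALSE)
    return(structure(list(rss_obs = NA_real_, global_pval = NA_real_,
                          n_sim = n_sim, outliers = NULL,
                          distortion_pval = NA_real_,
                          beta_raw = NA_real_, beta_corrected = NA_real_,
                          seed = seed),
                     class = "presso_result"))
  }
  if (n_sim < 100) warning("n_sim < 100 gives a coarse p-value", call. = FALSE)

  g <- h$beta_exposure
  G <- h$beta_outcome
  w <- 1 / h$se_outcome^2
  s1 <- sum(w * g * G)
  s2 <- sum(w * g^2)
  # fixed-effect IVW slope with variant j held out, for every j at once
  beta_loo <- (s1 - w * g * G) / (s2 - w * g^2)
  res_obs <- w * (G - g * beta_loo)^2
  rss_obs <- sum(res_obs)

  sims <- with_seed(seed, {
    Gs <- matrix(stats::rnorm(j * n_sim, mean = g * beta_loo,
                              sd = h$se_outcome),
                 nrow = j, ncol = n_sim)
    s1s <- colSums(w * g * Gs)
    beta_loo_s <- (rep(s1s, each = j) - w * g * Gs) / (s2 - w * g^2)
    w * (Gs - g * beta_loo_s)^2
  })
  rss_sim <- colSums(sims)
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  outlier_p <- (1 + rowSums(sims >= res_obs)) / (n_sim + 1)
  flagged <- outlier_p < outlier_alpha / j
  outliers <- data.frame(snp = h$snp[flagged], pval = outlier_p[flagged],
                         stringsAsFactors = FALSE)

  beta_raw <- mr_ivw(h)$beta
  beta_corrected <- NA_real_
  distortion_pval <- NA_real_
  if (any(flagged) && sum(!flagged) >= 1) {
    beta_corrected <- mr_ivw(subset_harmonized(h, !flagged))$beta
    d_obs <- beta_corrected - beta_raw
    k <- sum(flagged)
    d_rand <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
      vapply(seq_len(n_sim), function(b) {
        drop_idx <- sample.int(j, k)
        mr_ivw(subset_harmonized(h, -drop_idx))$beta - beta_raw
      }, numeric(1))
    })
    distortion_pval <- (1 + sum(abs(d_rand) >= abs(d_obs))) / (n_sim + 1)
  }
  structure(list(rss_obs = rss_obs, global_pval = global_pval,
                 n_sim = n_sim, outliers = outliers,
                 distortion_pval = distortion_pval,
                 beta_raw = beta_raw, beta_corrected = beta_corrected,
                 seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.4g (%d sims)\n",
              x$rss_obs, x$global_pval, x$n_sim))
  if (!is.null(x$outliers) && nrow(x$outliers) > 0) {
    cat("  outliers:", paste(x$outliers$snp, collapse = ", "), "\n")
    cat(sprintf("  beta raw %.4g -> corrected %.4g (distortion p = %.3g)\n",
                x$beta_raw, x$beta_corrected, x$distortion_pval))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}

#' Leave-one-out sensitivity series
#'
#' Refits the IVW estimator (same model variant as the headline fit) with
#' each variant excluded in turn; a result driven by a single variant
#' shows up as a large shift in its row.
#'
#' @param h A [harmonize()]d table with at least 2 usable variants.
#' @param model IVW model passed to [mr_ivw()].
#' @return Data frame with one row per excluded variant: `snp`, `beta`,
#'   `se`, `pval`.
#' @export
leave_one_out <- function(h, model = "random_multiplicative") {
  stopifnot(inherits(h, "harmonized_table"))
  h <- subset_harmonized(h, h$beta_exposure != 0)
  j <- nrow(h)
  if (j < 2) stop("leave-one-out needs at least 2 variants", call. = FALSE)
  rows <- lapply(seq_len(j), function(i) {
    fit <- mr_ivw(subset_harmonized(h, -i), model = model)
    data.frame(snp = h$snp[i], beta = fit$beta, se = fit$se,
               pval = fit$pval, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full diagnostics bundle for one exposure-outcome pair
#'
#' @param h A [harmonize()]d table.
#' @param presso_n_sim Simulations for [mr_presso()]; 0 skips the test.
#' @param seed Seed forwarded to [mr_presso()].
#' @param qc_alpha Level for the QC flag: the pair passes when the
#'   heterogeneity and pleiotropy p-values both exceed this (tests that
#'   could not run do not fail QC).
#' @return A list of class `mr_diagnostics` with elements `q`
#'   (heterogeneity), `egger_intercept`, `presso`, `loo`, and `qc_pass`.
#' @export
mr_diagnostics <- function(h, presso_n_sim = 1000, seed = NULL,
                           qc_alpha = 0.05) {
  usable <- sum(h$beta_exposure != 0)
  q <- if (usable >= 2) cochran_q(h) else {
    structure(list(q = NA_real_, df = NA_integer_, pval = NA_real_),
              class = "heterogeneity_result")
  }
  eg <- egger_intercept_test(h)
  pr <- if (presso_n_sim > 0 && usable >= 4) {
    mr_presso(h, n_sim = presso_n_sim, seed = seed)
  } else NULL
  loo <- if (usable >= 2) leave_one_out(h) else NULL
  pvals <- c(q$pval, eg$pval, if (!is.null(pr)) pr$global_pval)
  qc_pass <- all(pvals > qc_alpha, na.rm = TRUE)
  structure(list(q = q, egger_intercept = eg, presso = pr, loo = loo,
                 qc_pass = qc_pass),
            class = "mr_diagnostics")
}
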