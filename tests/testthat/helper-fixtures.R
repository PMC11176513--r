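# Shared fixtures and independent oracles for the test suite.

# Build a sumstat_table from vectors, defaulting to a non-palindromic A/G
# coding so harmonization is the identity.
make_sumstats <- function(beta, se, pval = NULL, snp = NULL, eaf = 0.3,
                          n = 10000, ea = "A", oa = "G",
                          label = "trait", type = "quantitative") {
  j <- length(beta)
  if (is.null(snp)) snp <- sprintf("rs%03d", seq_len(j))
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)),
                                  .Machine$double.xmin)
  sumstat_table(
    data.frame(snp = snp, effect_allele = ea, other_allele = oa,
               eaf = eaf, beta = beta, se = se, pval = pval, n = n,
               stringsAsFactors = FALSE),
    trait_label = label, trait_type = type)
}

# Build a harmonized exposure-outcome table directly from effect vectors.
make_harmonized <- function(gamma, Gamma, se_gamma = rep(0.01, length(gamma)),
                            se_Gamma = rep(0.01, length(gamma)),
                            snp = sprintf("rs%03d", seq_along(gamma))) {
  h <- data.frame(
    snp = snp, effect_allele = "A", other_allele = "G",
    beta_exposure = gamma, se_exposure = se_gamma, eaf_exposure = 0.3,
    pval_exposure = 2 * pnorm(-abs(gamma / se_gamma)),
    beta_outcome = Gamma, se_outcome = se_Gamma, eaf_outcome = 0.3,
    pval_outcome = 2 * pnorm(-abs(Gamma / se_Gamma)),
    action = "unchanged", stringsAsFactors = FALSE)
  structure(h, exposure_label = "exposure", outcome_label = "outcome",
            dropped = h[0, c("snp", "action")],
            class = c("harmonized_table", "data.frame"))
}

# Random harmonized instance for property tests.
random_harmonized <- function(j, theta = 0.3) {
  gamma <- rnorm(j, 0, 0.2)
  gamma[abs(gamma) < 0.02] <- 0.05
  se_G <- runif(j, 0.005, 0.05)
  make_harmonized(gamma, theta * gamma + rnorm(j, 0, se_G),
                  se_gamma = runif(j, 0.005, 0.02), se_Gamma = se_G)
}

# Independent oracle: weighted regression through the origin via lm().
ivw_oracle <- function(h) {
  unname(coef(lm(beta_outcome ~ 0 + beta_exposure, data = h,
                 weights = 1 / h$se_outcome^2)))
}

# Independent oracle: weighted straight line via lm(), after orienting
# exposure effects positive.
egger_oracle <- function(h) {
  s <- sign(h$beta_exposure)
  fit <- lm(I(h$beta_outcome * s) ~ I(h$beta_exposure * s),
            weights = 1 / h$se_outcome^2)
  unname(coef(fit))  # c(intercept, slope)
}

# Independent oracle: weighted median by stepping through the weighted
# empirical CDF (no approx()).
weighted_median_oracle <- function(values, w) {
  ord <- order(values)
  v <- values[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(v[1])
  if (0.5 >= p[length(p)]) return(v[length(v)])
  i <- max(which(p < 0.5))
  v[i] + (v[i + 1] - v[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
}

# Exhaustive greedy clumping oracle: explicit pairwise conflict matrix.
clump_oracle <- function(candidates, ld, criteria) {
  snps <- candidates$snp
  j <- length(snps)
  conflict <- matrix(FALSE, j, j)
  pos <- ld$positions
  for (a in seq_len(j)) {
    for (b in seq_len(j)) {
      if (a == b) next
      r2 <- ld$r2[snps[a], snps[b]]
      inside <- TRUE
      if (!is.null(pos)) {
        ia <- match(snps[a], pos$snp); ib <- match(snps[b], pos$snp)
        inside <- pos$chr[ia] == pos$chr[ib] &&
          abs(pos$pos[ia] - pos$pos[ib]) <= criteria$clump_window_kb * 1000
      }
      conflict[a, b] <- r2 >= criteria$clump_r2 && inside
    }
  }
  ord <- order(candidates$pval, candidates$snp)
  kept <- integer(0)
  for (i in ord) {
    if (!any(conflict[i, kept])) kept <- c(kept, i)
  }
  sort(snps[sort(kept)])
}

# Mediation panel over 5 disjoint 20-SNP blocks: block 1 instruments the
# exposure, block 2 the active mediator, blocks 3-5 three null mediators.
# The exposure acts on the outcome directly (theta_direct) and through
# the active mediator (theta_xm * theta_my); the exposure-to-mediator
# signal (theta_xm * gamma) is kept below the mediator's selection
# threshold so step-2 instruments are the mediator's own.
make_mediation_panel <- function(theta_direct = 0.25, theta_xm = 0.3,
                                 theta_my = 0.5, seed = 77) {
  withr::with_seed(seed, {
    block <- 20
    total <- 5 * block
    snp <- sprintf("rs%04d", seq_len(total))
    se_x <- 0.005; se_m <- 0.025; se_y <- 0.004
    blk <- function(k) (k - 1) * block + seq_len(block)
    gma <- function() sample(c(-1, 1), block, TRUE) * runif(block, 0.1, 0.3)

    g <- rep(0, total); g[blk(1)] <- gma()
    gm_own <- rep(0, total); gm_own[blk(2)] <- gma()
    exposure <- make_sumstats(g + rnorm(total, 0, se_x), rep(se_x, total),
                              snp = snp, label = "exposure")
    active <- make_sumstats(theta_xm * g + gm_own + rnorm(total, 0, se_m),
                            rep(se_m, total), snp = snp, label = "active_mediator")
    nulls <- lapply(1:3, function(k) {
      own <- rep(0, total); own[blk(2 + k)] <- gma()
      make_sumstats(own + rnorm(total, 0, se_m), rep(se_m, total),
                    snp = snp, label = paste0("null_mediator_", k))
    })
    theta_total <- theta_direct + theta_xm * theta_my
    outcome <- make_sumstats(
      theta_total * g + theta_my * gm_own + rnorm(total, 0, se_y),
      rep(se_y, total), snp = snp, label = "outcome", type = "binary")
    list(exposure = exposure, active = active, nulls = nulls,
         outcome = outcome,
         truth = list(theta_direct = theta_direct, theta_xm = theta_xm,
                      theta_my = theta_my, theta_total = theta_total))
  })
}

# Five-exposure panel over one shared SNP set: exposures 1 and 2 drive
# the outcome (log-odds effects theta1/theta2), 3-5 are true nulls with
# their own strong instruments. Each exposure's instruments live on a
# disjoint 20-SNP block.
make_screen_panel <- function(theta1 = 0.4, theta2 = -0.5, seed = 42,
                              block = 20, n_exposures = 5) {
  withr::with_seed(seed, {
    total <- block * n_exposures
    snp <- sprintf("rs%04d", seq_len(total))
    se_x <- 0.01
    se_y <- 0.004
    gammas <- matrix(0, total, n_exposures)
    exposures <- vector("list", n_exposures)
    for (k in seq_len(n_exposures)) {
      idx <- (k - 1) * block + seq_len(block)
      g <- rep(0, total)
      g[idx] <- rnorm(block, 0, 0.15)
      g[idx][abs(g[idx]) < 0.08] <- 0.1
      gammas[, k] <- g
      exposures[[k]] <- make_sumstats(
        beta = g + rnorm(total, 0, se_x), se = rep(se_x, total),
        snp = snp, label = paste0("exposure_", k))
    }
    G <- theta1 * gammas[, 1] + theta2 * gammas[, 2] +
      rnorm(total, 0, se_y)
    outcome <- make_sumstats(G, rep(se_y, total), snp = snp,
                             label = "outcome", type = "binary")
    list(exposures = exposures, outcome = outcome)
  })
}
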