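test_that("Wald ratios: arithmetic, null, symmetry, zero-gamma handling", {
  h <- make_harmonized(gamma = 0.1, Gamma = 0.05, se_Gamma = 0.01)
  wr <- wald_ratios(h)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$se_ratio, 0.1)
  expect_equal(wald_ratios(make_harmonized(0.1, 0))$ratio, 0)
  # flipping the exposure sign negates the ratio, SE unchanged
  h2 <- make_harmonized(c(0.1, -0.1), c(0.05, 0.05), se_Gamma = c(0.01, 0.01))
  wr2 <- wald_ratios(h2)
  expect_equal(wr2$ratio, c(0.5, -0.5))
  expect_equal(wr2$se_ratio, c(0.1, 0.1))
  h3 <- make_harmonized(c(0.1, 0), c(0.05, 0.02))
  expect_warning(wr3 <- wald_ratios(h3), "zero exposure effect")
  expect_equal(nrow(wr3), 1)
})

test_that("IVW reduces to the Wald ratio for one variant and pools exactly", {
  one <- mr_ivw(make_harmonized(0.1, 0.05, se_Gamma = 0.01))
  expect_equal(one$beta, 0.5)
  expect_equal(one$se, 0.1)
  # homogeneous ratios: beta = r, Q = 0, fixed = random SE
  hom <- make_harmonized(c(0.1, 0.2, 0.4), 0.3 * c(0.1, 0.2, 0.4),
                         se_Gamma = c(0.01, 0.02, 0.01))
  expect_equal(mr_ivw(hom)$beta, 0.3)
  expect_equal(mr_ivw(hom)$q, 0)
  expect_equal(mr_ivw(hom)$se, mr_ivw(hom, model = "fixed")$se)
  # hand-solved normal equations: beta = 220/725
  h <- make_harmonized(c(0.1, 0.2, 0.3), c(0.03, 0.05, 0.12),
                       se_Gamma = c(0.01, 0.01, 0.02))
  expect_equal(mr_ivw(h)$beta, 220 / 725, tolerance = 1e-12)
})

test_that("IVW matches the weighted-least-squares-through-origin oracle", {
  withr::with_seed(6, {
    for (i in 1:100) {
      h <- random_harmonized(sample(2:10, 1))
      expect_equal(mr_ivw(h, model = "fixed")$beta, ivw_oracle(h),
                   tolerance = 1e-10)
    }
  })
})

test_that("IVW agrees with an independent fixed-effect meta-analysis", {
  skip_if_not_installed("metafor")
  withr::with_seed(7, {
    h <- random_harmonized(8)
    wr <- wald_ratios(h)
    fit <- metafor::rma(yi = wr$ratio, sei = wr$se_ratio, method = "FE")
    est <- mr_ivw(h, model = "fixed")
    expect_equal(est$beta, as.numeric(fit$beta), tolerance = 1e-10)
    expect_equal(est$se, as.numeric(fit$se), tolerance = 1e-10)
    expect_equal(cochran_q(h)$q, as.numeric(fit$QE), tolerance = 1e-10)
  })
})

test_that("Egger recovers exact linear structure", {
  g <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_harmonized(g, 0.03 + 0.2 * g, se_Gamma = rep(0.01, 4))
  fit <- mr_egger(h)
  expect_equal(fit$intercept, 0.03, tolerance = 1e-12)
  expect_equal(fit$beta, 0.2, tolerance = 1e-12)
  # proportional points: intercept 0, slope = ratio = IVW beta
  h2 <- make_harmonized(g, 0.25 * g, se_Gamma = rep(0.01, 4))
  fit2 <- mr_egger(h2)
  expect_equal(fit2$intercept, 0, tolerance = 1e-12)
  expect_equal(fit2$beta, 0.25, tolerance = 1e-12)
  expect_equal(fit2$beta, mr_ivw(h2)$beta, tolerance = 1e-12)
})

test_that("Egger matches the weighted normal-equations oracle on random instances", {
  withr::with_seed(8, {
    for (i in 1:100) {
      h <- random_harmonized(sample(4:10, 1))
      fit <- mr_egger(h)
      oracle <- egger_oracle(h)
      expect_equal(fit$intercept, oracle[1], tolerance = 1e-10)
      expect_equal(fit$beta, oracle[2], tolerance = 1e-10)
    }
  })
})

test_that("Egger is inapplicable below 3 variants, reported as missing", {
  fit <- mr_egger(make_harmonized(c(0.1, 0.2), c(0.05, 0.1)))
  expect_true(is.na(fit$beta))
  expect_equal(fit$nsnp, 2)
})

test_that("weighted median interpolates the weighted CDF", {
  # equal weights: the ordinary median
  h <- make_harmonized(c(0.1, 0.1, 0.1), c(0.01, 0.02, 0.03),
                       se_Gamma = rep(0.01, 3))
  est <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.2)
  # hand-worked interpolation: ratios (.1,.2,.3), weights (.2,.3,.5) -> 0.2375
  expect_equal(weighted_median_oracle(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.5)),
               0.2375)
  se_G <- 0.1 * sqrt(1 / c(0.2, 0.3, 0.5))
  h2 <- make_harmonized(rep(0.1, 3), 0.1 * c(0.1, 0.2, 0.3), se_Gamma = se_G)
  est2 <- mr_weighted_median(h2, n_boot = 50, seed = 1)
  expect_equal(est2$beta, 0.2375, tolerance = 1e-12)
})

test_that("weighted median matches the brute-force CDF oracle on random instances", {
  withr::with_seed(9, {
    for (i in 1:100) {
      h <- random_harmonized(sample(3:10, 1))
      wr <- wald_ratios(h)
      expect_equal(mr_weighted_median(h, n_boot = 2, seed = 1)$beta,
                   weighted_median_oracle(wr$ratio, 1 / wr$se_ratio^2),
                   tolerance = 1e-12)
    }
  })
})

test_that("weighted median is deterministic given a seed and degenerate on equal ratios", {
  h <- make_harmonized(c(0.1, 0.2, 0.3), 0.4 * c(0.1, 0.2, 0.3),
                       se_Gamma = c(0.01, 0.02, 0.015),
                       se_gamma = rep(1e-6, 3))
  a <- mr_weighted_median(h, n_boot = 200, seed = 42)
  b <- mr_weighted_median(h, n_boot = 200, seed = 42)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
  expect_equal(a$beta, 0.4, tolerance = 1e-12)
  # near-noiseless resamples give a small bootstrap SE
  h0 <- make_harmonized(c(0.1, 0.2, 0.3), 0.4 * c(0.1, 0.2, 0.3),
                        se_Gamma = rep(1e-6, 3), se_gamma = rep(1e-6, 3))
  expect_lt(mr_weighted_median(h0, n_boot = 100, seed = 1)$se, 1e-4)
})

test_that("mode estimators find the majority cluster", {
  withr::with_seed(10, {
    g <- runif(12, 0.1, 0.3)
    G <- 0.3 * g
    G[12] <- 2 * g[12]   # one distant outlier
    h <- make_harmonized(g, G, se_Gamma = rep(0.01, 12))
    wm <- mr_weighted_mode(h, n_boot = 50, seed = 1)
    expect_equal(wm$beta, 0.3, tolerance = 0.02)
    # identical ratios: exactly r
    hr <- make_harmonized(g, 0.25 * g, se_Gamma = rep(0.01, 12))
    expect_equal(mr_weighted_mode(hr, n_boot = 10, seed = 1)$beta, 0.25)
    expect_equal(mr_simple_mode(hr, n_boot = 10, seed = 1)$beta, 0.25)
  })
})

test_that("weighted and simple modes separate on weight-skewed bimodal ratios", {
  # cluster A (3 precise variants) at 0.2; cluster B (5 noisy variants) at 0.8
  g <- rep(0.2, 8)
  ratios <- c(0.2, 0.201, 0.199, 0.8, 0.801, 0.799, 0.8005, 0.7995)
  se_G <- c(rep(0.002, 3), rep(0.05, 5))
  h <- make_harmonized(g, ratios * g, se_Gamma = se_G)
  wm <- mr_weighted_mode(h, n_boot = 10, seed = 1)
  sm <- mr_simple_mode(h, n_boot = 10, seed = 1)
  expect_lt(abs(wm$beta - 0.2), 0.05)   # weight mass on the precise cluster
  expect_lt(abs(sm$beta - 0.8), 0.05)   # head count on the larger cluster
  # grid-search oracle at the same bandwidth agrees
  wr <- wald_ratios(h)
  grid_mode <- function(v, w, bw) {
    grid <- seq(min(v) - 3 * bw, max(v) + 3 * bw, length.out = 20000)
    dens <- vapply(grid, function(x) {
      sum(w / sum(w) * dnorm((x - v) / bw) / bw)
    }, numeric(1))
    grid[which.max(dens)]
  }
  s <- 0.9 * min(sd(wr$ratio), mad(wr$ratio)) / length(wr$ratio)^0.2
  expect_equal(wm$beta, grid_mode(wr$ratio, 1 / wr$se_ratio^2, max(1e-8, s)),
               tolerance = 5e-3)
})

test_that("scale and sign equivariance hold for every estimator", {
  withr::with_seed(12, {
    h <- random_harmonized(8)
    scale_h <- function(h, c) {
      h$beta_outcome <- h$beta_outcome * c
      h$se_outcome <- h$se_outcome * abs(c)
      h
    }
    ests <- list(analytic_ivw = function(x) mr_ivw(x),
                 analytic_egger = function(x) mr_egger(x),
                 boot_median = function(x) mr_weighted_median(x, n_boot = 20, seed = 3),
                 boot_mode = function(x) mr_weighted_mode(x, n_boot = 20, seed = 3))
    for (nm in names(ests)) {
      f <- ests[[nm]]
      base <- f(h)
      up <- f(scale_h(h, 2.5))
      neg <- f(scale_h(h, -1))
      expect_equal(up$beta, 2.5 * base$beta, tolerance = 1e-6)
      expect_equal(neg$beta, -base$beta, tolerance = 1e-6)
      if (startsWith(nm, "analytic")) {
        # analytic SEs are exactly invariant; bootstrap SEs only in
        # distribution (the resampling draws differ under negation)
        expect_equal(neg$se, base$se, tolerance = 1e-10)
        expect_equal(up$se, 2.5 * base$se, tolerance = 1e-10)
      }
    }
  })
})

test_that("mr_all runs all five with per-method minimum variant counts", {
  g <- seq(0.1, 1, length.out = 10)
  hom <- make_harmonized(g, 0.3 * g, se_Gamma = rep(0.01, 10))
  all5 <- mr_all(hom, n_boot = 20, seed = 1)
  expect_named(all5, c("ivw", "egger", "weighted_median", "weighted_mode",
                       "simple_mode"))
  expect_equal(attr(all5, "primary"), "ivw")
  for (e in all5) expect_equal(e$beta, 0.3, tolerance = 1e-8)
  # OR scale bookkeeping
  expect_equal(all5$ivw$or, exp(all5$ivw$beta))
  expect_equal(all5$ivw$ci_low, exp(all5$ivw$beta - 1.96 * all5$ivw$se))
  # 2 variants: IVW present, the rest reported missing
  two <- make_harmonized(c(0.1, 0.2), c(0.05, 0.11))
  all2 <- mr_all(two, n_boot = 20, seed = 1)
  expect_false(is.na(all2$ivw$beta))
  expect_true(all(is.na(c(all2$egger$beta, all2$weighted_median$beta,
                          all2$weighted_mode$beta, all2$simple_mode$beta))))
})
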