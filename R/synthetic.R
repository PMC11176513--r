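#' Ground-truth parameters for the summary-statistics simulator
#'
#' Encodes the structural model behind a two-step mediation MR study:
#' an exposure (e.g. a gut-microbial genus) acts on a binary outcome
#' (log-odds scale) directly and through a circulating mediator (e.g. an
#' inflammatory protein), so the total effect decomposes as
#' `theta_total = theta_direct + theta_xm * theta_my`.
#'
#' Defaults mirror the headline decomposition the package's worked
#' example reproduces (total 0.387 = direct 0.369 + mediated 0.018) and
#' GWAS sample sizes typical of the consortia this design is used with
#' (a ~18k-sample microbiome GWAS, a 14,824-sample Olink pQTL study and
#' a ~187k-sample biobank disease GWAS).
#'
#' @param n_snps Number of variants that instrument the exposure.
#' @param n_snps_mediator Number of additional variants that directly
#'   instrument the mediator (default `n_snps`). These are needed for the
#'   mediator-to-outcome step to be identified: variants associated with
#'   the mediator only through the exposure carry no independent
#'   information about `theta_my`.
#' @param theta_direct Direct exposure-to-outcome effect (log-odds per
#'   exposure SD).
#' @param theta_xm Exposure-to-mediator effect (mediator SD per exposure
#'   SD).
#' @param theta_my Mediator-to-outcome effect (log-odds per mediator SD).
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct
#'   variant-outcome effects), `"directional"` (positive-mean) or
#'   `"inside_violating"` (pleiotropy proportional to the variant's
#'   exposure effect, breaking the InSIDE assumption).
#' @param pleiotropy_sd Scale of the pleiotropic effects.
#' @param prop_invalid Fraction of exposure instruments carrying
#'   pleiotropy, in \[0,1\].
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes (>= 100).
#' @param gamma_sd SD of the true variant-exposure effects.
#' @param maf_range Range of simulated minor-allele frequencies.
#' @param seed Integer seed; the study is reproducible from
#'   `(truth, seed)`.
#' @return A list of class `truth_params`, including the derived
#'   `theta_total`.
#' @export
truth_params <- function(n_snps = 100, n_snps_mediator = n_snps,
                         theta_direct = 0.369, theta_xm = 0.3,
                         theta_my = 0.06,
                         pleiotropy_mode = c("none", "balanced",
                                             "directional",
                                             "inside_violating"),
                         pleiotropy_sd = 0, prop_invalid = 0,
                         n_exposure = 18340, n_mediator = 14824,
                         n_outcome = 187119,
                         gamma_sd = 0.08, maf_range = c(0.05, 0.5),
                         seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps >= 1, n_snps_mediator >= 0,
            prop_invalid >= 0, prop_invalid <= 1,
            n_exposure >= 100, n_mediator >= 100, n_outcome >= 100,
            gamma_sd > 0, length(maf_range) == 2)
  if (!(maf_range[1] > 0 && maf_range[2] < 1 &&
        maf_range[1] <= maf_range[2])) {
    stop("maf_range must satisfy 0 < low <= high < 1", call. = FALSE)
  }
  structure(list(
    n_snps = as.integer(n_snps),
    n_snps_mediator = as.integer(n_snps_mediator),
    theta_direct = theta_direct, theta_xm = theta_xm, theta_my = theta_my,
    theta_total = theta_direct + theta_xm * theta_my,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_sd = pleiotropy_sd,
    prop_invalid = prop_invalid,
    n_exposure = n_exposure, n_mediator = n_mediator,
    n_outcome = n_outcome,
    gamma_sd = gamma_sd, maf_range = maf_range, seed = as.integer(seed)
  ), class = "truth_params")
}

# Summary-level GWAS standard error for a standardized trait:
# se = 1 / sqrt(2 N f (1 - f)).
gwas_se <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

#' Simulate a two-sample mediation MR study at the summary level
#'
#' Draws, per variant, a minor-allele frequency and a true
#' variant-exposure effect, then propagates effects through the
#' structural model of [truth_params()]: the mediator inherits
#' `theta_xm` times the exposure effect plus its own direct instruments,
#' and the outcome receives `theta_total` times the exposure effect,
#' `theta_my` times the mediator's direct effects, and any configured
#' pleiotropy. Observed effects add independent Gaussian noise at each
#' study's summary-level standard error (two-sample independence), with
#' two-sided normal p-values and EAF equal to the MAF. All three tables
#' share the same variant identifiers.
#'
#' @param truth A [truth_params()].
#' @return A list of class `synthetic_study`: `exposure`, `mediator`,
#'   `outcome` ([sumstat_table()]s), `truth`, and `instruments` (the
#'   ground-truth variant sets instrumenting the exposure and the
#'   mediator).
#' @export
simulate_study <- function(truth) {
  stopifnot(inherits(truth, "truth_params"))
  with_seed(truth$seed, {
    m <- truth$n_snps
    k <- truth$n_snps_mediator
    total_snps <- m + k
    snp <- sprintf("rs%05d", seq_len(total_snps))
    maf <- stats::runif(total_snps, truth$maf_range[1], truth$maf_range[2])

    g_true <- c(stats::rnorm(m, 0, truth$gamma_sd), rep(0, k))
    gm_own <- c(rep(0, m),
                if (k > 0) stats::rnorm(k, 0, truth$gamma_sd) else numeric(0))
    gm_true <- truth$theta_xm * g_true + gm_own

    alpha <- rep(0, total_snps)
    n_invalid <- round(truth$prop_invalid * m)
    if (truth$pleiotropy_mode != "none" && n_invalid > 0) {
      idx <- sample.int(m, n_invalid)
      alpha[idx] <- switch(
        truth$pleiotropy_mode,
        balanced = stats::rnorm(n_invalid, 0, truth$pleiotropy_sd),
        directional = stats::rnorm(n_invalid, truth$pleiotropy_sd,
                                   truth$pleiotropy_sd),
        inside_violating = truth$pleiotropy_sd * g_true[idx] / truth$gamma_sd
      )
    }
    G_true <- truth$theta_total * g_true + truth$theta_my * gm_own + alpha

    make_table <- function(true_beta, n, label, type) {
      se <- gwas_se(n, maf)
      beta <- true_beta + stats::rnorm(total_snps, 0, se)
      z <- ifelse(se > 0, beta / se, Inf)
      pval <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
      sumstat_table(
        data.frame(snp = snp, effect_allele = "A", other_allele = "G",
                   eaf = maf, beta = beta, se = se, pval = pval, n = n,
                   stringsAsFactors = FALSE),
        trait_label = label, trait_type = type)
    }
    structure(list(
      exposure = make_table(g_true, truth$n_exposure, "exposure",
                            "quantitative"),
      mediator = make_table(gm_true, truth$n_mediator, "mediator",
                            "quantitative"),
      outcome = make_table(G_true, truth$n_outcome, "outcome", "binary"),
      truth = truth,
      instruments = list(exposure = snp[seq_len(m)],
                         mediator = if (k > 0) snp[m + seq_len(k)]
                                    else character(0))
    ), class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_study> %d exposure + %d mediator ",
                     "instrument(s); theta_total = %.4g (seed %d)\n"),
              x$truth$n_snps, x$truth$n_snps_mediator,
              x$truth$theta_total, x$truth$seed))
  invisible(x)
}

#' Batteries of replicate studies for calibration experiments
#'
#' Generates `n_reps` independent studies sharing the structural
#' parameters of `base`, with per-replicate seeds drawn
#' deterministically from `seed`.
#'
#' @param base A [truth_params()] template.
#' @param n_reps Number of replicates.
#' @param seed Master seed for deriving the replicate seeds.
#' @return A list of `synthetic_study` objects.
#' @export
simulate_null_battery <- function(base, n_reps, seed = 1L) {
  stopifnot(inherits(base, "truth_params"), n_reps >= 1)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_reps))
  lapply(sub_seeds, function(s) {
    t <- base
    t$seed <- s
    simulate_study(t)
  })
}

#' Simulate a block-structured LD matrix
#'
#' Block-diagonal squared correlations: `within_r2` for every pair inside
#' a block, 0 between blocks, with synthetic positions on one chromosome
#' spaced `spacing_kb` apart so that blocks can be placed inside or
#' outside a clumping window.
#'
#' @param n_snps Total variants; `block_size` must divide it.
#' @param block_size Variants per block.
#' @param within_r2 Off-diagonal r-squared inside a block, in \[0,1\].
#' @param spacing_kb Distance in kb between adjacent variants
#'   (default 1).
#' @param snp_ids Optional identifiers (default `rs00001...`), matching
#'   [simulate_study()]'s naming.
#' @return An [ld_matrix()] with positions.
#' @export
simulate_ld_blocks <- function(n_snps, block_size, within_r2,
                               spacing_kb = 1, snp_ids = NULL) {
  stopifnot(n_snps >= 1, block_size >= 1, n_snps %% block_size == 0)
  if (within_r2 < 0 || within_r2 > 1) {
    stop("within_r2 must lie in [0,1]", call. = FALSE)
  }
  if (is.null(snp_ids)) snp_ids <- sprintf("rs%05d", seq_len(n_snps))
  block <- matrix(within_r2, block_size, block_size)
  diag(block) <- 1
  r2 <- matrix(0, n_snps, n_snps)
  for (b in seq_len(n_snps / block_size)) {
    idx <- (b - 1) * block_size + seq_len(block_size)
    r2[idx, idx] <- block
  }
  positions <- data.frame(snp = snp_ids, chr = 1L,
                          pos = as.numeric(seq_len(n_snps) - 1) *
                            spacing_kb * 1000)
  ld_matrix(snp_ids, r2, positions = positions)
}
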