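# Deterministic per-pair seed derived from a base seed and a trait label,
# so screen results do not depend on input ordering.
pair_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) + h) %% .Machine$integer.max)
}

#' Screen one exposure against one outcome
#'
#' Instrument selection, harmonization, all five estimators and the
#' diagnostics bundle for a single trait pair.
#'
#' @param exposure,outcome [sumstat_table()] objects.
#' @param criteria An [instrument_criteria()].
#' @param ld Optional [ld_matrix()].
#' @param alpha Nominal significance level for the primary (IVW)
#'   estimate (default 0.05).
#' @param seed Seed for bootstrap and simulation-based components.
#' @param presso_n_sim Simulations for MR-PRESSO (0 skips it).
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @return A list of class `screen_result`: labels, `n_instruments`,
#'   `estimates` ([mr_all()] list), `diagnostics` ([mr_diagnostics()]),
#'   `significant` (IVW p < alpha) and `qc_pass`; `NULL` (with a
#'   message) when no instruments survive selection.
#' @export
screen_pair <- function(exposure, outcome,
                        criteria = instrument_criteria(), ld = NULL,
                        alpha = 0.05, seed = NULL, presso_n_sim = 0,
                        n_boot = 1000) {
  iv <- select_instruments(exposure, criteria, ld)
  if (nrow(iv) == 0) {
    message("skipping ", attr(exposure, "trait_label"),
            ": no instruments survive selection")
    return(NULL)
  }
  h <- tryCatch(harmonize(iv, outcome), error = function(e) {
    message("skipping ", attr(exposure, "trait_label"), ": ",
            conditionMessage(e))
    NULL
  })
  if (is.null(h) || nrow(h) == 0) return(NULL)
  s <- pair_seed(seed, paste0(attr(exposure, "trait_label"), "|",
                              attr(outcome, "trait_label")))
  ests <- mr_all(h, n_boot = n_boot, seed = s)
  diag <- mr_diagnostics(h, presso_n_sim = presso_n_sim, seed = s)
  structure(list(
    exposure_label = attr(exposure, "trait_label"),
    outcome_label = attr(outcome, "trait_label"),
    n_instruments = nrow(iv),
    n_harmonized = nrow(h),
    estimates = ests,
    diagnostics = diag,
    significant = isTRUE(ests$ivw$pval < alpha),
    qc_pass = diag$qc_pass
  ), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %s -> %s (%d instrument(s)%s%s)\n",
              x$exposure_label, x$outcome_label, x$n_harmonized,
              if (x$significant) ", significant" else "",
              if (x$qc_pass) ", QC pass" else ", QC fail"))
  print(x$estimates$ivw)
  invisible(x)
}

#' Forward screen: many exposures against one outcome
#'
#' Runs [screen_pair()] for every exposure. Exposures whose label matches
#' `exclude_pattern` (by default unnamed/unclassified taxa) are removed
#' before screening; exposures with zero surviving instruments are
#' skipped with a message.
#'
#' @param exposures List of [sumstat_table()] objects.
#' @param outcome A [sumstat_table()].
#' @inheritParams screen_pair
#' @param exclude_pattern Regular expression of trait labels to exclude
#'   (case-insensitive; `NULL` keeps everything).
#' @return List of `screen_result` (class `screen_result_list`), named by
#'   exposure label; see [screen_table()] for the flat report.
#' @export
run_forward_screen <- function(exposures, outcome,
                               criteria = instrument_criteria(),
                               ld = NULL, alpha = 0.05, seed = NULL,
                               presso_n_sim = 0, n_boot = 1000,
                               exclude_pattern = "unknown|unclassified") {
  if (length(exposures) == 0) stop("no exposures supplied", call. = FALSE)
  labels <- vapply(exposures, function(e) attr(e, "trait_label"), "")
  if (!is.null(exclude_pattern)) {
    drop <- grepl(exclude_pattern, labels, ignore.case = TRUE)
    if (any(drop)) {
      message("excluding ", sum(drop), " trait(s) by label pattern")
      exposures <- exposures[!drop]
      labels <- labels[!drop]
    }
    if (length(exposures) == 0) stop("all exposures excluded", call. = FALSE)
  }
  out <- lapply(exposures, screen_pair, outcome = outcome,
                criteria = criteria, ld = ld, alpha = alpha, seed = seed,
                presso_n_sim = presso_n_sim, n_boot = n_boot)
  names(out) <- labels
  structure(out[!vapply(out, is.null, TRUE)], class = "screen_result_list")
}

#' Reverse-direction screen
#'
#' The same machinery with the roles swapped: instruments are selected on
#' the disease trait and tested against each target trait, asking whether
#' liability to the outcome feeds back on the exposures. Targets whose
#' label equals the exposure's are degenerate and skipped.
#'
#' @param outcome_as_exposure The disease [sumstat_table()], now playing
#'   the exposure role.
#' @param targets List of [sumstat_table()] traits to test against.
#' @inheritParams run_forward_screen
#' @return A `screen_result_list`, named by target label.
#' @export
run_reverse_mr <- function(outcome_as_exposure, targets,
                           criteria = instrument_criteria(), ld = NULL,
                           alpha = 0.05, seed = NULL, presso_n_sim = 0,
                           n_boot = 1000) {
  if (length(targets) == 0) stop("no targets supplied", call. = FALSE)
  out <- lapply(targets, function(tg) {
    if (identical(attr(tg, "trait_label"),
                  attr(outcome_as_exposure, "trait_label"))) {
      message("skipping degenerate target identical to the exposure")
      return(NULL)
    }
    screen_pair(outcome_as_exposure, tg, criteria = criteria, ld = ld,
                alpha = alpha, seed = seed, presso_n_sim = presso_n_sim,
                n_boot = n_boot)
  })
  names(out) <- vapply(targets, function(e) attr(e, "trait_label"), "")
  structure(out[!vapply(out, is.null, TRUE)], class = "screen_result_list")
}

#' Flatten a screen into a report table
#'
#' One row per (pair, method), mirroring the usual MR report layout:
#' exposure, outcome, method, nSNP, beta, se, OR with 95\% CI, p-value,
#' plus the QC columns and a Benjamini-Hochberg adjusted p-value across
#' the primary (IVW) tests (an addition to the nominal-significance
#' reading; the `significant` flag uses the unadjusted IVW p).
#'
#' @param screens A `screen_result_list`.
#' @return A data frame ordered by exposure label.
#' @export
screen_table <- function(screens) {
  stopifnot(inherits(screens, "screen_result_list"))
  if (length(screens) == 0) {
    return(data.frame(exposure = character(0)))
  }
  rows <- lapply(screens, function(s) {
    df <- as.data.frame(s$estimates)
    df <- cbind(exposure = s$exposure_label, outcome = s$outcome_label,
                df, row.names = NULL)
    df$q_pval <- s$diagnostics$q$pval
    df$egger_intercept_pval <- s$diagnostics$egger_intercept$pval
    df$presso_global_pval <- if (!is.null(s$diagnostics$presso)) {
      s$diagnostics$presso$global_pval
    } else NA_real_
    df$significant <- s$significant
    df$qc_pass <- s$qc_pass
    df
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab <- tab[order(tab$exposure, tab$method), ]
  ivw_rows <- tab$method == "ivw"
  tab$padj_bh <- NA_real_
  tab$padj_bh[ivw_rows] <- stats::p.adjust(tab$pval[ivw_rows], method = "BH")
  rownames(tab) <- NULL
  tab
}

# Diagnostics summary table for a screen list.
diagnostics_table <- function(screens) {
  if (length(screens) == 0) return(data.frame(exposure = character(0)))
  rows <- lapply(screens, function(s) {
    d <- s$diagnostics
    data.frame(
      exposure = s$exposure_label, outcome = s$outcome_label,
      q = d$q$q, q_df = d$q$df, q_pval = d$q$pval,
      egger_intercept = d$egger_intercept$intercept,
      egger_intercept_pval = d$egger_intercept$pval,
      presso_global_pval = if (!is.null(d$presso)) d$presso$global_pval
                           else NA_real_,
      presso_outliers = if (!is.null(d$presso) && !is.null(d$presso$outliers))
        paste(d$presso$outliers$snp, collapse = ",") else "",
      loo_max_abs_shift = if (!is.null(d$loo)) {
        full <- s$estimates$ivw$beta
        max(abs(d$loo$beta - full))
      } else NA_real_,
      qc_pass = d$qc_pass,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}

#' Run the full four-stage study
#'
#' Orchestrates the complete design: (1) forward screen of every exposure
#' against the outcome; (2) reverse MR of the outcome against the
#' exposures significant in stage 1; (3) exposure-to-mediator and
#' (4) mediator-to-outcome screens, followed by mediation decomposition
#' for mediators significant in both steps (with a significant total
#' effect). Writes one TSV per stage plus a JSON run log with seeds,
#' thresholds and per-stage counts; outputs are byte-identical across
#' reruns with the same config and seed.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `out` (output directory); `seed`; `alpha` (default 0.05);
#'   `criteria` (named list passed to [instrument_criteria()]);
#'   `presso_n_sim` (default 0); `n_boot` (default 200);
#'   `exclude_pattern` (label filter, default "unknown|unclassified");
#'   and either `simulate` (named list passed to [truth_params()]) or
#'   `inputs` (list with `exposure` paths, `mediators` paths, `outcome`
#'   path, optional `ld` path).
#' @return Invisibly, a list with the per-stage results and the run log;
#'   files are written under `config$out`.
#' @export
run_full_study <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out))
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  alpha <- config$alpha %||% 0.05
  criteria <- do.call(instrument_criteria, config$criteria %||% list())
  presso_n_sim <- config$presso_n_sim %||% 0
  n_boot <- config$n_boot %||% 200
  exclude_pattern <- config$exclude_pattern %||% "unknown|unclassified"

  ld <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    study <- simulate_study(do.call(truth_params, sim_args))
    exposures <- list(study$exposure)
    mediators <- list(study$mediator)
    outcome <- study$outcome
  } else {
    inp <- config$inputs
    stopifnot(!is.null(inp$exposure), !is.null(inp$outcome))
    read_many <- function(paths, type) {
      lapply(paths, read_sumstats, trait_type = type)
    }
    exposures <- read_many(as.list(inp$exposure), "quantitative")
    mediators <- if (!is.null(inp$mediators)) {
      read_many(as.list(inp$mediators), "quantitative")
    } else list()
    outcome <- read_sumstats(inp$outcome, trait_type = "binary")
    if (!is.null(inp$ld)) ld <- read_ld_matrix(inp$ld)
  }

  log <- list(package = "mrmediate",
              version = as.character(utils::packageVersion("mrmediate")),
              seed = seed, alpha = alpha,
              criteria = unclass(criteria),
              counts = list())

  # Stage 1: forward screen
  forward <- run_forward_screen(exposures, outcome, criteria = criteria,
                                ld = ld, alpha = alpha, seed = seed,
                                presso_n_sim = presso_n_sim,
                                n_boot = n_boot,
                                exclude_pattern = exclude_pattern)
  write_tsv(screen_table(forward), file.path(out_dir, "forward_screen.tsv"))
  write_tsv(diagnostics_table(forward),
            file.path(out_dir, "forward_diagnostics.tsv"))
  sig_labels <- names(forward)[vapply(forward, `[[`, TRUE, "significant")]
  log$counts$exposures_in <- length(exposures)
  log$counts$exposures_screened <- length(forward)
  log$counts$exposures_significant <- length(sig_labels)

  reverse <- NULL
  med_results <- list()
  if (length(sig_labels) > 0) {
    sig_exposures <- exposures[match(
      sig_labels,
      vapply(exposures, function(e) attr(e, "trait_label"), ""))]

    # Stage 2: reverse MR on the stage-1 hits
    reverse <- run_reverse_mr(outcome, sig_exposures, criteria = criteria,
                              ld = ld, alpha = alpha, seed = seed,
                              presso_n_sim = presso_n_sim, n_boot = n_boot)
    write_tsv(screen_table(reverse), file.path(out_dir, "reverse_mr.tsv"))
    log$counts$reverse_screened <- length(reverse)

    # Stages 3 + 4: mediator screens and mediation decomposition
    if (length(mediators) > 0) {
      med_rows <- list()
      for (lab in sig_labels) {
        exp_tab <- sig_exposures[[match(lab, sig_labels)]]
        res <- mediation_screen(exp_tab, mediators, outcome,
                                criteria = criteria, alpha = alpha,
                                ld = ld)
        med_results[[lab]] <- res
        scr <- attr(res, "screen")
        scr <- cbind(exposure = lab, scr, row.names = NULL)
        med_rows[[lab]] <- scr
      }
      write_tsv(do.call(rbind, c(med_rows, list(make.row.names = FALSE))),
                file.path(out_dir, "mediator_screen.tsv"))
      qualified <- unlist(lapply(med_results, function(r) {
        lapply(unclass(r), as.data.frame)
      }), recursive = FALSE)
      if (length(qualified) > 0) {
        write_tsv(do.call(rbind, c(qualified, list(make.row.names = FALSE))),
                  file.path(out_dir, "mediation.tsv"))
      }
      log$counts$mediators_in <- length(mediators)
      log$counts$mediators_qualified <- length(qualified)
    }
  } else {
    message("no significant exposure in stage 1; downstream stages skipped")
    log$counts$skipped_after_stage <- 1
  }

  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(forward = forward, reverse = reverse,
                 mediation = med_results, log = log))
}
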