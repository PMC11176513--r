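#' Two-step mediation decomposition
#'
#' Product-of-coefficients mediation on the MR scale: the mediated
#' (indirect) effect is the product of the exposure-to-mediator and
#' mediator-to-outcome IVW estimates, with the delta-method standard
#' error \eqn{\sqrt{\beta_{xm}^2 se_{my}^2 + \beta_{my}^2 se_{xm}^2}}
#' and a 95\% Wald interval. The direct effect is the total effect minus
#' the mediated effect, so the decomposition
#' `direct + mediated = total` holds exactly; the proportion mediated is
#' `mediated / total` (undefined when the total effect is zero, flagged
#' "inconsistent mediation" when mediated and total effects have
#' opposite signs).
#'
#' @param step1 `mr_estimate` for exposure -> mediator (IVW).
#' @param step2 `mr_estimate` for mediator -> outcome (IVW).
#' @param total `mr_estimate` for exposure -> outcome (IVW).
#' @param labels Optional named character vector (`exposure`, `mediator`,
#'   `outcome`) for reporting.
#' @return A list of class `mediation_result` with the decomposition,
#'   delta-method CI, `proportion_mediated` (fraction) and flags.
#' @export
two_step_mediation <- function(step1, step2, total, labels = NULL) {
  for (e in list(step1, step2, total)) {
    stopifnot(inherits(e, "mr_estimate"))
    if (is.na(e$beta)) stop("all three estimates must be available", call. = FALSE)
  }
  mediated <- step1$beta * step2$beta
  med_se <- sqrt(step1$beta^2 * step2$se^2 + step2$beta^2 * step1$se^2)
  direct <- total$beta - mediated
  prop <- if (total$beta == 0) NA_real_ else mediated / total$beta
  inconsistent <- !is.na(prop) && mediated != 0 &&
    sign(mediated) != sign(total$beta)
  structure(list(
    total_effect = total$beta,
    total_se = total$se,
    total_pval = total$pval,
    beta_xm = step1$beta, se_xm = step1$se,
    beta_my = step2$beta, se_my = step2$se,
    mediated_effect = mediated,
    mediated_se = med_se,
    mediated_ci_low = mediated - 1.96 * med_se,
    mediated_ci_high = mediated + 1.96 * med_se,
    mediated_pval = two_sided_p(if (med_se > 0) mediated / med_se else Inf),
    direct_effect = direct,
    proportion_mediated = prop,
    inconsistent_mediation = inconsistent,
    labels = labels
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  if (!is.null(x$labels)) {
    cat(sprintf("Mediation: %s -> %s -> %s\n", x$labels[["exposure"]],
                x$labels[["mediator"]], x$labels[["outcome"]]))
  }
  cat(sprintf("  total effect    %.3f\n", x$total_effect))
  cat(sprintf("  direct effect   %.3f\n", x$direct_effect))
  cat(sprintf("  mediated effect %.3f (95%% CI %.3f - %.3f)\n",
              x$mediated_effect, x$mediated_ci_low, x$mediated_ci_high))
  if (is.na(x$proportion_mediated)) {
    cat("  proportion mediated: undefined (total effect is zero)\n")
  } else {
    cat(sprintf("  proportion mediated %.3f%%%s\n",
                100 * x$proportion_mediated,
                if (x$inconsistent_mediation) " [inconsistent mediation]" else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(
    exposure = x$labels[["exposure"]] %||% NA_character_,
    mediator = x$labels[["mediator"]] %||% NA_character_,
    outcome = x$labels[["outcome"]] %||% NA_character_,
    total = x$total_effect, direct = x$direct_effect,
    mediated = x$mediated_effect,
    mediated_ci_low = x$mediated_ci_low,
    mediated_ci_high = x$mediated_ci_high,
    proportion_pct = 100 * x$proportion_mediated,
    inconsistent = x$inconsistent_mediation,
    stringsAsFactors = FALSE
  )
}

#' Screen candidate mediators between an exposure and an outcome
#'
#' For each candidate mediator, estimates exposure -> mediator (step 1,
#' instruments selected on the exposure) and mediator -> outcome (step 2,
#' instruments selected on the mediator) by IVW, alongside the total
#' exposure -> outcome effect. A mediator qualifies when both steps and
#' the total effect are significant at `alpha`; qualifying mediators get
#' a full [two_step_mediation()] decomposition. A mediator whose step-2
#' instruments and effects coincide with the exposure's (the exposure
#' relabelled) is flagged degenerate and excluded.
#'
#' @param exposure,outcome [sumstat_table()] objects.
#' @param mediators List of [sumstat_table()] candidate mediators.
#' @param criteria An [instrument_criteria()].
#' @param alpha Significance threshold (default 0.05).
#' @param ld Optional [ld_matrix()] used for every trait's clumping.
#' @return A list of `mediation_result` for qualifying mediators, with a
#'   `"screen"` attribute: one data-frame row per candidate with step
#'   estimates, p-values and status
#'   (`qualified` / `not_significant` / `degenerate` / `no_instruments`).
#' @export
mediation_screen <- function(exposure, mediators, outcome,
                             criteria = instrument_criteria(),
                             alpha = 0.05, ld = NULL) {
  stopifnot(inherits(exposure, "sumstat_table"), length(mediators) >= 1)
  iv_x <- select_instruments(exposure, criteria, ld)
  if (nrow(iv_x) == 0) stop("no instruments for the exposure", call. = FALSE)
  total <- mr_ivw(harmonize(iv_x, outcome))

  results <- list()
  screen <- list()
  for (k in seq_along(mediators)) {
    med <- mediators[[k]]
    label <- attr(med, "trait_label")
    row <- data.frame(mediator = label, beta_xm = NA_real_, p_xm = NA_real_,
                      beta_my = NA_real_, p_my = NA_real_,
                      status = "no_instruments", stringsAsFactors = FALSE)
    iv_m <- select_instruments(med, criteria, ld)
    degenerate <- identical(label, attr(exposure, "trait_label")) ||
      (nrow(iv_m) > 0 && setequal(iv_m$snp, iv_x$snp) &&
         isTRUE(max(abs(iv_m$beta[match(iv_x$snp, iv_m$snp)] - iv_x$beta)) < 1e-12))
    if (degenerate) {
      row$status <- "degenerate"
      screen[[k]] <- row
      next
    }
    step1 <- tryCatch(mr_ivw(harmonize(iv_x, med)), error = function(e) NULL)
    step2 <- if (nrow(iv_m) > 0) {
      tryCatch(mr_ivw(harmonize(iv_m, outcome)), error = function(e) NULL)
    } else NULL
    if (is.null(step1) || is.null(step2)) {
      screen[[k]] <- row
      next
    }
    row$beta_xm <- step1$beta; row$p_xm <- step1$pval
    row$beta_my <- step2$beta; row$p_my <- step2$pval
    qualifies <- step1$pval < alpha && step2$pval < alpha &&
      total$pval < alpha
    row$status <- if (qualifies) "qualified" else "not_significant"
    if (qualifies) {
      results[[label]] <- two_step_mediation(
        step1, step2, total,
        labels = c(exposure = attr(exposure, "trait_label"),
                   mediator = label,
                   outcome = attr(outcome, "trait_label")))
    }
    screen[[k]] <- row
  }
  if (length(results) == 0) {
    message("no mediator qualified at alpha = ", alpha)
  }
  structure(results, screen = do.call(rbind, screen))
}
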