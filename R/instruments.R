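#' Instrument-selection criteria
#'
#' Bundles the thresholds used to pick instrumental variables: the
#' genome-wide association p-value cut-off, the LD-clumping r-squared and
#' window, and the minimum F statistic for instrument strength.
#'
#' @param p_threshold Keep variants with `pval < p_threshold`
#'   (strict inequality; default `1e-5`).
#' @param clump_r2 Squared-correlation threshold for clumping
#'   (default 0.001).
#' @param clump_window_kb Clumping window in kilobases (default 10000);
#'   pairs farther apart, or on different chromosomes, are never clumped.
#' @param f_min Minimum F statistic; instruments with `F <= f_min` are
#'   considered weak (default 10).
#' @return A list of class `instrument_criteria`.
#' @export
instrument_criteria <- function(p_threshold = 1e-5, clump_r2 = 0.001,
                                clump_window_kb = 10000, f_min = 10) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 >= 0, clump_r2 <= 1,
            clump_window_kb > 0)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, f_min = f_min),
            class = "instrument_criteria")
}

#' Linkage-disequilibrium matrix
#'
#' A symmetric matrix of squared correlations (r-squared) between
#' variants, with unit diagonal, optionally annotated with genomic
#' positions for window-aware clumping. Stands in for a reference-panel
#' LD lookup.
#'
#' @param snp_ids Character vector of variant identifiers.
#' @param r2 Square symmetric numeric matrix in \[0,1\] with unit diagonal,
#'   dimensions matching `snp_ids`.
#' @param positions Optional data frame with columns `snp`, `chr`, `pos`
#'   (base pairs).
#' @return A list of class `ld_matrix` with elements `snp_ids`, `r2`,
#'   `positions`.
#' @export
ld_matrix <- function(snp_ids, r2, positions = NULL) {
  r2 <- as.matrix(r2)
  stopifnot(length(snp_ids) == nrow(r2), nrow(r2) == ncol(r2))
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0,1]", call. = FALSE)
  if (max(abs(r2 - t(r2))) > 1e-12) stop("r2 matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(r2) - 1)) > 1e-12) stop("r2 diagonal must be 1", call. = FALSE)
  dimnames(r2) <- list(snp_ids, snp_ids)
  if (!is.null(positions)) {
    stopifnot(all(c("snp", "chr", "pos") %in% names(positions)))
    if (!all(snp_ids %in% positions$snp)) {
      stop("positions missing for some variants", call. = FALSE)
    }
    positions <- positions[match(snp_ids, positions$snp), ]
    rownames(positions) <- NULL
  }
  structure(list(snp_ids = as.character(snp_ids), r2 = r2,
                 positions = positions),
            class = "ld_matrix")
}

#' Write / read an LD matrix as a square TSV
#'
#' The on-disk format is a square tab-separated matrix with variant
#' identifiers as the header row and first column; positions, when
#' present, travel in a sibling `<path>.pos` TSV with columns
#' `snp, chr, pos`.
#'
#' @param ld An [ld_matrix()].
#' @param path Output path.
#' @return `path` invisibly (write) or an [ld_matrix()] (read).
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  utils::write.table(ld$r2, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  if (!is.null(ld$positions)) {
    utils::write.table(ld$positions, paste0(path, ".pos"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  pos_path <- paste0(path, ".pos")
  positions <- if (file.exists(pos_path)) {
    utils::read.table(pos_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else NULL
  ld_matrix(rownames(m), m, positions = positions)
}

#' Filter variants by association p-value
#'
#' @param table A [sumstat_table()].
#' @param p_threshold Strict upper bound on the p-value.
#' @return The rows with `pval < p_threshold`, original order preserved.
#' @export
select_by_pvalue <- function(table, p_threshold = 1e-5) {
  stopifnot(inherits(table, "sumstat_table"))
  keep <- table$pval < p_threshold
  if (!any(keep)) {
    message("no variants pass p < ", format(p_threshold),
            " for ", attr(table, "trait_label"))
  }
  subset_sumstats(table, keep)
}

subset_sumstats <- function(table, idx) {
  out <- as.data.frame(table)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_label = attr(table, "trait_label"),
            trait_type = attr(table, "trait_type"),
            class = class(table))
}

#' Greedy LD clumping of candidate instruments
#'
#' Sorts candidates by ascending p-value (ties broken lexicographically by
#' variant id, so the output is deterministic), accepts the best remaining
#' variant, and discards every remaining variant whose r-squared with an
#' accepted variant meets `clump_r2` within the clumping window. Pairs on
#' different chromosomes are never clumped; a base-pair distance exactly
#' equal to the window counts as inside. Without positions every pair is
#' treated as within the window.
#'
#' @param candidates A [sumstat_table()] of candidate instruments.
#' @param ld An [ld_matrix()] covering every candidate.
#' @param criteria An [instrument_criteria()].
#' @return The retained [sumstat_table()] rows (original order), in which
#'   no pair within the window has `r2 >= clump_r2`.
#' @export
ld_clump <- function(candidates, ld, criteria = instrument_criteria()) {
  stopifnot(inherits(candidates, "sumstat_table"), inherits(ld, "ld_matrix"))
  absent <- setdiff(candidates$snp, ld$snp_ids)
  if (length(absent) > 0) {
    stop("variant(s) absent from LD matrix: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(candidates) == 0) return(candidates)
  ord <- order(candidates$pval, candidates$snp)
  accepted <- character(0)
  for (i in ord) {
    snp <- candidates$snp[i]
    if (length(accepted) > 0) {
      r2 <- ld$r2[snp, accepted]
      conflict <- r2 >= criteria$clump_r2 &
        within_window(ld, snp, accepted, criteria$clump_window_kb)
      if (any(conflict)) next
    }
    accepted <- c(accepted, snp)
  }
  subset_sumstats(candidates, candidates$snp %in% accepted)
}

# TRUE where `others` lie on the same chromosome as `snp` and within
# `window_kb` kilobases (boundary inclusive); all TRUE without positions.
within_window <- function(ld, snp, others, window_kb) {
  if (is.null(ld$positions)) return(rep(TRUE, length(others)))
  p <- ld$positions
  i <- match(snp, p$snp)
  j <- match(others, p$snp)
  p$chr[j] == p$chr[i] & abs(p$pos[j] - p$pos[i]) <= window_kb * 1000
}

#' Proportion of trait variance explained by one variant
#'
#' Uses the standard summary-level formula
#' \deqn{R^2 = \frac{2\beta^2 f(1-f)}{2\beta^2 f(1-f) + 2\,SE^2\,N\,f(1-f)}}
#' with \eqn{f} the effect-allele frequency, which simplifies to
#' \eqn{\beta^2 / (\beta^2 + N\,SE^2)}.
#'
#' @param beta,se Per-allele effect and its standard error.
#' @param eaf Effect-allele frequency, strictly inside (0,1).
#' @param n Study sample size (at least 3).
#' @return The variance explained, in \[0,1).
#' @export
variance_explained <- function(beta, eaf, se, n) {
  if (any(!is.na(eaf) & (eaf <= 0 | eaf >= 1))) {
    stop("eaf must lie strictly inside (0,1)", call. = FALSE)
  }
  stopifnot(all(se > 0, na.rm = TRUE), all(n >= 3, na.rm = TRUE))
  num <- 2 * beta^2 * eaf * (1 - eaf)
  num / (num + 2 * se^2 * n * eaf * (1 - eaf))
}

#' Instrument-strength F statistic
#'
#' \eqn{F = R^2 (N - 2) / (1 - R^2)}; values above 10 are conventionally
#' taken to indicate little weak-instrument bias.
#'
#' @param r2 Variance explained, in \[0,1).
#' @param n Sample size (at least 3).
#' @return Non-negative F statistic, strictly increasing in both arguments.
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1, na.rm = TRUE)) {
    stop("r2 must lie in [0,1)", call. = FALSE)
  }
  stopifnot(all(n >= 3, na.rm = TRUE))
  r2 * (n - 2) / (1 - r2)
}

#' Per-variant instrument strength for a table
#'
#' @param table A [sumstat_table()].
#' @return Data frame with `snp`, `r2_explained`, `f_stat`; both statistics
#'   are `NA` where the EAF is missing.
#' @export
instrument_strength <- function(table) {
  stopifnot(inherits(table, "sumstat_table"))
  r2 <- rep(NA_real_, nrow(table))
  ok <- !is.na(table$eaf)
  r2[ok] <- variance_explained(table$beta[ok], table$eaf[ok],
                               table$se[ok], table$n[ok])
  f <- rep(NA_real_, nrow(table))
  f[ok] <- f_statistic(r2[ok], table$n[ok])
  data.frame(snp = table$snp, r2_explained = r2, f_stat = f,
             stringsAsFactors = FALSE)
}

#' Drop weak instruments
#'
#' Keeps variants whose F statistic (from [variance_explained()] and
#' [f_statistic()] on the exposure study) strictly exceeds `f_min`. Rows
#' with missing EAF have incomputable strength and are excluded with a
#' warning.
#'
#' @param instruments A [sumstat_table()].
#' @param f_min Minimum F (default 10).
#' @return The retained [sumstat_table()] rows.
#' @export
filter_weak <- function(instruments, f_min = 10) {
  strength <- instrument_strength(instruments)
  if (anyNA(strength$f_stat)) {
    warning(sum(is.na(strength$f_stat)),
            " instrument(s) excluded: missing EAF, strength incomputable",
            call. = FALSE)
  }
  keep <- !is.na(strength$f_stat) & strength$f_stat > f_min
  subset_sumstats(instruments, keep)
}

#' Select instrumental variables for a trait
#'
#' Applies, in order, the p-value threshold, greedy LD clumping (when an
#' LD matrix is supplied) and the weak-instrument F filter (when EAFs are
#' available; strength is computed on the exposure study, whose beta, SE,
#' EAF and N enter the formula).
#'
#' @param table Exposure [sumstat_table()].
#' @param criteria An [instrument_criteria()].
#' @param ld Optional [ld_matrix()].
#' @return The selected instruments as a [sumstat_table()].
#' @export
select_instruments <- function(table, criteria = instrument_criteria(),
                               ld = NULL) {
  iv <- select_by_pvalue(table, criteria$p_threshold)
  if (nrow(iv) == 0) return(iv)
  if (!is.null(ld)) iv <- ld_clump(iv, ld, criteria)
  if (any(!is.na(iv$eaf))) iv <- filter_weak(iv, criteria$f_min)
  iv
}
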