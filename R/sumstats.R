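# Canonical column order for summary-statistics tables on disk.
SUMSTAT_COLS <- c("snp", "effect_allele", "other_allele", "eaf",
                  "beta", "se", "pval", "n")

NUCLEOTIDES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct a GWAS summary-statistics table
#'
#' A `sumstat_table` holds one association per variant: identifier, effect
#' and other allele, effect-allele frequency (EAF, optional), per-allele
#' effect `beta` (log-odds for binary traits, SD units for quantitative),
#' its standard error, p-value and study sample size.
#'
#' @param x A data frame with columns `snp`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`, `n` and optionally `eaf`.
#' @param trait_label Human-readable trait name.
#' @param trait_type `"quantitative"` or `"binary"` (effects on the
#'   log-odds scale).
#' @param on_invalid What to do with rows violating the record invariants
#'   (non-ACGT or identical alleles, `se <= 0`, `pval` outside (0,1],
#'   non-finite `beta`, `n < 1`, `eaf` outside (0,1)): `"error"` (default)
#'   or `"drop"` with a message giving the count.
#' @return A `sumstat_table`: a data frame in canonical column order with
#'   attributes `trait_label` and `trait_type`.
#' @export
sumstat_table <- function(x, trait_label = "trait",
                          trait_type = c("quantitative", "binary"),
                          on_invalid = c("error", "drop")) {
  trait_type <- match.arg(trait_type)
  on_invalid <- match.arg(on_invalid)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  needed <- setdiff(SUMSTAT_COLS, "eaf")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"eaf" %in% names(x)) x$eaf <- NA_real_
  x <- x[SUMSTAT_COLS]
  x$snp <- as.character(x$snp)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) x[[col]] <- as.numeric(x[[col]])
  x$n <- as.numeric(x$n)

  bad <- invalid_sumstat_rows(x)
  if (any(bad)) {
    if (on_invalid == "error") {
      stop(sum(bad), " row(s) violate summary-statistic invariants ",
           "(first offending snp: ", x$snp[bad][1], ")", call. = FALSE)
    }
    message("dropping ", sum(bad), " invalid summary-statistic row(s)")
    x <- x[!bad, , drop = FALSE]
  }
  if (nrow(x) == 0) stop("summary-statistics table is empty", call. = FALSE)
  if (anyDuplicated(x$snp)) {
    stop("duplicated snp identifiers: ",
         paste(unique(x$snp[duplicated(x$snp)]), collapse = ", "),
         call. = FALSE)
  }
  rownames(x) <- NULL
  structure(x, trait_label = trait_label, trait_type = trait_type,
            class = c("sumstat_table", "data.frame"))
}

# Logical vector flagging rows that break the per-record invariants.
# Indels / multi-allelic codings fail the single-nucleotide check.
invalid_sumstat_rows <- function(x) {
  ok_alleles <- x$effect_allele %in% NUCLEOTIDES &
    x$other_allele %in% NUCLEOTIDES &
    x$effect_allele != x$other_allele
  ok_se <- is.finite(x$se) & x$se > 0
  ok_p <- is.finite(x$pval) & x$pval > 0 & x$pval <= 1
  ok_beta <- is.finite(x$beta)
  ok_n <- is.finite(x$n) & x$n >= 1 & x$n == round(x$n)
  ok_eaf <- is.na(x$eaf) | (x$eaf > 0 & x$eaf < 1)
  ok_snp <- !is.na(x$snp) & nzchar(x$snp)
  !(ok_alleles & ok_se & ok_p & ok_beta & ok_n & ok_eaf & ok_snp)
}

#' @export
print.sumstat_table <- function(x, ...) {
  cat(sprintf("<sumstat_table> %s (%s), %d variant(s)\n",
              attr(x, "trait_label"), attr(x, "trait_type"), nrow(x)))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Expects a tab-separated table with a header row. The canonical header is
#' `snp, effect_allele, other_allele, eaf, beta, se, pval, n`; other
#' dialects are handled through `column_map` (no auto-sniffing). Rows that
#' violate the record invariants are dropped with a message giving the
#' count; missing EAF is read from the "NA" sentinel.
#'
#' @param path Path to a delimited text file.
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(snp = "rsid", pval = "p")`. Unmapped
#'   canonical names are looked up verbatim.
#' @param sep Field separator (default tab).
#' @inheritParams sumstat_table
#' @return A [sumstat_table()].
#' @export
read_sumstats <- function(path, column_map = NULL, trait_label = NULL,
                          trait_type = c("quantitative", "binary"),
                          sep = "\t") {
  trait_type <- match.arg(trait_type)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = "NA",
                           check.names = FALSE)
  if (nrow(raw) == 0) stop("no data rows in ", path, call. = FALSE)
  src <- SUMSTAT_COLS
  names(src) <- SUMSTAT_COLS
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), SUMSTAT_COLS)
    if (length(unknown) > 0) {
      stop("column_map refers to unknown canonical name(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    src[names(column_map)] <- column_map
  }
  mandatory <- setdiff(SUMSTAT_COLS, "eaf")
  absent <- mandatory[!src[mandatory] %in% names(raw)]
  if (length(absent) > 0) {
    stop("input lacks mandatory column(s): ",
         paste(src[absent], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in SUMSTAT_COLS) {
    out[[canon]] <- if (src[[canon]] %in% names(raw)) {
      raw[[src[[canon]]]]
    } else {
      NA_real_
    }
  }
  if (is.null(trait_label)) {
    trait_label <- sub("\\.[^.]+$", "", basename(path))
  }
  sumstat_table(out, trait_label = trait_label, trait_type = trait_type,
                on_invalid = "drop")
}

#' Write a summary-statistics table to a TSV file
#'
#' Columns are written in the fixed canonical order with missing values
#' encoded as `NA`, so that `read_sumstats(write_sumstats(t)) == t` and
#' repeated writes are diff-stable.
#'
#' @param table A [sumstat_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstat_table"))
  if (nrow(table) == 0) stop("refusing to write an empty table", call. = FALSE)
  utils::write.table(as.data.frame(table)[SUMSTAT_COLS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Harmonize two summary-statistics tables to a common effect allele
#'
#' Restricts to the variants shared by the exposure and outcome studies and
#' re-expresses every outcome association on the exposure's effect allele.
#' If the outcome codes the same pair of alleles in the opposite order (or
#' its strand complement), the outcome beta is negated and its EAF replaced
#' by 1 - EAF. Palindromic variants (A/T or C/G), whose strand cannot be
#' resolved from alleles alone, are aligned through allele frequency: both
#' EAFs must lie outside `0.5 +/- palindromic_eaf_window`; matching sides
#' keep the coding, opposite sides flip, anything else (including a missing
#' EAF) is dropped. Allele pairs that cannot be reconciled are dropped as
#' mismatches.
#'
#' @param exposure,outcome [sumstat_table()] objects.
#' @param palindromic_eaf_window Half-width of the ambiguous EAF zone
#'   around 0.5 (default 0.08, i.e. drop when either EAF is in
#'   \[0.42, 0.58\]).
#' @return A `harmonized_table`: a data frame with one row per retained
#'   variant holding `beta_exposure`/`se_exposure` and aligned
#'   `beta_outcome`/`se_outcome` (plus EAFs and the per-variant
#'   `action`), with the dropped variants recorded in the `"dropped"`
#'   attribute.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "sumstat_table"),
            inherits(outcome, "sumstat_table"))
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0) {
    stop("no shared variants between exposure and outcome", call. = FALSE)
  }
  ex <- exposure[match(shared, exposure$snp), ]
  ou <- outcome[match(shared, outcome$snp), ]
  lo <- 0.5 - palindromic_eaf_window
  hi <- 0.5 + palindromic_eaf_window

  action <- character(length(shared))
  flip <- logical(length(shared))
  for (i in seq_along(shared)) {
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    o_ea <- ou$effect_allele[i]; o_oa <- ou$other_allele[i]
    palindromic <- COMPLEMENT[[ea]] == oa
    if (palindromic) {
      if (!setequal(c(o_ea, o_oa), c(ea, oa))) {
        action[i] <- "dropped_mismatch"
        next
      }
      f_ex <- ex$eaf[i]
      f_ou <- if (o_ea == ea) ou$eaf[i] else 1 - ou$eaf[i]
      if (is.na(f_ex) || is.na(f_ou) ||
          (f_ex >= lo && f_ex <= hi) || (f_ou >= lo && f_ou <= hi)) {
        action[i] <- "dropped_palindromic"
      } else if ((f_ex < lo) == (f_ou < lo)) {
        # frequencies agree on which allele is minor: keep orientation
        action[i] <- if (o_ea == ea) "unchanged" else "flipped"
        flip[i] <- o_ea != ea
      } else {
        # outcome is on the opposite strand: the reported effect allele
        # frequency corresponds to the exposure's other allele
        action[i] <- if (o_ea == ea) "flipped" else "unchanged"
        flip[i] <- o_ea == ea
      }
    } else {
      same <- (o_ea == ea && o_oa == oa) ||
        (o_ea == COMPLEMENT[[ea]] && o_oa == COMPLEMENT[[oa]])
      swapped <- (o_ea == oa && o_oa == ea) ||
        (o_ea == COMPLEMENT[[oa]] && o_oa == COMPLEMENT[[ea]])
      if (same) {
        action[i] <- "unchanged"
      } else if (swapped) {
        action[i] <- "flipped"
        flip[i] <- TRUE
      } else {
        action[i] <- "dropped_mismatch"
      }
    }
  }

  beta_outcome <- ifelse(flip, -ou$beta, ou$beta)
  eaf_outcome <- ifelse(flip, 1 - ou$eaf, ou$eaf)
  h <- data.frame(
    snp = shared,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    eaf_exposure = ex$eaf,
    pval_exposure = ex$pval,
    beta_outcome = beta_outcome,
    se_outcome = ou$se,
    eaf_outcome = eaf_outcome,
    pval_outcome = ou$pval,
    action = action,
    stringsAsFactors = FALSE
  )
  kept <- !startsWith(action, "dropped")
  dropped <- h[!kept, c("snp", "action")]
  rownames(dropped) <- NULL
  h <- h[kept, , drop = FALSE]
  rownames(h) <- NULL
  structure(h,
            exposure_label = attr(exposure, "trait_label"),
            outcome_label = attr(outcome, "trait_label"),
            dropped = dropped,
            class = c("harmonized_table", "data.frame"))
}

#' @export
print.harmonized_table <- function(x, ...) {
  cat(sprintf("<harmonized_table> %s -> %s: %d variant(s) retained, %d dropped\n",
              attr(x, "exposure_label"), attr(x, "outcome_label"),
              nrow(x), nrow(attr(x, "dropped"))))
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

# Subset a harmonized table while keeping its class and labels.
subset_harmonized <- function(h, idx) {
  out <- as.data.frame(h)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            exposure_label = attr(h, "exposure_label"),
            outcome_label = attr(h, "outcome_label"),
            dropped = attr(h, "dropped"),
            class = class(h))
}
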