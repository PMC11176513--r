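test_that("read/write round-trips a table, including missing EAF", {
  tab <- make_sumstats(beta = c(0.1, -0.2, 0.05), se = c(0.01, 0.02, 0.01))
  tab$eaf[2] <- NA
  tab <- sumstat_table(tab, trait_label = "demo")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path)
  back <- read_sumstats(path, trait_label = "demo")
  expect_equal(as.data.frame(back), as.data.frame(tab))
  # the missing value is written as the NA sentinel, not dropped
  expect_true(any(grepl("\tNA\t", readLines(path))))
})

test_that("invalid rows are rejected at read time with a count", {
  df <- data.frame(
    snp = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
    effect_allele = c("A", "A", "AT", "A", "A", "A"),
    other_allele = c("G", "G", "G", "G", "G", "A"),
    eaf = c(0.3, 0.3, 0.3, 0.3, 1.2, 0.3),
    beta = 0.1, se = c(0.01, 0, 0.01, 0.01, 0.01, 0.01),
    pval = c(0.01, 0.01, 0.01, 0, 0.01, 0.01), n = 1000)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  # rs2 (se = 0), rs3 (indel), rs4 (p = 0), rs5 (eaf > 1), rs6 (same alleles)
  expect_message(tab <- read_sumstats(path), "5 invalid")
  expect_equal(tab$snp, "rs1")
})

test_that("column_map reproduces the canonical construction from a shuffled dialect", {
  tab <- make_sumstats(beta = c(0.12, -0.3, 0.07), se = c(0.01, 0.03, 0.02))
  raw <- data.frame(p = tab$pval, b = tab$beta, rsid = tab$snp,
                    a1 = tab$effect_allele, a2 = tab$other_allele,
                    freq = tab$eaf, stderr = tab$se, size = tab$n)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_sumstats(path, column_map = c(
    snp = "rsid", effect_allele = "a1", other_allele = "a2", eaf = "freq",
    beta = "b", se = "stderr", pval = "p", n = "size"),
    trait_label = "trait")
  expect_equal(as.data.frame(got), as.data.frame(tab))
})

test_that("missing mandatory columns and empty tables are errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(snp = "rs1", beta = 0.1), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path), "mandatory column")
  tab <- make_sumstats(0.1, 0.01)
  expect_error(write_sumstats(tab[0, ], tempfile()), "empty")
})

test_that("harmonize keeps identical coding and flips swapped alleles", {
  ex <- make_sumstats(beta = c(0.1, 0.1), se = 0.01, eaf = 0.2,
                      snp = c("rs1", "rs2"))
  ou <- sumstat_table(data.frame(
    snp = c("rs1", "rs2"), effect_allele = c("A", "G"),
    other_allele = c("G", "A"), eaf = c(0.2, 0.8),
    beta = 0.2, se = 0.01, pval = 0.001, n = 10000))
  h <- harmonize(ex, ou)
  expect_equal(h$action, c("unchanged", "flipped"))
  expect_equal(h$beta_outcome, c(0.2, -0.2))
  expect_equal(h$eaf_outcome, c(0.2, 0.2))
})

test_that("strand-complement codings are recognised", {
  ex <- make_sumstats(beta = c(0.1, 0.1), se = 0.01, ea = "A", oa = "G",
                      snp = c("rs1", "rs2"))
  ou <- sumstat_table(data.frame(
    snp = c("rs1", "rs2"), effect_allele = c("T", "C"),
    other_allele = c("C", "T"), eaf = 0.3, beta = 0.2, se = 0.01,
    pval = 0.001, n = 10000))
  h <- harmonize(ex, ou)
  expect_equal(h$action, c("unchanged", "flipped"))
  expect_equal(h$beta_outcome, c(0.2, -0.2))
})

test_that("irreconcilable allele pairs are dropped as mismatches", {
  ex <- make_sumstats(beta = 0.1, se = 0.01, ea = "A", oa = "G", snp = "rs1")
  ou <- make_sumstats(beta = 0.2, se = 0.01, ea = "A", oa = "C", snp = "rs1")
  h <- harmonize(ex, ou)
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "dropped")$action, "dropped_mismatch")
})

test_that("palindromic decision table over EAF quadrants is honoured", {
  pal <- function(eaf_ex, eaf_ou, o_ea = "A", o_oa = "T") {
    ex <- make_sumstats(beta = 0.1, se = 0.01, ea = "A", oa = "T",
                        eaf = eaf_ex, snp = "rs1")
    ou <- sumstat_table(data.frame(
      snp = "rs1", effect_allele = o_ea, other_allele = o_oa,
      eaf = eaf_ou, beta = 0.2, se = 0.01, pval = 0.001, n = 10000))
    harmonize(ex, ou)
  }
  # both minor, same side: aligned, kept unchanged
  h <- pal(0.10, 0.12)
  expect_equal(h$action, "unchanged")
  expect_equal(h$beta_outcome, 0.2)
  # outcome EAF ambiguous (0.5): dropped
  h <- pal(0.10, 0.50)
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "dropped")$action, "dropped_palindromic")
  # window boundary is inclusive: 0.42 and 0.58 still drop
  expect_equal(attr(pal(0.10, 0.42), "dropped")$action, "dropped_palindromic")
  expect_equal(attr(pal(0.58, 0.10), "dropped")$action, "dropped_palindromic")
  # opposite sides: the outcome effect allele is the exposure's other
  # allele on the opposite strand, so the effect flips
  h <- pal(0.10, 0.90)
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_outcome, -0.2)
  expect_equal(h$eaf_outcome, 0.1)
  # swapped allele order with agreeing minor allele flips too
  h <- pal(0.10, 0.88, o_ea = "T", o_oa = "A")
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_outcome, -0.2)
  # missing EAF on either side: conservative drop
  expect_equal(attr(pal(NA, 0.10), "dropped")$action, "dropped_palindromic")
  expect_equal(attr(pal(0.10, NA), "dropped")$action, "dropped_palindromic")
})

test_that("self-harmonization retains every non-palindromic variant unchanged", {
  withr::with_seed(1, {
    tab <- make_sumstats(beta = rnorm(20), se = runif(20, 0.01, 0.1),
                         eaf = runif(20, 0.05, 0.95))
    h <- harmonize(tab, tab)
    expect_equal(nrow(h), 20)
    expect_true(all(h$action == "unchanged"))
    expect_equal(h$beta_outcome, h$beta_exposure)
  })
})

test_that("double allele flip of the outcome is the identity", {
  withr::with_seed(2, {
    ex <- make_sumstats(beta = rnorm(10), se = runif(10, 0.01, 0.05))
    ou <- make_sumstats(beta = rnorm(10), se = runif(10, 0.01, 0.05))
    flip_tab <- function(t) {
      d <- as.data.frame(t)
      d[c("effect_allele", "other_allele")] <- d[c("other_allele", "effect_allele")]
      d$beta <- -d$beta
      d$eaf <- 1 - d$eaf
      sumstat_table(d, trait_label = attr(t, "trait_label"))
    }
    h1 <- harmonize(ex, ou)
    h2 <- harmonize(ex, flip_tab(flip_tab(ou)))
    expect_equal(as.data.frame(h1), as.data.frame(h2))
  })
})

test_that("negating outcome betas preserves |Wald ratios|", {
  withr::with_seed(3, {
    ex <- make_sumstats(beta = rnorm(10, 0.2, 0.05), se = 0.01)
    ou <- make_sumstats(beta = rnorm(10), se = 0.02)
    neg <- as.data.frame(ou)
    neg$beta <- -neg$beta
    neg <- sumstat_table(neg, trait_label = "neg")
    w1 <- wald_ratios(harmonize(ex, ou))
    w2 <- wald_ratios(harmonize(ex, neg))
    expect_equal(abs(w1$ratio), abs(w2$ratio))
    expect_equal(w1$se_ratio, w2$se_ratio)
  })
})

test_that("harmonize errors when no variants are shared", {
  ex <- make_sumstats(0.1, 0.01, snp = "rs1")
  ou <- make_sumstats(0.1, 0.01, snp = "rs2")
  expect_error(harmonize(ex, ou), "no shared")
})
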