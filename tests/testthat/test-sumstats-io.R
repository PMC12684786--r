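test_that("reading normalizes records and drops invariant violations", {
  d <- make_sumstat_df(4)
  d$effect_allele[2] <- "a"; d$other_allele[2] <- "g"  # lowercase in file
  d$se[3] <- 0                                          # invalid record
  path <- write_raw_sumstats(d, withr::local_tempfile(fileext = ".tsv"))
  tab <- readSumStats(path, traitType = "quantitative")
  expect_s4_class(tab, "SumStatTable")
  expect_equal(length(tab), 3L)
  expect_equal(as.data.frame(tab)$effect_allele[2], "A")
  expect_equal(as.data.frame(tab)$other_allele[2], "G")
  expect_equal(unname(processingLog(tab)$dropped[["bad_se"]]), 1L)

  d2 <- make_sumstat_df(3)
  path2 <- write_raw_sumstats(d2, withr::local_tempfile(fileext = ".tsv"))
  tab2 <- readSumStats(path2)
  expect_equal(as.data.frame(tab2)$beta, d2$beta)
  expect_equal(as.data.frame(tab2)$pos, as.integer(d2$pos))
})

test_that("parse errors: missing mapped column and empty result", {
  d <- make_sumstat_df(2)
  path <- write_raw_sumstats(d, withr::local_tempfile(fileext = ".tsv"))
  bad_map <- defaultColumnMap()
  bad_map["beta"] <- "no_such_column"
  expect_error(readSumStats(path, columnMap = bad_map), "absent from file")

  d$se <- 0  # every row invalid
  path2 <- write_raw_sumstats(d, withr::local_tempfile(fileext = ".tsv"))
  expect_error(readSumStats(path2), "no records remain")
})

test_that("indels and multi-allelic duplicates are rejected at parse", {
  d <- make_sumstat_df(4)
  d$effect_allele[1] <- "AT"                    # indel
  d$variant_id[3] <- d$variant_id[4]            # multi-allelic duplicate
  path <- write_raw_sumstats(d, withr::local_tempfile(fileext = ".tsv"))
  tab <- readSumStats(path)
  expect_equal(length(tab), 1L)
  drops <- processingLog(tab)$dropped
  expect_equal(unname(drops[["not_snp"]]), 1L)
  expect_equal(unname(drops[["duplicate_id"]]), 2L)
})

test_that("write/read round-trips all fields bit-identically", {
  d <- make_sumstat_df(3)
  d$beta <- c(0.123456789012345, -1 / 3, 2e-7)
  d$eaf[2] <- NA  # missing frequency written as the NA sentinel
  z <- abs(d$beta / d$se)
  d$pvalue <- pmax(2 * pnorm(-z), 1e-320)
  tab <- SumStatTable(d, traitLabel = "crp", traitType = "quantitative")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSumStats(tab, path)
  back <- readSumStats(path, traitLabel = "crp")
  expect_identical(as.data.frame(back), as.data.frame(tab))

  empty <- SumStatTable(d[0, ], traitLabel = "crp")
  expect_warning(writeSumStats(empty, path), "header-only")
})

test_that("harmonization applies match, flip, palindromic, and exclusion rules", {
  ex <- make_sumstats(4, ea = c("A", "A", "A", "A"),
                      oa = c("G", "G", "T", "G"), eaf = c(0.3, 0.3, 0.5, 0.3))
  ou_d <- make_sumstat_df(4, ea = c("A", "G", "A", "A"),
                          oa = c("G", "A", "T", "C"),
                          eaf = c(0.3, 0.7, 0.5, 0.3), beta = 0.1)
  ou <- SumStatTable(ou_d, traitLabel = "out", traitType = "binary")
  h <- harmonize(ex, ou, palindromeEafWindow = 0.08)
  d <- as.data.frame(h)
  # same alleles: match, beta kept
  expect_equal(d$action[d$variant_id == "rsT001"], "match")
  expect_equal(d$beta_out[d$variant_id == "rsT001"], 0.1)
  # swapped alleles: flip, beta negated
  expect_equal(d$action[d$variant_id == "rsT002"], "flip")
  expect_equal(d$beta_out[d$variant_id == "rsT002"], -0.1)
  # palindromic A/T at eaf 0.5: dropped
  expect_false("rsT003" %in% d$variant_id)
  # irreconcilable A/G vs A/C: excluded with reason, not fatal
  expect_false("rsT004" %in% d$variant_id)
  excl <- processingLog(h)$excluded
  expect_equal(unname(excl[["drop_palindromic"]]), 1L)
  expect_equal(unname(excl[["irreconcilable"]]), 1L)
})

test_that("variants absent from the outcome are excluded and counted", {
  ex <- make_sumstats(3)
  ou <- SumStatTable(make_sumstat_df(2), traitLabel = "out",
                     traitType = "binary")
  h <- harmonize(ex, ou)
  expect_equal(nrow(as.data.frame(h)), 2L)
  expect_equal(unname(processingLog(h)$excluded[["absent_in_outcome"]]), 1L)
})

test_that("harmonization is an involution on non-palindromic variants", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 6
    pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
    al <- pairs[sample(4, n, replace = TRUE)]
    d <- make_sumstat_df(n, ea = vapply(al, `[`, "", 1),
                         oa = vapply(al, `[`, "", 2),
                         beta = round(rnorm(n, 0, 0.1), 4),
                         eaf = round(runif(n, 0.05, 0.95), 3))
    ex <- SumStatTable(d)
    # swap alleles and negate betas: an equivalent encoding of the outcome
    d2 <- d
    d2$effect_allele <- d$other_allele
    d2$other_allele <- d$effect_allele
    d2$beta <- -d$beta
    d2$eaf <- 1 - d$eaf
    ou <- SumStatTable(d2, traitLabel = "out", traitType = "binary")
    h <- harmonize(ex, ou)
    dd <- as.data.frame(h)
    expect_equal(nrow(dd), n)
    expect_true(all(dd$action == "flip"))
    # flipping back restores the original effect
    expect_equal(dd$beta_out, d$beta)
  }
})

test_that("the bundled synthetic instrument fixture is a valid strong instrument", {
  path <- system.file("extdata", "il6r_crp_instrument_synthetic.tsv",
                      package = "cisMRkit")
  tab <- readSumStats(path, traitLabel = "ln_crp")
  expect_equal(length(tab), 26L)
  d <- as.data.frame(tab)
  expect_true(all(d$pvalue < 5e-8))
  expect_true(all(fStatistic(d$beta, d$se) > 10))
  expect_true(all(d$chrom == "1"))
})
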