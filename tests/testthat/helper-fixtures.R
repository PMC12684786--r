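# Builders shared across test files. Fixtures are constructed in code so the
# repository ships no binary data.

make_sumstat_df <- function(n = 3, chrom = "1", pos = NULL,
                            ea = "A", oa = "G", eaf = 0.3,
                            beta = 0.1, se = 0.02, n_sample = 1000L) {
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = n)
  z <- abs(rep_len(beta, n) / rep_len(se, n))
  data.frame(variant_id = sprintf("rsT%03d", seq_len(n)),
             chrom = chrom, pos = pos,
             effect_allele = rep_len(ea, n), other_allele = rep_len(oa, n),
             eaf = rep_len(eaf, n), beta = rep_len(beta, n),
             se = rep_len(se, n),
             pvalue = pmax(2 * pnorm(-z), 1e-320), n = n_sample,
             stringsAsFactors = FALSE)
}

make_sumstats <- function(..., traitLabel = "trait",
                          traitType = "quantitative") {
  SumStatTable(make_sumstat_df(...), traitLabel = traitLabel,
               traitType = traitType)
}

# a harmonized set straight from its numeric ingredients
make_h <- function(beta_exp, se_exp, beta_out, se_out,
                   eaf = 0.3, ids = NULL) {
  k <- length(beta_exp)
  if (is.null(ids)) ids <- sprintf("rsT%03d", seq_len(k))
  new("HarmonizedInstruments",
      data = data.frame(variant_id = ids,
                        beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
                        beta_out = beta_out, se_out = rep_len(se_out, k),
                        eaf = rep_len(eaf, k), action = "match",
                        stringsAsFactors = FALSE))
}

# write a sumstats data.frame in the package's file dialect
write_raw_sumstats <- function(d, path) {
  names(d) <- c("variant_id", "chromosome", "base_pair_location",
                "effect_allele", "other_allele", "effect_allele_frequency",
                "beta", "standard_error", "p_value", "n")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
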