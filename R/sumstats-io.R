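#' Default column mapping for summary-statistics files
#'
#' Source GWAS files use heterogeneous headers, so parsing is driven by a
#' name-to-column mapping. The default matches GWAS-SSF-like headers; pass a
#' modified copy to [readSumStats()] for other dialects.
#'
#' @return named character vector mapping internal field names to file
#'   column names.
#' @export
defaultColumnMap <- function() {
  c(variant_id = "variant_id", chrom = "chromosome",
    pos = "base_pair_location", effect_allele = "effect_allele",
    other_allele = "other_allele", eaf = "effect_allele_frequency",
    beta = "beta", se = "standard_error", pvalue = "p_value", n = "n")
}

.parse_numeric <- function(x) {
  x <- as.character(x)
  x[x %in% c("NA", "", ".")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read GWAS summary statistics from delimited text
#'
#' Parses a delimited text file into a [SumStatTable-class]. Alleles are
#' uppercased; `"NA"`, `""` and `"."` are treated as missing for numeric
#' fields. Rows violating the record invariants are dropped and counted in
#' the processing log rather than aborting the read: indels/multi-allelic
#' rows (allele length != 1), non-positive or missing `se`, missing `beta`,
#' p-values outside (0, 1], frequencies outside (0, 1), and rows whose
#' p-value disagrees with the normal approximation `2 * pnorm(-|beta/se|)`
#' by more than 2-fold.
#'
#' @param path file path.
#' @param columnMap named vector mapping internal names (`variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`) to file column names; defaults to [defaultColumnMap()].
#'   `eaf` and `n` entries may be omitted (recorded as missing).
#' @param traitType `"quantitative"` or `"binary"`.
#' @param traitLabel trait name stored in the table.
#' @param delim field delimiter (default tab).
#' @return a [SumStatTable-class]; `processingLog()` reports drop counts.
#' @export
readSumStats <- function(path, columnMap = defaultColumnMap(),
                         traitType = c("quantitative", "binary"),
                         traitLabel = basename(path), delim = "\t") {
  traitType <- match.arg(traitType)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "pvalue")
  missing_map <- setdiff(required, names(columnMap))
  if (length(missing_map))
    stop("columnMap lacks required fields: ",
         paste(missing_map, collapse = ", "))
  present <- intersect(names(columnMap), .SUMSTAT_COLS)
  absent_cols <- columnMap[present][!columnMap[present] %in% names(raw)]
  if (length(absent_cols))
    stop("mapped columns absent from file: ",
         paste(absent_cols, collapse = ", "))

  d <- data.frame(variant_id = raw[[columnMap[["variant_id"]]]],
                  chrom = raw[[columnMap[["chrom"]]]],
                  pos = .parse_numeric(raw[[columnMap[["pos"]]]]),
                  effect_allele = toupper(raw[[columnMap[["effect_allele"]]]]),
                  other_allele = toupper(raw[[columnMap[["other_allele"]]]]),
                  eaf = if ("eaf" %in% names(columnMap))
                    .parse_numeric(raw[[columnMap[["eaf"]]]]) else NA_real_,
                  beta = .parse_numeric(raw[[columnMap[["beta"]]]]),
                  se = .parse_numeric(raw[[columnMap[["se"]]]]),
                  pvalue = .parse_numeric(raw[[columnMap[["pvalue"]]]]),
                  n = if ("n" %in% names(columnMap))
                    .parse_numeric(raw[[columnMap[["n"]]]]) else NA_real_,
                  stringsAsFactors = FALSE)

  drops <- c(not_snp = 0L, bad_se = 0L, bad_beta = 0L, bad_pvalue = 0L,
             bad_eaf = 0L, p_beta_inconsistent = 0L, duplicate_id = 0L)
  keep <- rep(TRUE, nrow(d))

  is_snp <- d$effect_allele %in% c("A", "C", "G", "T") &
    d$other_allele %in% c("A", "C", "G", "T") &
    d$effect_allele != d$other_allele
  drops["not_snp"] <- sum(keep & !is_snp); keep <- keep & is_snp

  ok_se <- !is.na(d$se) & is.finite(d$se) & d$se > 0
  drops["bad_se"] <- sum(keep & !ok_se); keep <- keep & ok_se

  ok_beta <- !is.na(d$beta) & is.finite(d$beta)
  drops["bad_beta"] <- sum(keep & !ok_beta); keep <- keep & ok_beta

  ok_p <- !is.na(d$pvalue) & d$pvalue > 0 & d$pvalue <= 1
  drops["bad_pvalue"] <- sum(keep & !ok_p); keep <- keep & ok_p

  ok_eaf <- is.na(d$eaf) | (d$eaf > 0 & d$eaf < 1)
  drops["bad_eaf"] <- sum(keep & !ok_eaf); keep <- keep & ok_eaf

  # p vs |beta/se| coherence under the normal approximation, within 2-fold;
  # below double precision the z-score is compared instead.
  pz <- 2 * stats::pnorm(-abs(d$beta / d$se))
  coherent <- ifelse(pz > 1e-300,
                     d$pvalue >= pz / 2 & d$pvalue <= pmin(1, pz * 2),
                     d$pvalue <= 1e-250)
  coherent[is.na(coherent)] <- FALSE
  drops["p_beta_inconsistent"] <- sum(keep & !coherent)
  keep <- keep & coherent

  dup <- duplicated(d$variant_id) | duplicated(d$variant_id, fromLast = TRUE)
  first_dup <- duplicated(d$variant_id)
  drops["duplicate_id"] <- sum(keep & dup)
  keep <- keep & !dup

  d <- d[keep, , drop = FALSE]
  if (!nrow(d))
    stop("no records remain after invariant filtering in '", path, "'")
  SumStatTable(d, traitLabel = traitLabel, traitType = traitType,
               log = list(dropped = drops, n_read = length(keep),
                          n_kept = nrow(d)))
}

#' Write a SumStatTable to delimited text
#'
#' Writes the table in the package dialect (missing values as `"NA"`),
#' printing numeric fields with 17 significant digits so that
#' `readSumStats(writeSumStats(x))` round-trips all values bit-identically.
#'
#' @param table a [SumStatTable-class].
#' @param path output file path.
#' @param delim field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
writeSumStats <- function(table, path, delim = "\t") {
  stopifnot(is(table, "SumStatTable"))
  d <- table@data
  if (!nrow(d)) warning("writing a header-only file: table has no records")
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(variant_id = d$variant_id, chromosome = d$chrom,
                    base_pair_location = d$pos,
                    effect_allele = d$effect_allele,
                    other_allele = d$other_allele,
                    effect_allele_frequency = fmt(d$eaf),
                    beta = fmt(d$beta), standard_error = fmt(d$se),
                    p_value = fmt(d$pvalue),
                    n = ifelse(is.na(d$n), "NA", as.character(d$n)),
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = delim, quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(ea, oa) .COMPLEMENT[ea] == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Expresses the outcome association of every shared variant on the
#' exposure's effect allele, the form every two-sample MR estimator
#' consumes. For each variant present in both tables:
#' \itemize{
#'   \item identical allele pairs (directly or after strand complement):
#'     `action = "match"`;
#'   \item swapped allele pairs (directly or after strand complement): the
#'     outcome beta is negated and its frequency complemented,
#'     `action = "flip"`;
#'   \item palindromic variants (A/T or C/G) whose minor-allele frequency is
#'     within `palindromeEafWindow` of 0.5 in either table (or whose
#'     frequency is missing) are dropped as strand-unresolvable; otherwise
#'     they are aligned by frequency;
#'   \item irreconcilable allele sets (e.g. A/G vs A/C) are excluded with a
#'     reason code, not a fatal error.
#' }
#' Variants absent from the outcome table are excluded and counted.
#'
#' @param exposure,outcome [SumStatTable-class] objects.
#' @param palindromeEafWindow drop palindromic variants when
#'   `0.5 - maf < palindromeEafWindow` (default 0.08, i.e. maf > 0.42).
#' @return a [HarmonizedInstruments-class]; exclusion counts in
#'   `processingLog()`.
#' @export
harmonize <- function(exposure, outcome, palindromeEafWindow = 0.08) {
  stopifnot(is(exposure, "SumStatTable"), is(outcome, "SumStatTable"))
  ex <- exposure@data
  ou <- outcome@data
  if (!nrow(ex) || !nrow(ou)) stop("both tables must be non-empty")
  shared <- intersect(ex$variant_id, ou$variant_id)
  n_absent <- nrow(ex) - length(shared)
  if (!length(shared))
    stop("no shared variants between exposure and outcome tables")
  ex <- ex[match(shared, ex$variant_id), ]
  ou <- ou[match(shared, ou$variant_id), ]

  action <- character(length(shared))
  beta_out <- ou$beta
  excl <- c(absent_in_outcome = n_absent, drop_palindromic = 0L,
            irreconcilable = 0L)
  for (i in seq_along(shared)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    if (.is_palindromic(ea_x, oa_x)) {
      if (!(ea_y %in% c(ea_x, oa_x)) || !(oa_y %in% c(ea_x, oa_x)) ||
          ea_y == oa_y) {
        action[i] <- "irreconcilable"
        next
      }
      maf_x <- if (is.na(ex$eaf[i])) NA_real_ else min(ex$eaf[i], 1 - ex$eaf[i])
      maf_y <- if (is.na(ou$eaf[i])) NA_real_ else min(ou$eaf[i], 1 - ou$eaf[i])
      if (is.na(maf_x) || is.na(maf_y) ||
          (0.5 - maf_x) < palindromeEafWindow ||
          (0.5 - maf_y) < palindromeEafWindow) {
        action[i] <- "drop_palindromic"
        next
      }
      # strand is ambiguous for A/T and C/G pairs: align by frequency side
      same_side <- (ex$eaf[i] < 0.5) == (ou$eaf[i] < 0.5)
      if (same_side) {
        action[i] <- "match"
      } else {
        action[i] <- "flip"
        beta_out[i] <- -beta_out[i]
      }
      next
    }
    ea_yc <- .COMPLEMENT[ea_y]; oa_yc <- .COMPLEMENT[oa_y]
    if (ea_y == ea_x && oa_y == oa_x) {
      action[i] <- "match"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      action[i] <- "flip"
      beta_out[i] <- -beta_out[i]
    } else if (ea_yc == ea_x && oa_yc == oa_x) {
      action[i] <- "match"            # strand complement, same orientation
    } else if (ea_yc == oa_x && oa_yc == ea_x) {
      action[i] <- "flip"             # strand complement, swapped
      beta_out[i] <- -beta_out[i]
    } else {
      action[i] <- "irreconcilable"
    }
  }
  excl["drop_palindromic"] <- sum(action == "drop_palindromic")
  excl["irreconcilable"] <- sum(action == "irreconcilable")
  keep <- action %in% c("match", "flip")
  d <- data.frame(variant_id = shared[keep],
                  beta_exp = ex$beta[keep], se_exp = ex$se[keep],
                  beta_out = beta_out[keep], se_out = ou$se[keep],
                  eaf = ex$eaf[keep], action = action[keep],
                  stringsAsFactors = FALSE)
  rownames(d) <- NULL
  new("HarmonizedInstruments", data = d,
      exposureLabel = exposure@traitLabel, outcomeLabel = outcome@traitLabel,
      log = list(excluded = excl))
}

#' Read an LD r-squared matrix from square delimited text
#'
#' Expects a header row of variant ids and one row per variant in the same
#' order.
#'
#' @param path file path.
#' @param delim field delimiter.
#' @return an [LDMatrix-class].
#' @export
readLDMatrix <- function(path, delim = "\t") {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = delim,
                                   check.names = FALSE))
  LDMatrix(m, variantIds = colnames(m))
}

#' Write an LD r-squared matrix as square delimited text
#'
#' @param ld an [LDMatrix-class].
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
writeLDMatrix <- function(ld, path, delim = "\t") {
  stopifnot(is(ld, "LDMatrix"))
  out <- ld@r2
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = delim, quote = FALSE, row.names = FALSE,
                     col.names = ld@variantIds)
  invisible(path)
}
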