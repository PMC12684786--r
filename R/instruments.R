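#' Select cis variants around a gene at a significance threshold
#'
#' Retains variants on the region's chromosome with
#' `geneStart - flank <= pos <= geneEnd + flank` (boundaries inclusive on
#' both ends) and association p-value strictly below `pThreshold`. This is
#' the standard construction of a cis instrument for a protein drug target:
#' variants at the encoding locus robustly associated with the downstream
#' biomarker.
#'
#' @param table a [SumStatTable-class] with chrom/pos populated.
#' @param region a [CisRegion-class].
#' @param pThreshold genome-wide significance threshold (default 5e-8).
#' @return a [SumStatTable-class] restricted to the selected variants.
#' @export
selectCisVariants <- function(table, region, pThreshold = 5e-8) {
  stopifnot(is(table, "SumStatTable"), is(region, "CisRegion"))
  d <- table@data
  if (!any(d$chrom == region@chrom))
    warning("chromosome '", region@chrom, "' absent from table; ",
            "returning an empty selection")
  lo <- region@geneStart - region@flank
  hi <- region@geneEnd + region@flank
  keep <- d$chrom == region@chrom & !is.na(d$pos) &
    d$pos >= lo & d$pos <= hi & d$pvalue < pThreshold
  SumStatTable(d[keep, , drop = FALSE], traitLabel = table@traitLabel,
               traitType = table@traitType,
               log = c(table@log, list(cis_selected = sum(keep))))
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p unassigned variant as an index and
#' discards unassigned variants correlated with it at
#' `r2 >= r2Threshold`; the output is the index variants in ascending-p
#' order. Ties on p are broken by variant id so the result is independent
#' of input row order. Every retained variant has `r2 < r2Threshold` with
#' every earlier-selected index.
#'
#' @param table a [SumStatTable-class]; every variant must be present in
#'   `ld`.
#' @param ld an [LDMatrix-class].
#' @param r2Threshold clumping threshold (default 0.1).
#' @return a [SumStatTable-class] of index variants in p order.
#' @export
ldClump <- function(table, ld, r2Threshold = 0.1) {
  stopifnot(is(table, "SumStatTable"), is(ld, "LDMatrix"))
  d <- table@data
  missing <- setdiff(d$variant_id, ld@variantIds)
  if (length(missing))
    stop("variants missing from LD matrix: ",
         paste(missing, collapse = ", "))
  ord <- order(d$pvalue, d$variant_id)
  d <- d[ord, , drop = FALSE]
  r2 <- ld@r2[d$variant_id, d$variant_id, drop = FALSE]
  n <- nrow(d)
  state <- rep("unassigned", n)
  for (i in seq_len(n)) {
    if (state[i] != "unassigned") next
    state[i] <- "index"
    if (i < n) {
      later <- seq.int(i + 1L, n)
      hit <- later[state[later] == "unassigned" &
                     r2[i, later] >= r2Threshold]
      state[hit] <- "clumped"
    }
  }
  SumStatTable(d[state == "index", , drop = FALSE],
               traitLabel = table@traitLabel, traitType = table@traitType,
               log = c(table@log, list(clumped_away = sum(state == "clumped"))))
}

#' Instrument F statistic
#'
#' `(beta / se)^2`, the single-variant strength statistic; values above 10
#' conventionally indicate that weak-instrument bias is small.
#'
#' @param beta,se numeric vectors of exposure effect and standard error.
#' @return numeric vector of F statistics.
#' @export
fStatistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be finite and > 0")
  (beta / se)^2
}

#' Additive variance explained by an instrument set
#'
#' `sum(2 * eaf * (1 - eaf) * beta^2) / traitVariance`, the cumulative
#' trait variance explained under an additive model treating the clumped
#' variants as independent. Residual correlation below the clumping
#' threshold makes this an approximation.
#'
#' @param instruments a [SumStatTable-class] (exposure associations) or a
#'   data.frame with `eaf` and `beta` columns.
#' @param traitVariance variance of the trait on the scale of `beta`
#'   (default 1, i.e. a standardized trait).
#' @return fraction of variance explained.
#' @export
varianceExplained <- function(instruments, traitVariance = 1) {
  d <- if (is(instruments, "SumStatTable")) instruments@data
       else as.data.frame(instruments)
  if (traitVariance <= 0) stop("traitVariance must be > 0")
  if (any(is.na(d$eaf)))
    stop("eaf missing for variants: ",
         paste(d$variant_id[is.na(d$eaf)], collapse = ", "))
  sum(2 * d$eaf * (1 - d$eaf) * d$beta^2) / traitVariance
}

#' Natural-log scale of a proportional biomarker decrement
#'
#' Converts a stated proportional reduction in the biomarker (e.g. the 30%
#' decrement spanned by the extremes of a genetic score, or the 18%
#' decrement between homozygote classes of a missense variant) to the
#' signed change on the natural-log trait scale: `ln(1 - percent/100)`.
#' Multiplying a per-ln-unit causal estimate by this quantity (via
#' [rescaleEstimate()]) yields the odds ratio per decrement.
#'
#' @param percentDecrement percent reduction in (0, 100).
#' @return negative ln-scale change.
#' @export
decrementScale <- function(percentDecrement) {
  if (any(percentDecrement <= 0) || any(percentDecrement >= 100))
    stop("percentDecrement must lie strictly between 0 and 100")
  log(1 - percentDecrement / 100)
}
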