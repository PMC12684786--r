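#' Construct a SumStatTable from a data.frame
#'
#' Normalizes alleles to uppercase and coerces column types; rows are taken
#' as-is (no filtering — use [readSumStats()] for tolerant parsing).
#'
#' @param data data.frame with the ten summary-statistic columns.
#' @param traitLabel trait name.
#' @param traitType `"quantitative"` or `"binary"`.
#' @param log optional list of provenance counts.
#' @return a [SumStatTable-class].
#' @export
SumStatTable <- function(data, traitLabel = "trait",
                         traitType = c("quantitative", "binary"),
                         log = list()) {
  traitType <- match.arg(traitType)
  data <- as.data.frame(data)
  data$variant_id <- as.character(data$variant_id)
  data$chrom <- as.character(data$chrom)
  data$pos <- as.integer(data$pos)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue"))
    data[[col]] <- as.numeric(data[[col]])
  data$n <- as.integer(data$n)
  rownames(data) <- NULL
  new("SumStatTable", data = data[, .SUMSTAT_COLS], traitLabel = traitLabel,
      traitType = traitType, log = log)
}

#' Construct a CisRegion
#'
#' @param chrom chromosome label.
#' @param geneStart,geneEnd 1-based gene boundaries.
#' @param flank flank in base pairs (default 300 kb, the conventional
#'   cis window for protein drug targets).
#' @return a [CisRegion-class].
#' @export
cisRegion <- function(chrom, geneStart, geneEnd, flank = 3e5) {
  new("CisRegion", chrom = as.character(chrom), geneStart = geneStart,
      geneEnd = geneEnd, flank = flank)
}

#' Construct an LDMatrix
#'
#' @param r2 square symmetric matrix of squared correlations; dimnames are
#'   used as variant ids if `variantIds` is missing.
#' @param variantIds optional ordered variant ids.
#' @return an [LDMatrix-class].
#' @export
LDMatrix <- function(r2, variantIds = rownames(r2)) {
  if (is.null(variantIds))
    stop("variantIds must be supplied or present as dimnames(r2)")
  r2 <- as.matrix(r2)
  dimnames(r2) <- list(variantIds, variantIds)
  new("LDMatrix", variantIds = as.character(variantIds), r2 = r2)
}

#' Construct a PowerSpec
#'
#' @param nCases,nControls outcome study composition.
#' @param r2Explained instrument variance explained, in (0, 1).
#' @param alpha two-sided significance level.
#' @param targetPower power used by [minDetectableOr()].
#' @param decrementScale ln-scale change per reported decrement, usually
#'   [decrementScale()] of 30 or 18.
#' @return a [PowerSpec-class].
#' @export
powerSpec <- function(nCases, nControls, r2Explained, alpha = 0.05,
                      targetPower = 0.8, decrementScale = log(0.7)) {
  new("PowerSpec", nCases = nCases, nControls = nControls,
      r2Explained = r2Explained, alpha = alpha, targetPower = targetPower,
      decrementScale = decrementScale)
}

#' @describeIn SumStatTable-class number of records.
#' @param x,object a SumStatTable.
#' @export
setMethod("length", "SumStatTable", function(x) nrow(x@data))

#' Coerce package containers to data.frame
#'
#' @param x a `SumStatTable`, `HarmonizedInstruments`, or `CohortTable`.
#' @param row.names,optional,... ignored, present for generic compatibility.
#' @return the underlying `data.frame`.
#' @name as.data.frame-methods
#' @export
as.data.frame.SumStatTable <- function(x, row.names = NULL,
                                       optional = FALSE, ...) x@data

#' @rdname as.data.frame-methods
#' @export
as.data.frame.HarmonizedInstruments <- function(x, row.names = NULL,
                                                optional = FALSE, ...) x@data

#' @rdname as.data.frame-methods
#' @export
as.data.frame.CohortTable <- function(x, row.names = NULL,
                                      optional = FALSE, ...) x@data

#' Trait label accessor
#' @param x a SumStatTable.
#' @return character scalar.
#' @export
traitLabel <- function(x) x@traitLabel

#' Trait type accessor
#' @param x a SumStatTable.
#' @return `"quantitative"` or `"binary"`.
#' @export
traitType <- function(x) x@traitType

#' Variant id accessor
#'
#' @param x a SumStatTable, HarmonizedInstruments, LDMatrix, or CohortTable.
#' @return character vector of variant ids in table order.
#' @export
variantIds <- function(x) {
  if (is(x, "LDMatrix")) return(x@variantIds)
  if (is(x, "CohortTable")) return(x@variantIds)
  x@data$variant_id
}

#' Processing-log accessor
#' @param x a SumStatTable or HarmonizedInstruments.
#' @return list of counts recorded during parsing/harmonization.
#' @export
processingLog <- function(x) x@log

#' Dosage matrix accessor
#' @param x a CohortTable.
#' @return numeric matrix (individuals x variants) of genotype dosages.
#' @export
dosages <- function(x) {
  m <- as.matrix(x@data[, paste0("dos_", x@variantIds), drop = FALSE])
  colnames(m) <- x@variantIds
  m
}

setMethod("show", "SumStatTable", function(object) {
  cat(sprintf("SumStatTable '%s' (%s): %d variants\n", object@traitLabel,
              object@traitType, nrow(object@data)))
  if (nrow(object@data))
    print(utils::head(object@data, 5))
  if (nrow(object@data) > 5) cat("...\n")
})

setMethod("show", "HarmonizedInstruments", function(object) {
  cat(sprintf("HarmonizedInstruments: %s -> %s, %d variants retained\n",
              object@exposureLabel, object@outcomeLabel, nrow(object@data)))
  drops <- object@log$excluded
  if (length(drops))
    cat("  excluded:", paste(names(drops), drops, sep = "=", collapse = ", "),
        "\n")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s] beta=%.4f se=%.4f (95%% CI %.4f, %.4f) p=%.3g, %d variant(s)\n",
              object@method, object@beta, object@se, object@ciLow,
              object@ciHigh, object@pvalue, object@nVariants))
  if (is.finite(object@or))
    cat(sprintf("  OR=%.3f (95%% CI %.3f, %.3f)\n", object@or, object@orLow,
                object@orHigh))
})

setMethod("show", "QResult", function(object) {
  cat(sprintf("Cochran Q = %.4f on %d df, p = %.4g\n", object@q, object@df,
              object@pvalue))
})

setMethod("show", "EggerResult", function(object) {
  cat("MR-Egger\n  slope: ")
  show(object@slope)
  cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g\n", object@intercept,
              object@interceptSE, object@interceptP))
})

setMethod("show", "CohortTable", function(object) {
  cat(sprintf("CohortTable: %d individuals, %d variants%s\n",
              nrow(object@data), length(object@variantIds),
              if (!is.na(object@focalVariant))
                sprintf(", focal variant %s", object@focalVariant) else ""))
})

setMethod("show", "ContrastResult", function(object) {
  cat(sprintf("Contrast: %+.2f%% (95%% CI %+.2f%%, %+.2f%%), %d bootstrap reps, test p = %.3g\n",
              object@percentChange, object@ciLow, object@ciHigh,
              object@nBoot, object@testP))
})

setMethod("show", "GenotypeContrastResult", function(object) {
  cat(sprintf("Genotype contrast (reference %s)\n", object@reference))
  print(object@table)
  cat(sprintf("Kruskal-Wallis H = %.3f on %d df, p = %.3g\n",
              object@kruskalH, object@kruskalDf, object@kruskalP))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d variants, ldRho=%.2f, theta=%.3f, n(exposure/outcome/cohort)=%g/%g/%g, seed=%d\n",
              object@mVariants, object@ldRho, object@theta, object@nExposure,
              object@nOutcome, object@nCohort, object@seed))
})
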