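#' @import methods
NULL

# 95% normal quantile used throughout so that confidence limits are exactly
# beta +/- 1.959964 * se, matching how printed CIs are back-transformed.
Z95 <- 1.959964

.SUMSTAT_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pvalue", "n")

#' SumStatTable: per-variant GWAS summary statistics for one trait
#'
#' An ordered table of single-variant association records for one trait.
#' Each record carries the variant identity (id, chromosome, 1-based
#' position, effect and other allele), the effect-allele frequency, the
#' per-allele effect estimate with its standard error, the association
#' p-value, and the sample size. Only biallelic SNPs (single-base A/C/G/T
#' alleles) are admitted; standard errors must be positive and p-values in
#' (0, 1].
#'
#' @slot data a `data.frame` with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' @slot traitLabel single string naming the trait.
#' @slot traitType `"quantitative"` or `"binary"`.
#' @slot log list of parsing/filtering counts (e.g. dropped rows).
#' @export
setClass("SumStatTable",
         representation(data = "data.frame",
                        traitLabel = "character",
                        traitType = "character",
                        log = "list"),
         prototype(traitLabel = "trait", traitType = "quantitative",
                   log = list()))

setValidity("SumStatTable", function(object) {
  d <- object@data
  msg <- character()
  missing_cols <- setdiff(.SUMSTAT_COLS, names(d))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (!object@traitType %in% c("quantitative", "binary"))
    msg <- c(msg, "traitType must be 'quantitative' or 'binary'")
  if (nrow(d)) {
    if (anyDuplicated(d$variant_id))
      msg <- c(msg, "variant_id must be unique within a table")
    if (!all(d$effect_allele %in% c("A", "C", "G", "T")) ||
        !all(d$other_allele %in% c("A", "C", "G", "T")))
      msg <- c(msg, "alleles must be single uppercase bases A/C/G/T")
    if (any(d$effect_allele == d$other_allele))
      msg <- c(msg, "effect_allele must differ from other_allele")
    if (any(!is.finite(d$se)) || any(d$se <= 0))
      msg <- c(msg, "se must be finite and > 0")
    ok_p <- is.finite(d$pvalue) & d$pvalue > 0 & d$pvalue <= 1
    if (!all(ok_p)) msg <- c(msg, "pvalue must lie in (0, 1]")
    eaf <- d$eaf[!is.na(d$eaf)]
    if (length(eaf) && (any(eaf <= 0) || any(eaf >= 1)))
      msg <- c(msg, "eaf must lie in (0, 1) when present")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' HarmonizedInstruments: exposure and outcome effects on a shared allele
#'
#' The per-variant ingredients of every two-sample MR estimator: for each
#' instrument, the exposure association (`beta_exp`, `se_exp`) and the
#' outcome association (`beta_out`, `se_out`) expressed on the exposure's
#' effect allele, together with the harmonization action taken
#' (`match`, `flip`).
#'
#' @slot data a `data.frame` with columns `variant_id`, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`, `eaf`, `action`.
#' @slot exposureLabel,outcomeLabel trait labels carried through for reports.
#' @slot log list with counts of excluded variants by reason
#'   (`absent_in_outcome`, `drop_palindromic`, `irreconcilable`).
#' @export
setClass("HarmonizedInstruments",
         representation(data = "data.frame",
                        exposureLabel = "character",
                        outcomeLabel = "character",
                        log = "list"),
         prototype(exposureLabel = "exposure", outcomeLabel = "outcome",
                   log = list()))

setValidity("HarmonizedInstruments", function(object) {
  d <- object@data
  need <- c("variant_id", "beta_exp", "se_exp", "beta_out", "se_out",
            "eaf", "action")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(d)) {
    if (any(d$se_exp <= 0) || any(d$se_out <= 0))
      return("se_exp and se_out must be > 0")
    if (!all(d$action %in% c("match", "flip")))
      return("retained actions must be 'match' or 'flip'")
  }
  TRUE
})

#' MREstimate: a method-labeled causal-effect estimate
#'
#' A causal-effect estimate on the log-odds (binary outcome) or SD
#' (quantitative outcome) scale per unit of exposure, with normal-theory
#' 95% CI and two-sided p-value. After [rescaleEstimate()] the odds-ratio
#' slots (`or`, `orLow`, `orHigh`) are populated.
#'
#' @slot method one of `wald_ratio`, `ivw_fixed`, `egger_slope`,
#'   `weighted_median`, `weighted_mode`.
#' @slot beta,se point estimate and standard error.
#' @slot ciLow,ciHigh `beta -/+ 1.959964 * se`.
#' @slot pvalue two-sided normal p-value.
#' @slot nVariants number of instruments used.
#' @slot or,orLow,orHigh exponentiated estimate and CI (NA until rescaled).
#' @export
setClass("MREstimate",
         representation(method = "character", beta = "numeric",
                        se = "numeric", ciLow = "numeric", ciHigh = "numeric",
                        pvalue = "numeric", nVariants = "integer",
                        or = "numeric", orLow = "numeric", orHigh = "numeric"),
         prototype(or = NA_real_, orLow = NA_real_, orHigh = NA_real_))

setValidity("MREstimate", function(object) {
  ok_methods <- c("wald_ratio", "ivw_fixed", "egger_slope",
                  "weighted_median", "weighted_mode")
  if (!object@method %in% ok_methods)
    return(paste("method must be one of:", paste(ok_methods, collapse = ", ")))
  if (object@se < 0) return("se must be >= 0")
  if (is.finite(object@beta) && is.finite(object@se)) {
    if (abs(object@ciLow - (object@beta - Z95 * object@se)) > 1e-8 ||
        abs(object@ciHigh - (object@beta + Z95 * object@se)) > 1e-8)
      return("ci must equal beta -/+ 1.959964 * se")
  }
  TRUE
})

#' QResult: a Cochran Q heterogeneity statistic
#'
#' @slot q nonnegative Q statistic.
#' @slot df degrees of freedom (>= 1).
#' @slot pvalue upper-tail chi-square p-value at `q` on `df` df.
#' @export
setClass("QResult",
         representation(q = "numeric", df = "integer", pvalue = "numeric"))

setValidity("QResult", function(object) {
  if (object@q < 0) return("q must be >= 0")
  if (object@df < 1L) return("df must be >= 1")
  TRUE
})

#' EggerResult: MR-Egger slope and pleiotropy intercept
#'
#' @slot slope an [MREstimate-class] for the Egger slope.
#' @slot intercept,interceptSE intercept of the weighted regression; a
#'   nonzero value indicates directional (unbalanced) pleiotropy.
#' @slot interceptP two-sided normal p-value for the intercept.
#' @export
setClass("EggerResult",
         representation(slope = "MREstimate", intercept = "numeric",
                        interceptSE = "numeric", interceptP = "numeric"))

#' CohortTable: individual-level cohort rows
#'
#' One row per individual: per-variant genotype dosages (columns prefixed
#' `dos_`, values in \[0, 2\]), the biomarker on its original positive scale
#' (`trait`) and natural-log scale (`ln_trait`), `age` in years, `sex`
#' coded 0/1, ten principal components `pc1`..`pc10`, and optionally a
#' `genotype_class` factor (e.g. AA/AC/CC) for a focal variant.
#'
#' @slot data the cohort `data.frame`.
#' @slot variantIds variant ids matching the `dos_` columns in order.
#' @slot focalVariant id of the variant behind `genotype_class`, or NA.
#' @export
setClass("CohortTable",
         representation(data = "data.frame", variantIds = "character",
                        focalVariant = "character"),
         prototype(focalVariant = NA_character_))

setValidity("CohortTable", function(object) {
  d <- object@data
  dos_cols <- paste0("dos_", object@variantIds)
  missing_cols <- setdiff(c(dos_cols, "trait", "ln_trait", "age", "sex",
                            paste0("pc", 1:10)), names(d))
  if (length(missing_cols))
    return(paste("missing columns:",
                 paste(utils::head(missing_cols, 5), collapse = ", ")))
  if (nrow(d)) {
    dos <- as.matrix(d[, dos_cols, drop = FALSE])
    if (any(dos < 0) || any(dos > 2)) return("dosages must lie in [0, 2]")
    if (any(d$trait <= 0)) return("trait must be > 0")
    if (!all(d$sex %in% c(0, 1))) return("sex must be coded 0/1")
  }
  TRUE
})

#' ContrastResult: a bootstrap-calibrated group contrast
#'
#' @slot groupMedians named group medians.
#' @slot percentChange percent change of the comparison group relative to
#'   the reference group, `100 * (m_cmp - m_ref) / m_ref`.
#' @slot ciLow,ciHigh percentile bootstrap 95% CI for `percentChange`.
#' @slot nBoot bootstrap iterations used.
#' @slot testP p-value of the accompanying rank test.
#' @export
setClass("ContrastResult",
         representation(groupMedians = "numeric", percentChange = "numeric",
                        ciLow = "numeric", ciHigh = "numeric",
                        nBoot = "integer", testP = "numeric"))

setValidity("ContrastResult", function(object) {
  if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
      (object@ciLow > object@percentChange ||
       object@ciHigh < object@percentChange))
    return("percentChange must lie within [ciLow, ciHigh]")
  TRUE
})

#' GenotypeContrastResult: genotype-class medians with omnibus and pairwise tests
#'
#' @slot table per-class `data.frame`: class, n, median, percent change vs
#'   the reference class with bootstrap CI.
#' @slot kruskalH,kruskalDf,kruskalP Kruskal-Wallis omnibus test.
#' @slot dunn `data.frame` of Dunn pairwise z tests with adjusted p-values.
#' @slot reference the reference class label.
#' @export
setClass("GenotypeContrastResult",
         representation(table = "data.frame", kruskalH = "numeric",
                        kruskalDf = "integer", kruskalP = "numeric",
                        dunn = "data.frame", reference = "character"))

#' CisRegion: a gene window for cis-instrument selection
#'
#' @slot chrom chromosome label (string, e.g. "1").
#' @slot geneStart,geneEnd 1-based gene boundaries, start <= end.
#' @slot flank flanking distance in base pairs added to both sides.
#' @export
setClass("CisRegion",
         representation(chrom = "character", geneStart = "numeric",
                        geneEnd = "numeric", flank = "numeric"))

setValidity("CisRegion", function(object) {
  if (object@geneStart > object@geneEnd) return("geneStart must be <= geneEnd")
  if (object@flank < 0) return("flank must be >= 0")
  TRUE
})

#' LDMatrix: pairwise squared-correlation matrix for a variant panel
#'
#' @slot variantIds ordered variant ids.
#' @slot r2 symmetric matrix of squared correlations in \[0, 1\] with unit
#'   diagonal, dimnames matching `variantIds`.
#' @export
setClass("LDMatrix",
         representation(variantIds = "character", r2 = "matrix"))

setValidity("LDMatrix", function(object) {
  r2 <- object@r2
  if (nrow(r2) != length(object@variantIds) ||
      ncol(r2) != length(object@variantIds))
    return("r2 dimensions must match variantIds")
  if (any(r2 < -1e-12) || any(r2 > 1 + 1e-12))
    return("r2 values must lie in [0, 1]")
  if (max(abs(r2 - t(r2))) > 1e-8) return("r2 must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) return("r2 diagonal must be 1")
  TRUE
})

#' PowerSpec: design parameters for MR power on a binary outcome
#'
#' @slot nCases,nControls outcome sample composition.
#' @slot r2Explained fraction of exposure variance explained by the
#'   instrument.
#' @slot alpha two-sided type-I error rate.
#' @slot targetPower power at which the minimum detectable OR is computed.
#' @slot decrementScale signed ln-scale change per reported decrement
#'   (from [decrementScale()]), connecting per-decrement ORs to per-ln-unit
#'   effects.
#' @export
setClass("PowerSpec",
         representation(nCases = "numeric", nControls = "numeric",
                        r2Explained = "numeric", alpha = "numeric",
                        targetPower = "numeric", decrementScale = "numeric"))

setValidity("PowerSpec", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
  if (object@targetPower <= 0 || object@targetPower >= 1)
    return("targetPower must be in (0,1)")
  if (object@r2Explained <= 0 || object@r2Explained >= 1)
    return("r2Explained must be in (0,1)")
  if (object@nCases <= 0 || object@nControls <= 0)
    return("nCases and nControls must be > 0")
  TRUE
})

#' SimConfig: generating parameters of a synthetic two-sample MR study
#'
#' Describes a cis region of `mVariants` LD-correlated SNPs with additive
#' effects `a` on a log-normal biomarker, a binary outcome generated from a
#' logistic model with causal effect `theta` (log-odds per ln-unit of the
#' biomarker) and per-variant direct effects `gamma` (pleiotropy), and the
#' sample sizes of the exposure GWAS, outcome GWAS, and individual-level
#' cohort.
#'
#' @slot mVariants number of variants in the region.
#' @slot mafRange range the per-variant minor allele frequencies are drawn
#'   from, within (0, 0.5\].
#' @slot ldRho first-order autoregressive correlation of the latent
#'   haplotype Gaussians (adjacent-variant LD), in \[0, 1).
#' @slot a per-variant effects on the ln-biomarker; `NA` means "draw
#'   standard-normal directions and scale so the additive variance explained
#'   equals `r2Target`".
#' @slot r2Target additive variance-explained fraction used when `a` is
#'   auto-generated.
#' @slot exposureSd residual SD of the ln-biomarker.
#' @slot lnTraitMean mean of the ln-biomarker (sets the trait median).
#' @slot theta causal log-odds per ln-unit of the biomarker.
#' @slot gamma per-variant direct log-odds on the outcome (recycled).
#' @slot prevalenceIntercept logistic intercept controlling the case
#'   fraction.
#' @slot nExposure,nOutcome,nCohort sample sizes.
#' @slot seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @export
setClass("SimConfig",
         representation(mVariants = "integer", mafRange = "numeric",
                        ldRho = "numeric", a = "numeric", r2Target = "numeric",
                        exposureSd = "numeric", lnTraitMean = "numeric",
                        theta = "numeric", gamma = "numeric",
                        prevalenceIntercept = "numeric",
                        nExposure = "numeric", nOutcome = "numeric",
                        nCohort = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@mVariants < 1L) return("mVariants must be >= 1")
  if (length(object@mafRange) != 2 || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    return("mafRange must lie within (0, 0.5]")
  if (object@ldRho < 0 || object@ldRho >= 1) return("ldRho must be in [0, 1)")
  if (object@nExposure <= 0 || object@nOutcome <= 0 || object@nCohort <= 0)
    return("sample sizes must be > 0")
  if (object@exposureSd <= 0) return("exposureSd must be > 0")
  TRUE
})

#' SimTruth: the realized generating parameters of a synthetic study
#'
#' Kept alongside simulated data so that recovery tests can compare
#' estimates with the truth.
#'
#' @slot a realized per-variant ln-biomarker effects.
#' @slot theta causal log-odds per ln-unit of the biomarker.
#' @slot gamma realized per-variant direct outcome effects.
#' @slot mafs configured minor allele frequencies.
#' @slot r2 realized LD r-squared matrix (exposure sample).
#' @slot variantIds variant ids.
#' @export
setClass("SimTruth",
         representation(a = "numeric", theta = "numeric", gamma = "numeric",
                        mafs = "numeric", r2 = "matrix",
                        variantIds = "character"))
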