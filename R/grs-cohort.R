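#' Compute genetic risk scores
#'
#' `score_i = sum_j dosage_ij * weight_j` — the clumping-and-thresholding
#' score: per-individual weighted sums of effect-allele dosages, weighted
#' by the instrument's exposure effects.
#'
#' @param cohort a [CohortTable-class].
#' @param weights per-variant weights; if named, names must match the
#'   cohort's variant ids (order is reconciled), otherwise length and order
#'   must match.
#' @return numeric vector of scores, one per individual.
#' @export
computeGRS <- function(cohort, weights) {
  stopifnot(is(cohort, "CohortTable"))
  dos <- dosages(cohort)
  if (!is.null(names(weights))) {
    missing <- setdiff(colnames(dos), names(weights))
    if (length(missing))
      stop("weights missing for variants: ", paste(missing, collapse = ", "))
    weights <- weights[colnames(dos)]
  } else if (length(weights) != ncol(dos)) {
    stop("length(weights) = ", length(weights), " but cohort has ",
         ncol(dos), " variants")
  }
  drop(dos %*% weights)
}

.boot_percent_change <- function(ref, cmp, n_boot, seed) {
  with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      m_ref <- stats::median(sample(ref, replace = TRUE))
      m_cmp <- stats::median(sample(cmp, replace = TRUE))
      100 * (m_cmp - m_ref) / m_ref
    }, numeric(1))
  })
}

#' Trait contrast between score-distribution tails
#'
#' Compares the median trait between individuals in the top and bottom
#' `percentile` tails of a genetic score (tails cut at type-7 quantiles,
#' boundary values included). Reports the percent change of the top-tail
#' median relative to the bottom-tail median, a percentile bootstrap 95%
#' CI from `nBoot` seeded resamples of both tails, and a Wilcoxon rank-sum
#' p-value.
#'
#' @param scores per-individual scores.
#' @param trait per-individual trait values (original positive scale).
#' @param percentile tail fraction (default 0.01, i.e. top vs bottom
#'   percentile).
#' @param nBoot bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @return a [ContrastResult-class] with `groupMedians = c(bottom, top)`.
#' @export
percentileContrast <- function(scores, trait, percentile = 0.01,
                               nBoot = 10000L, seed = 1L) {
  stopifnot(length(scores) == length(trait))
  qlo <- stats::quantile(scores, percentile, type = 7, names = FALSE)
  qhi <- stats::quantile(scores, 1 - percentile, type = 7, names = FALSE)
  bottom <- trait[scores <= qlo]
  top <- trait[scores >= qhi]
  if (!length(bottom) || !length(top))
    stop("empty tail at percentile ", percentile)
  m <- c(bottom = stats::median(bottom), top = stats::median(top))
  pc <- 100 * (m["top"] - m["bottom"]) / m["bottom"]
  boots <- .boot_percent_change(bottom, top, nBoot, seed)
  ci <- stats::quantile(boots, c(0.025, 0.975), type = 7, names = FALSE)
  new("ContrastResult", groupMedians = m, percentChange = unname(pc),
      ciLow = min(ci[1], pc), ciHigh = max(ci[2], pc),
      nBoot = as.integer(nBoot),
      testP = stats::wilcox.test(top, bottom, exact = FALSE)$p.value)
}

# Dunn pairwise z statistics on the joint ranks, with the standard tie
# correction; reduces to the no-tie formula on tie-free data.
.dunn_test <- function(values, groups, p_adjust = "holm") {
  groups <- factor(groups)
  rk <- rank(values)
  n <- length(values)
  mean_ranks <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(p) {
    (mean_ranks[[p[1]]] - mean_ranks[[p[2]]]) /
      sqrt((n * (n + 1) / 12 - tie_term) *
             (1 / n_g[[p[1]]] + 1 / n_g[[p[2]]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, pvalue = p,
             p_adjusted = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

#' Trait contrast across genotype classes of a focal variant
#'
#' Per-class trait medians with the percent decrease of each class relative
#' to the reference class, percentile bootstrap 95% CIs for the decreases
#' (seeded, 10000 iterations by default), a Kruskal-Wallis omnibus test,
#' and Dunn pairwise z tests with multiplicity adjustment.
#'
#' @param cohort a [CohortTable-class] with `genotype_class` populated, or
#'   a data.frame with `trait` and `genotype_class` columns.
#' @param reference reference class label (default the first class in
#'   sorted order, conventionally the non-carrier homozygote).
#' @param nBoot bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @param pAdjust multiplicity adjustment for the Dunn tests (default
#'   `"holm"`; any [stats::p.adjust()] method).
#' @return a [GenotypeContrastResult-class].
#' @export
genotypeContrast <- function(cohort, reference = NULL, nBoot = 10000L,
                             seed = 1L, pAdjust = "holm") {
  d <- if (is(cohort, "CohortTable")) cohort@data else as.data.frame(cohort)
  if (!"genotype_class" %in% names(d) || all(is.na(d$genotype_class)))
    stop("cohort has no genotype_class column populated")
  d <- d[!is.na(d$genotype_class), ]
  classes <- sort(unique(as.character(d$genotype_class)))
  if (length(classes) < 2L) stop("need >= 2 non-empty genotype classes")
  if (is.null(reference)) reference <- classes[1]
  if (!reference %in% classes) stop("reference class '", reference,
                                    "' not present")
  ref_trait <- d$trait[d$genotype_class == reference]
  rows <- lapply(classes, function(cl) {
    tr <- d$trait[d$genotype_class == cl]
    med <- stats::median(tr)
    if (cl == reference)
      return(data.frame(class = cl, n = length(tr), median = med,
                        percent_change = 0, ci_low = NA_real_,
                        ci_high = NA_real_, stringsAsFactors = FALSE))
    pc <- 100 * (med - stats::median(ref_trait)) / stats::median(ref_trait)
    boots <- .boot_percent_change(ref_trait, tr, nBoot,
                                  seed + match(cl, classes))
    ci <- stats::quantile(boots, c(0.025, 0.975), type = 7, names = FALSE)
    data.frame(class = cl, n = length(tr), median = med, percent_change = pc,
               ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
  })
  kw <- stats::kruskal.test(d$trait, factor(d$genotype_class))
  new("GenotypeContrastResult", table = do.call(rbind, rows),
      kruskalH = unname(kw$statistic), kruskalDf = as.integer(kw$parameter),
      kruskalP = kw$p.value,
      dunn = .dunn_test(d$trait, d$genotype_class, pAdjust),
      reference = reference)
}

#' Variance in the ln-trait explained by a score or dosage
#'
#' Ordinary least squares of `ln_trait` on the predictor. The reported R2
#' is always from the univariable fit (the proportion of biomarker
#' variance the instrument explains); when `adjusted = TRUE` the returned
#' coefficient table additionally conditions on age, sex, and the first 10
#' principal components.
#'
#' @param cohort a [CohortTable-class].
#' @param predictor per-individual numeric predictor (a genetic score or a
#'   single variant's dosages).
#' @param adjusted adjust the coefficient model for age, sex, and 10 PCs.
#' @return list with `r2` (univariable R2) and `coefficients` (coefficient
#'   table of the requested model).
#' @export
olsVarianceExplained <- function(cohort, predictor, adjusted = FALSE) {
  stopifnot(is(cohort, "CohortTable"))
  d <- cohort@data
  if (length(predictor) != nrow(d))
    stop("predictor length must equal cohort size")
  df <- data.frame(y = d$ln_trait, x = predictor)
  uni <- stats::lm(y ~ x, data = df)
  model <- if (adjusted) {
    df <- cbind(df, age = d$age, sex = d$sex,
                d[, paste0("pc", 1:10), drop = FALSE])
    stats::lm(y ~ ., data = df)
  } else uni
  if (any(!is.finite(stats::coef(model))))
    stop("rank-deficient design: check the predictor and covariates")
  list(r2 = summary(uni)$r.squared,
       coefficients = summary(model)$coefficients)
}
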