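.mk_est <- function(method, beta, se, n) {
  z <- if (se > 0) beta / se else if (beta == 0) 0 else sign(beta) * Inf
  new("MREstimate", method = method, beta = beta, se = se,
      ciLow = beta - Z95 * se, ciHigh = beta + Z95 * se,
      pvalue = 2 * stats::pnorm(-abs(z)), nVariants = as.integer(n))
}

.hdata <- function(h) {
  if (is(h, "HarmonizedInstruments")) h@data else as.data.frame(h)
}

# per-variant Wald ratios and first-order IVW weights
.ratios <- function(d) {
  if (any(d$beta_exp == 0))
    stop("beta_exp must be nonzero for every instrument")
  list(r = d$beta_out / d$beta_exp, w = d$beta_exp^2 / d$se_out^2)
}

#' Subset harmonized instruments
#' @param x a HarmonizedInstruments.
#' @param i row index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "HarmonizedInstruments", function(x, i, j, ..., drop = FALSE) {
  d <- x@data[i, , drop = FALSE]
  rownames(d) <- NULL
  initialize(x, data = d)
})

#' Wald ratio estimator for a single instrument
#'
#' The causal effect from one variant: `beta_out / beta_exp`, with the
#' first-order standard error `se_out / |beta_exp|` (exposure-side
#' uncertainty ignored). Used when the instrument is a single functional
#' variant.
#'
#' @param h a [HarmonizedInstruments-class] with exactly one variant.
#' @return an [MREstimate-class] with method `"wald_ratio"`.
#' @export
waldRatio <- function(h) {
  d <- .hdata(h)
  if (nrow(d) != 1L)
    stop("waldRatio takes a single instrument; use ivwFixed for ", nrow(d))
  if (d$beta_exp == 0) stop("beta_exp is zero: Wald ratio undefined")
  .mk_est("wald_ratio", d$beta_out / d$beta_exp, d$se_out / abs(d$beta_exp), 1L)
}

#' Fixed-effect inverse-variance-weighted estimator
#'
#' The precision-weighted average of per-variant Wald ratios with
#' first-order weights `w_j = beta_exp_j^2 / se_out_j^2`:
#' `beta = sum(w * ratio) / sum(w)`, `se = 1 / sqrt(sum(w))`. Equivalent to
#' weighted least squares of `beta_out` on `beta_exp` through the origin
#' with weights `1 / se_out^2`. The primary estimator in the absence of
#' pleiotropy.
#'
#' @param h a [HarmonizedInstruments-class] with at least two variants.
#' @return an [MREstimate-class] with method `"ivw_fixed"`.
#' @export
ivwFixed <- function(h) {
  d <- .hdata(h)
  if (nrow(d) < 2L)
    stop("ivwFixed needs >= 2 instruments; use waldRatio for a single one")
  rw <- .ratios(d)
  .mk_est("ivw_fixed", sum(rw$w * rw$r) / sum(rw$w), 1 / sqrt(sum(rw$w)),
          nrow(d))
}

#' Cochran Q heterogeneity test across instruments
#'
#' `Q = sum(w_j * (ratio_j - beta_ivw)^2)` on `n - 1` degrees of freedom,
#' with the same first-order weights as [ivwFixed()]. Excess heterogeneity
#' among per-variant ratios is a metric of pleiotropy.
#'
#' @param h the [HarmonizedInstruments-class] used for the IVW fit.
#' @param ivw the corresponding [MREstimate-class]; recomputed from `h`
#'   when missing.
#' @return a [QResult-class].
#' @export
cochranQ <- function(h, ivw = ivwFixed(h)) {
  d <- .hdata(h)
  if (nrow(d) < 2L) stop("cochranQ needs >= 2 instruments")
  if (ivw@nVariants != nrow(d))
    stop("ivw estimate was computed from a different instrument set")
  rw <- .ratios(d)
  q <- sum(rw$w * (rw$r - ivw@beta)^2)
  df <- nrow(d) - 1L
  new("QResult", q = q, df = df,
      pvalue = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least squares of `beta_out` on `beta_exp` with weights
#' `1 / se_out^2` and a free intercept, after orienting every variant so
#' `beta_exp >= 0` (Egger regression is not invariant to allele flips; the
#' conventional resolution is a common positive-exposure orientation). The
#' slope estimates the causal effect under the assumption that pleiotropic
#' effects are uncorrelated with instrument strength; the intercept
#' measures directional (unbalanced) pleiotropy. Coefficient standard
#' errors come from the weighted regression with the residual standard
#' deviation floored at 1 (no sharpening below the fixed-effect model).
#'
#' @param h a [HarmonizedInstruments-class] with at least three variants.
#' @return an [EggerResult-class].
#' @export
mrEgger <- function(h) {
  d <- .hdata(h)
  if (nrow(d) < 3L) stop("mrEgger needs >= 3 instruments")
  s <- sign(d$beta_exp)
  s[s == 0] <- 1
  bx <- d$beta_exp * s
  by <- d$beta_out * s
  fit <- stats::lm(by ~ bx, weights = 1 / d$se_out^2)
  sm <- summary(fit)
  ses <- sm$coefficients[, "Std. Error"] / min(1, sm$sigma)
  slope <- .mk_est("egger_slope", unname(stats::coef(fit)["bx"]),
                   unname(ses["bx"]), nrow(d))
  int <- unname(stats::coef(fit)["(Intercept)"])
  int_se <- unname(ses["(Intercept)"])
  new("EggerResult", slope = slope, intercept = int, interceptSE = int_se,
      interceptP = 2 * stats::pnorm(-abs(int / int_se)))
}

.weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

.parametric_boot <- function(d, n_boot, seed, statistic) {
  boots <- numeric(n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      bx <- stats::rnorm(nrow(d), d$beta_exp, d$se_exp)
      by <- stats::rnorm(nrow(d), d$beta_out, d$se_out)
      boots[b] <- statistic(bx, by)
    }
  })
  boots
}

#' Weighted median estimator
#'
#' The median of per-variant Wald ratios under standardized cumulative
#' weights: ratios are sorted, cumulative weights
#' `s_j = (cumsum(w) - w/2) / sum(w)` computed, and the estimate
#' interpolates linearly between the ratios bracketing `s = 0.5`.
#' Consistent when at least 50% of the weight comes from valid
#' instruments. The standard error comes from a seeded parametric
#' bootstrap resampling `(beta_exp, beta_out)` from their normal errors.
#'
#' @param h a [HarmonizedInstruments-class] with at least three variants.
#' @param nBoot bootstrap replicates (default 1000; below 100 warns).
#' @param seed integer seed for the bootstrap.
#' @return an [MREstimate-class] with method `"weighted_median"`.
#' @export
weightedMedian <- function(h, nBoot = 1000L, seed = 1L) {
  d <- .hdata(h)
  if (nrow(d) < 3L) stop("weightedMedian needs >= 3 instruments")
  if (nBoot < 100L) warning("nBoot < 100 gives an unstable bootstrap se")
  rw <- .ratios(d)
  est <- .weighted_median_point(rw$r, rw$w)
  boots <- .parametric_boot(d, nBoot, seed, function(bx, by) {
    .weighted_median_point(by / bx, bx^2 / d$se_out^2)
  })
  .mk_est("weighted_median", est, stats::sd(boots), nrow(d))
}

.weighted_mode_point <- function(r, w, phi, grid_size = 512L) {
  n <- length(r)
  spread <- min(stats::sd(r), stats::IQR(r) / 1.34)
  h_bw <- phi * 0.9 * spread * n^(-1 / 5)
  if (!is.finite(h_bw) || h_bw <= 0) return(r[1])
  grid <- seq(mean(r) - 4 * stats::sd(r), mean(r) + 4 * stats::sd(r),
              length.out = grid_size)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm((x - r) / h_bw)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Weighted mode estimator
#'
#' Smooths the per-variant Wald ratios with a normal kernel (bandwidth
#' `phi * 0.9 * min(sd, IQR/1.34) * n^(-1/5)`) weighted by the IVW weights
#' and returns the density argmax over a grid spanning the ratio mean
#' +/- 4 sd. Consistent when the largest cluster of instruments is valid,
#' making it resistant to outlying pleiotropic variants. Standard error by
#' seeded parametric bootstrap.
#'
#' @param h a [HarmonizedInstruments-class] with at least three variants.
#' @param phi bandwidth multiplier (default 1).
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param gridSize density grid resolution (default 512).
#' @return an [MREstimate-class] with method `"weighted_mode"`.
#' @export
weightedMode <- function(h, phi = 1, nBoot = 1000L, seed = 1L,
                         gridSize = 512L) {
  d <- .hdata(h)
  if (nrow(d) < 3L) stop("weightedMode needs >= 3 instruments")
  if (phi <= 0) stop("phi must be > 0")
  rw <- .ratios(d)
  est <- .weighted_mode_point(rw$r, rw$w, phi, gridSize)
  boots <- .parametric_boot(d, nBoot, seed, function(bx, by) {
    .weighted_mode_point(by / bx, bx^2 / d$se_out^2, phi, gridSize)
  })
  .mk_est("weighted_mode", est, stats::sd(boots), nrow(d))
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the fixed-effect IVW estimator `n` times, omitting one variant
#' each time, to reveal single variants driving the pooled result.
#'
#' @param h a [HarmonizedInstruments-class] with at least three variants.
#' @return a `data.frame` with one row per omitted variant: `omitted`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pvalue`, `n_variants`.
#' @export
leaveOneOut <- function(h) {
  d <- .hdata(h)
  if (nrow(d) < 3L) stop("leaveOneOut needs >= 3 instruments")
  rows <- lapply(seq_len(nrow(d)), function(j) {
    e <- ivwFixed(d[-j, , drop = FALSE])
    data.frame(omitted = d$variant_id[j], beta = e@beta, se = e@se,
               ci_low = e@ciLow, ci_high = e@ciHigh, pvalue = e@pvalue,
               n_variants = e@nVariants, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rescale an estimate to a biomarker decrement and attach odds ratios
#'
#' Multiplies a per-ln-unit causal estimate by a decrement scale (from
#' [decrementScale()]), so the exponentiated effect reads as an odds ratio
#' per stated proportional reduction in the biomarker. The z-score, hence
#' the p-value, is unchanged.
#'
#' @param est an [MREstimate-class].
#' @param scale nonzero scale factor, e.g. `decrementScale(30)`.
#' @return an [MREstimate-class] with `beta`, `se`, CI rescaled and the
#'   odds-ratio slots populated.
#' @export
rescaleEstimate <- function(est, scale) {
  stopifnot(is(est, "MREstimate"))
  if (scale == 0) stop("scale must be nonzero")
  beta <- est@beta * scale
  se <- est@se * abs(scale)
  out <- .mk_est(est@method, beta, se, est@nVariants)
  out@or <- exp(beta)
  out@orLow <- exp(out@ciLow)
  out@orHigh <- exp(out@ciHigh)
  out
}
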