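#' Recover (beta, se) from a printed odds ratio and 95% CI
#'
#' Inverts the usual reporting transform: `beta = ln(OR)` and
#' `se = (ln(hi) - ln(lo)) / (2 * 1.959964)`. Lets printed forest-plot rows
#' be fed back into heterogeneity contrasts.
#'
#' @param orPoint point odds ratio.
#' @param ciLow,ciHigh 95% confidence limits, `0 < ciLow <= orPoint <=
#'   ciHigh`.
#' @param method method label attached to the returned estimate.
#' @return an [MREstimate-class] (with `nVariants = NA`); a zero-width CI
#'   yields `se = 0` with a warning flagging the degenerate input.
#' @export
estimateFromOrCi <- function(orPoint, ciLow, ciHigh, method = "ivw_fixed") {
  if (!(ciLow > 0 && ciLow <= orPoint && orPoint <= ciHigh))
    stop("need 0 < ciLow <= orPoint <= ciHigh")
  beta <- log(orPoint)
  se <- (log(ciHigh) - log(ciLow)) / (2 * Z95)
  if (se == 0) warning("degenerate input: zero-width CI gives se = 0")
  est <- .mk_est(method, beta, se, NA_integer_)
  est@or <- orPoint
  est@orLow <- exp(est@ciLow)
  est@orHigh <- exp(est@ciHigh)
  est
}

#' Cochran Q contrast between two causal-effect estimates
#'
#' Tests whether two estimates on the same scale (e.g. the IVW log-OR for
#' an outcome and the one for the positive control) differ by more than
#' their sampling errors allow: a fixed-effect pooled mean with weights
#' `1/se^2`, `Q = sum(w * (beta - pooled)^2)` on 1 degree of freedom.
#' Symmetric in its arguments.
#'
#' @param a,b [MREstimate-class] objects on the same scale.
#' @return a [QResult-class].
#' @export
betweenEstimateQ <- function(a, b) {
  stopifnot(is(a, "MREstimate"), is(b, "MREstimate"))
  if (a@se == 0 || b@se == 0)
    stop("degenerate estimate: se must be > 0 in both arguments")
  betas <- c(a@beta, b@beta)
  w <- 1 / c(a@se, b@se)^2
  pooled <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - pooled)^2)
  new("QResult", q = q, df = 1L,
      pvalue = stats::pchisq(q, 1L, lower.tail = FALSE))
}

.ncp_scale <- function(spec) {
  n <- spec@nCases + spec@nControls
  k <- spec@nCases / n
  sqrt(n * spec@r2Explained * k * (1 - k))
}

#' Power to detect an odds ratio per biomarker decrement
#'
#' Binary-outcome non-centrality approximation: the per-ln-unit effect is
#' `b = |ln(OR)| / |decrementScale|`, the non-centrality
#' `z = b * sqrt(N * r2 * K * (1 - K))` with `N` the total sample and `K`
#' the case fraction, and power `pnorm(z - z_{1-alpha/2})`.
#'
#' @param spec a [PowerSpec-class].
#' @param orPerDecrement odds ratio per decrement, > 0.
#' @return power in (0, 1).
#' @export
powerAtOr <- function(spec, orPerDecrement) {
  stopifnot(is(spec, "PowerSpec"))
  if (any(orPerDecrement <= 0)) stop("orPerDecrement must be > 0")
  b <- abs(log(orPerDecrement)) / abs(spec@decrementScale)
  z <- b * .ncp_scale(spec)
  stats::pnorm(z - stats::qnorm(1 - spec@alpha / 2))
}

#' Minimum detectable odds ratio at target power
#'
#' Inverts [powerAtOr()] at `targetPower`:
#' `b* = (z_{1-alpha/2} + z_{power}) / sqrt(N * r2 * K * (1 - K))`,
#' returned in the protective direction as
#' `exp(-b* * |decrementScale|)`.
#'
#' @param spec a [PowerSpec-class].
#' @return odds ratio per decrement below which the design reaches
#'   `targetPower`.
#' @export
minDetectableOr <- function(spec) {
  stopifnot(is(spec, "PowerSpec"))
  bstar <- (stats::qnorm(1 - spec@alpha / 2) +
              stats::qnorm(spec@targetPower)) / .ncp_scale(spec)
  exp(-bstar * abs(spec@decrementScale))
}
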