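test_that("Wald ratio arithmetic, null behaviour, and allele-flip invariance", {
  h <- make_h(0.1, 0.01, -0.05, 0.02)
  e <- waldRatio(h)
  expect_equal(e@beta, -0.5)
  expect_equal(e@se, 0.2)
  expect_equal(e@nVariants, 1L)
  expect_equal(e@ciLow, -0.5 - 1.959964 * 0.2)
  # null outcome effect
  e0 <- waldRatio(make_h(0.1, 0.01, 0, 0.02))
  expect_equal(e0@beta, 0)
  expect_equal(e0@pvalue, 1)
  # negating both effects (allele flip) leaves the ratio unchanged
  ef <- waldRatio(make_h(-0.1, 0.01, 0.05, 0.02))
  expect_equal(ef@beta, e@beta)
  expect_equal(ef@se, e@se)
  expect_error(waldRatio(make_h(0, 0.01, 0.1, 0.02)), "undefined")
  expect_error(waldRatio(make_h(c(1, 1), 0.01, c(1, 1), 0.02)), "ivwFixed")
})

test_that("fixed-effect IVW reproduces the hand-computed weighted mean", {
  # ratios -0.5 (se 0.2) and -0.2 (se 0.1): weights 25 and 100
  h <- make_h(c(0.1, 0.1), 0.01, c(-0.05, -0.02), c(0.02, 0.01))
  e <- ivwFixed(h)
  expect_equal(e@beta, -0.26)
  expect_equal(e@se, 1 / sqrt(125))
  expect_equal(e@nVariants, 2L)
  # all-null outcome
  e0 <- ivwFixed(make_h(c(0.1, 0.2), 0.01, c(0, 0), 0.02))
  expect_equal(e0@beta, 0)
  # one instrument duplicated: point estimate equals the Wald ratio
  hd <- make_h(c(0.1, 0.1), 0.01, c(-0.05, -0.05), 0.02)
  expect_equal(ivwFixed(hd)@beta, waldRatio(make_h(0.1, 0.01, -0.05, 0.02))@beta)
  expect_error(ivwFixed(make_h(0.1, 0.01, 0.1, 0.02)), "waldRatio")
})

test_that("IVW equals weighted least squares through the origin", {
  set.seed(7)
  for (rep in 1:25) {
    k <- sample(3:20, 1)
    bx <- rnorm(k, 0.1, 0.05); bx[bx == 0] <- 0.01
    by <- 0.3 * bx + rnorm(k, 0, 0.05)
    sey <- runif(k, 0.01, 0.1)
    h <- make_h(bx, 0.01, by, sey)
    e <- ivwFixed(h)
    fit <- lm(by ~ bx - 1, weights = 1 / sey^2)
    expect_equal(e@beta, unname(coef(fit)), tolerance = 1e-10)
    # and the fixed-effect se is (sum w)^(-1/2)
    expect_equal(e@se, 1 / sqrt(sum(bx^2 / sey^2)), tolerance = 1e-12)
  }
})

test_that("all multi-variant estimators are invariant to per-variant allele flips", {
  set.seed(11)
  bx <- rnorm(8, 0.15, 0.05); by <- 0.3 * bx + rnorm(8, 0, 0.03)
  h <- make_h(bx, 0.02, by, 0.04)
  flip <- sample(c(1, -1), 8, replace = TRUE)
  hf <- make_h(bx * flip, 0.02, by * flip, 0.04)
  expect_equal(ivwFixed(hf)@beta, ivwFixed(h)@beta)
  expect_equal(cochranQ(hf)@q, cochranQ(h)@q)
  expect_equal(weightedMedian(hf, 200, seed = 3)@beta,
               weightedMedian(h, 200, seed = 3)@beta)
  expect_equal(weightedMode(hf, nBoot = 200, seed = 3)@beta,
               weightedMode(h, nBoot = 200, seed = 3)@beta)
  expect_equal(mrEgger(hf)@slope@beta, mrEgger(h)@slope@beta)
})

test_that("Cochran Q matches hand arithmetic and the duplication identity", {
  h <- make_h(c(0.1, 0.1), 0.01, c(-0.05, -0.02), c(0.02, 0.01))
  q <- cochranQ(h)
  expect_equal(q@q, 25 * (-0.5 + 0.26)^2 + 100 * (-0.2 + 0.26)^2)
  expect_equal(q@q, 1.8)
  expect_equal(q@df, 1L)
  expect_equal(q@pvalue, pchisq(1.8, 1, lower.tail = FALSE))
  # identical ratios: q = 0, p = 1
  q0 <- cochranQ(make_h(c(0.1, 0.2), 0.01, c(0.05, 0.10), 0.02))
  expect_equal(q0@q, 0)
  expect_equal(q0@pvalue, 1)
  # duplicating every instrument doubles q; df becomes 2n - 1
  d <- as.data.frame(h)
  h2 <- make_h(rep(d$beta_exp, 2), 0.01, rep(d$beta_out, 2),
               rep(d$se_out, 2))
  q2 <- cochranQ(h2)
  expect_equal(q2@q, 2 * q@q)
  expect_equal(q2@df, 3L)
  expect_error(cochranQ(h, ivwFixed(h2)), "different instrument set")
})

test_that("MR-Egger recovers exact lines and the intercept shift property", {
  h <- make_h(c(0.1, 0.2, 0.3), 0.01, c(0.01, 0.02, 0.03), 0.05)
  eg <- mrEgger(h)
  expect_equal(eg@slope@beta, 0.1, tolerance = 1e-12)
  expect_equal(eg@intercept, 0, tolerance = 1e-12)
  # constant pleiotropy shifts the intercept, not the slope
  h2 <- make_h(c(0.1, 0.2, 0.3), 0.01, c(0.01, 0.02, 0.03) + 0.05, 0.05)
  eg2 <- mrEgger(h2)
  expect_equal(eg2@intercept, 0.05, tolerance = 1e-12)
  expect_equal(eg2@slope@beta, eg@slope@beta, tolerance = 1e-12)
  expect_error(mrEgger(make_h(c(1, 2), 0.01, c(1, 2), 0.05)), ">= 3")
})

test_that("weighted median interpolates standardized cumulative weights", {
  h <- make_h(c(1, 1, 1), 0.01, c(0.1, 0.2, 0.9), 1)
  wm <- weightedMedian(h, nBoot = 200, seed = 1)
  expect_equal(wm@beta, 0.2)  # s-midpoints 1/6, 1/2, 5/6
  # identical ratios: the common value, with a small bootstrap se
  hc <- make_h(c(1, 1, 1), 1e-4, c(0.4, 0.4, 0.4), 1e-4)
  wc <- weightedMedian(hc, nBoot = 200, seed = 1)
  expect_equal(wc@beta, 0.4)
  expect_lt(wc@se, 0.01)
  # an outlier holding 49% of the weight cannot move the estimate off the
  # majority value once the majority weight is spread over many variants
  # (weights b_exp^2/se_out^2 are set by construction: 60 valid instruments
  # with unit weight, one outlier carrying 0.49/0.51 of their total)
  bx <- c(rep(1, 60), sqrt(0.49 / 0.51 * 60))
  ho <- make_h(bx, 1e-3, c(rep(0.1, 60), 5) * bx, 1)
  wo <- weightedMedian(ho, nBoot = 200, seed = 1)
  expect_equal(wo@beta, 0.1)
  expect_warning(weightedMedian(h, nBoot = 50, seed = 1), "unstable")
  expect_error(weightedMedian(make_h(1, 1, 1, 1)), ">= 3")
})

test_that("weighted mode finds the dominant ratio cluster", {
  h <- make_h(c(1, 1, 1, 1), 0.01, c(0.10, 0.11, 0.12, 0.50), 1)
  wm <- weightedMode(h, nBoot = 200, seed = 2)
  expect_gte(wm@beta, 0.10)
  expect_lte(wm@beta, 0.12)
  # single cluster: the common ratio
  hc <- make_h(c(1, 1, 1), 1e-4, c(0.3, 0.3, 0.3), 1e-4)
  expect_equal(weightedMode(hc, nBoot = 100, seed = 2)@beta, 0.3)
  # translation equivariance: shifting every ratio by delta shifts the mode
  delta <- 0.25
  h2 <- make_h(c(1, 1, 1, 1), 0.01, c(0.10, 0.11, 0.12, 0.50) + delta, 1)
  expect_equal(weightedMode(h2, nBoot = 100, seed = 2)@beta,
               weightedMode(h, nBoot = 100, seed = 2)@beta + delta,
               tolerance = 1e-12)
  expect_error(weightedMode(h, phi = 0), "phi")
})

test_that("bootstrap standard errors are bit-identical under a fixed seed", {
  h <- make_h(c(0.1, 0.15, 0.2, 0.25), 0.02, c(0.03, 0.05, 0.06, 0.07), 0.04)
  a <- weightedMedian(h, nBoot = 300, seed = 99)
  b <- weightedMedian(h, nBoot = 300, seed = 99)
  expect_identical(a@se, b@se)
  m1 <- weightedMode(h, nBoot = 300, seed = 99)
  m2 <- weightedMode(h, nBoot = 300, seed = 99)
  expect_identical(m1@se, m2@se)
  # and the helpers leave the caller's RNG stream untouched
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(weightedMedian(h, nBoot = 100, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("leave-one-out flags a single driving variant", {
  # three identical instruments: every omission reproduces the full IVW
  h <- make_h(c(0.1, 0.1, 0.1), 0.01, c(0.05, 0.05, 0.05), 0.02)
  loo <- leaveOneOut(h)
  expect_equal(nrow(loo), 3L)
  full <- ivwFixed(h)
  expect_true(all(abs(loo$beta - full@beta) < 1e-12))
  # one gross outlier: exactly one omission moves the estimate > 2 se
  ho <- make_h(rep(0.1, 6), 0.01, c(rep(0.03, 5), 0.5), 0.02)
  loo2 <- leaveOneOut(ho)
  full2 <- ivwFixed(ho)
  moved <- abs(loo2$beta - full2@beta) > 2 * loo2$se
  expect_equal(sum(moved), 1L)
  expect_equal(loo2$omitted[moved], "rsT006")
})

test_that("decrement rescaling exponentiates correctly and preserves p", {
  est <- cisMRkit:::.mk_est("ivw_fixed", 0.661, 0.05, 26L)
  r <- rescaleEstimate(est, decrementScale(30))
  expect_equal(r@or, 0.790, tolerance = 1e-3)
  expect_equal(r@orLow, 0.763, tolerance = 1e-3)
  expect_equal(r@orHigh, 0.818, tolerance = 1e-3)
  expect_equal(r@pvalue, est@pvalue)
  expect_equal(r@se, est@se * abs(decrementScale(30)))
  # null effect maps to OR 1 under any scale
  null <- cisMRkit:::.mk_est("ivw_fixed", 0, 0.05, 26L)
  expect_equal(rescaleEstimate(null, decrementScale(18))@or, 1)
  expect_error(rescaleEstimate(est, 0), "nonzero")
})

test_that("single-instrument point formulas degenerate to the Wald ratio", {
  expect_equal(cisMRkit:::.weighted_median_point(-0.5, 25), -0.5)
  w <- cisMRkit:::.ratios(data.frame(beta_exp = 0.1, se_exp = 0.01,
                                     beta_out = -0.05, se_out = 0.02))
  expect_equal(w$r, -0.5)
  expect_equal(w$w, 25)
})
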