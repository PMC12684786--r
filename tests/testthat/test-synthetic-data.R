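test_that("genotype simulation is deterministic and respects Hardy-Weinberg", {
  cfg <- simConfig(mVariants = 5, mafRange = c(0.5, 0.5), ldRho = 0,
                   nExposure = 5000, nOutcome = 100, nCohort = 100, seed = 3)
  g1 <- simulateGenotypes(cfg, 5000)
  g2 <- simulateGenotypes(cfg, 5000)
  expect_identical(g1$dosages, g2$dosages)   # pure function of (config, seed)
  expect_true(all(g1$dosages %in% 0:2))
  # maf 0.5: mean dosage approximately 1
  expect_equal(unname(colMeans(g1$dosages)), rep(1, 5), tolerance = 0.02)
  # independent variants: realized off-diagonal r2 near zero
  off <- g1$r2[upper.tri(g1$r2)]
  expect_lt(mean(off), 0.01)
})

test_that("autoregressive LD yields elevated adjacent correlation and
           realized MAFs track the configuration", {
  cfg <- simConfig(mVariants = 8, mafRange = c(0.1, 0.5), ldRho = 0.8,
                   nExposure = 10000, nOutcome = 100, nCohort = 100,
                   seed = 5)
  g <- simulateGenotypes(cfg, 10000)
  adj <- g$r2[cbind(1:7, 2:8)]
  far <- g$r2[cbind(1:4, 5:8)]          # four steps apart
  expect_gt(mean(adj), mean(far))
  expect_gt(mean(adj), 0.1)
  realized_maf <- colMeans(g$dosages) / 2
  expect_true(all(abs(realized_maf - g$mafs) < 0.01 |
                    abs((1 - realized_maf) - g$mafs) < 0.01))
})

test_that("the exposure model has the configured residual noise and R2", {
  cfg0 <- simConfig(mVariants = 4, a = rep(0, 4), exposureSd = 0.7,
                    nExposure = 20000, nOutcome = 100, nCohort = 100,
                    seed = 9)
  g <- simulateGenotypes(cfg0, 20000)
  ex <- simulateExposure(g$dosages, cfg0)
  expect_equal(var(ex$ln_trait), 0.7^2, tolerance = 0.02)
  expect_true(all(ex$trait > 0))
  # single variant: realized R2 matches the closed form within 0.005
  cfg1 <- simConfig(mVariants = 1, mafRange = c(0.3, 0.3), a = 0.2,
                    exposureSd = 1, nExposure = 50000, nOutcome = 100,
                    nCohort = 100, seed = 10)
  g1 <- simulateGenotypes(cfg1, 50000)
  ex1 <- simulateExposure(g1$dosages, cfg1)
  r2_true <- (2 * 0.3 * 0.7 * 0.2^2) / (2 * 0.3 * 0.7 * 0.2^2 + 1)
  r2_hat <- summary(lm(ex1$ln_trait ~ g1$dosages))$r.squared
  expect_equal(r2_hat, r2_true, tolerance = 0.005 / r2_true)
})

test_that("the outcome model controls prevalence and induces case-control
           separation in the biomarker", {
  cfg <- simConfig(mVariants = 4, a = rep(0, 4), theta = 0, gamma = 0,
                   prevalenceIntercept = -1, nExposure = 100,
                   nOutcome = 50000, nCohort = 100, seed = 12)
  g <- simulateGenotypes(cfg, 50000)
  ex <- simulateExposure(g$dosages, cfg)
  y0 <- simulateOutcome(g$dosages, ex$ln_trait, cfg)
  expect_equal(mean(y0), plogis(-1), tolerance = 0.01)
  expect_identical(y0, simulateOutcome(g$dosages, ex$ln_trait, cfg))
  cfg2 <- simConfig(mVariants = 4, a = rep(0.2, 4), theta = 0.5, gamma = 0,
                    prevalenceIntercept = -1, nExposure = 100,
                    nOutcome = 50000, nCohort = 100, seed = 12)
  ex2 <- simulateExposure(g$dosages, cfg2)
  y2 <- simulateOutcome(g$dosages, ex2$ln_trait, cfg2)
  expect_gt(mean(ex2$ln_trait[y2 == 1]), mean(ex2$ln_trait[y2 == 0]))
})

test_that("association scans return calibrated, unbiased summary statistics", {
  set.seed(31)
  n <- 500
  dos <- matrix(rbinom(n * 30, 2, 0.3), n, 30)
  # null phenotype: uniform p-values, about 5% below 0.05
  ps <- unlist(lapply(1:20, function(i) {
    as.data.frame(associationScan(dos, rnorm(n), "quantitative"))$pvalue
  }))
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.6)
  expect_gt(length(ps), 550)
  # degenerate perfect fit is excluded and logged
  scan_deg <- associationScan(dos[, 1:3], 2 * dos[, 1], "quantitative")
  expect_equal(
    unname(processingLog(scan_deg)$excluded[["degenerate_or_nonconverged"]]),
    1L)
  # binary scan recovers a known per-allele log-odds at large n
  n2 <- 50000
  x <- rbinom(n2, 2, 0.3)
  y <- rbinom(n2, 1, plogis(-1 + 0.15 * x))
  scan_b <- associationScan(cbind(v1 = x), y, "binary")
  d <- as.data.frame(scan_b)
  expect_equal(d$beta, 0.15, tolerance = 0.02 / 0.15)  # bias below 2%
  expect_equal(d$eaf, mean(x) / 2)
  expect_equal(d$n, n2)
})

test_that("exposure-scan betas track the generating effects with slope ~ 1", {
  cfg <- simConfig(mVariants = 26, ldRho = 0,
                   a = seq(-0.5, 0.5, length.out = 26), nExposure = 50000,
                   nOutcome = 100, nCohort = 100, seed = 17)
  st_truth <- cisMRkit:::.resolve_truth(cfg)
  g <- simulateGenotypes(cfg, 50000)
  ex <- simulateExposure(g$dosages, cfg)
  scan <- associationScan(g$dosages, ex$ln_trait, "quantitative")
  d <- as.data.frame(scan)
  slope <- unname(coef(lm(d$beta ~ st_truth$a))[2])
  expect_equal(slope, 1, tolerance = 0.02)
})

test_that("two-sample studies carry a consistent truth and reproduce exactly", {
  cfg <- simConfig(mVariants = 6, a = rep(0.3, 6), ldRho = 0.2, theta = 0.4,
                   gamma = 0, prevalenceIntercept = -1, nExposure = 2000,
                   nOutcome = 2000, nCohort = 100, seed = 21)
  st <- makeTwoSampleStudy(cfg)
  expect_s4_class(st$exposure, "SumStatTable")
  expect_equal(traitType(st$outcome), "binary")
  expect_equal(st$truth@theta, 0.4)
  expect_length(st$truth@a, 6)
  expect_equal(dim(st$truth@r2), c(6L, 6L))
  st2 <- makeTwoSampleStudy(cfg)
  expect_identical(as.data.frame(st$exposure), as.data.frame(st2$exposure))
  expect_identical(as.data.frame(st$outcome), as.data.frame(st2$outcome))
  # the exposure and outcome samples are distinct draws
  expect_false(identical(as.data.frame(st$exposure)$beta,
                         as.data.frame(st$outcome)$beta))
})

test_that("synthetic cohorts have the documented structure", {
  cfg <- simConfig(mVariants = 5, nCohort = 3000, nExposure = 100,
                   nOutcome = 100, seed = 23)
  co <- makeCohort(cfg)
  d <- as.data.frame(co)
  expect_equal(nrow(d), 3000L)
  expect_true(all(paste0("pc", 1:10) %in% names(d)))
  expect_true(all(d$trait > 0))
  expect_equal(mean(d$age), 57.1, tolerance = 0.02)
  expect_equal(mean(d$sex), 0.542, tolerance = 0.1)
  # genotype_class mirrors the focal variant's dosage
  focal <- co@focalVariant
  expect_equal(unname(c("AA", "AC", "CC")[d[[paste0("dos_", focal)]] + 1]),
               d$genotype_class)
  co2 <- makeCohort(cfg)
  expect_identical(as.data.frame(co2), d)
})
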