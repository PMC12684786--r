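# Gene-window coordinates used for the synthetic cis region (IL6R-like
# locus on chromosome 1, GRCh37-style numbers; the region only needs to be
# internally consistent with cisRegion() defaults).
.SIM_CHROM <- "1"
.SIM_GENE_START <- 154377669
.SIM_GENE_END <- 154441926

#' Construct a SimConfig
#'
#' Defaults describe the study conditions the generator emulates: a
#' 26-variant cis instrument explaining 0.45% of the variance of a
#' log-normal biomarker with median 1.33 (ln-scale residual SD 1), an
#' exposure GWAS of 575531 individuals, a case-control outcome GWAS of
#' 1513117 individuals with case fraction ~0.6% (9219 cases), a causal
#' effect of 0.661 log-odds per ln-unit of the biomarker (the
#' positive-control magnitude: OR 0.79 per 30% biomarker decrement), no
#' pleiotropy, and a 464264-person individual-level cohort. All are
#' overridable; tests and examples use smaller samples.
#'
#' @param mVariants number of cis variants.
#' @param mafRange minor-allele-frequency range, within (0, 0.5].
#' @param ldRho adjacent-variant latent correlation (first-order
#'   autoregressive), in \[0, 1).
#' @param a per-variant ln-trait effects; `NA` (default) draws directions
#'   at random and scales them so the additive variance explained equals
#'   `r2Target`.
#' @param r2Target variance-explained fraction used when `a` is `NA`.
#' @param exposureSd residual SD of the ln-trait.
#' @param lnTraitMean mean of the ln-trait (trait median =
#'   `exp(lnTraitMean)`).
#' @param theta causal log-odds per ln-unit of the trait.
#' @param gamma per-variant direct outcome log-odds (pleiotropy; recycled
#'   to `mVariants`).
#' @param prevalenceIntercept logistic intercept for the outcome model.
#' @param nExposure,nOutcome,nCohort sample sizes.
#' @param seed integer seed.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(mVariants = 26L, mafRange = c(0.05, 0.5), ldRho = 0.3,
                      a = NA_real_, r2Target = 0.0045, exposureSd = 1,
                      lnTraitMean = log(1.33), theta = 0.661, gamma = 0,
                      prevalenceIntercept = -5.1, nExposure = 575531,
                      nOutcome = 1513117, nCohort = 464264, seed = 1L) {
  new("SimConfig", mVariants = as.integer(mVariants), mafRange = mafRange,
      ldRho = ldRho, a = as.numeric(a), r2Target = r2Target,
      exposureSd = exposureSd, lnTraitMean = lnTraitMean, theta = theta,
      gamma = as.numeric(gamma), prevalenceIntercept = prevalenceIntercept,
      nExposure = nExposure, nOutcome = nOutcome, nCohort = nCohort,
      seed = as.integer(seed))
}

# The variant-level truth is a pure function of the config: MAFs drawn
# uniformly on mafRange, effect directions standard normal, magnitudes
# scaled so the additive (independence) variance explained hits r2Target.
.resolve_truth <- function(config) {
  m <- config@mVariants
  with_seed(config@seed, {
    mafs <- stats::runif(m, config@mafRange[1], config@mafRange[2])
    a <- config@a
    if (length(a) != m || anyNA(a)) {
      raw <- stats::rnorm(m)
      g_var <- config@r2Target / (1 - config@r2Target) * config@exposureSd^2
      a <- raw * sqrt(g_var / sum(2 * mafs * (1 - mafs) * raw^2))
    }
  })
  gamma <- rep_len(config@gamma, m)
  ids <- sprintf("sv%03d", seq_len(m))
  pos <- round(seq(.SIM_GENE_START - 250000, .SIM_GENE_END + 250000,
                   length.out = m))
  list(mafs = mafs, a = a, gamma = gamma, ids = ids, pos = pos,
       chrom = .SIM_CHROM)
}

.sim_haplotype <- function(n, mafs, rho) {
  m <- length(mafs)
  e <- matrix(stats::rnorm(n * m), n, m)
  if (rho > 0 && m > 1) {
    for (j in 2:m) e[, j] <- rho * e[, j - 1] + sqrt(1 - rho^2) * e[, j]
  }
  # threshold the latent Gaussian at the MAF quantile: allele carried when
  # the latent value falls below qnorm(maf)
  sweep(e, 2, stats::qnorm(mafs), "<") + 0
}

#' Simulate genotype dosages for a cis region
#'
#' Each individual receives two haplotypes drawn from a first-order
#' autoregressive latent Gaussian (adjacent-variant correlation `ldRho`)
#' thresholded at the per-variant MAF quantiles; the dosage is the
#' haplotype sum. This yields tunable adjacent LD without a reference
#' panel.
#'
#' @param config a [SimConfig-class].
#' @param n individuals to simulate (default `config@nExposure`).
#' @param seed seed for this draw (default the config seed); the
#'   variant-level truth always comes from `config@seed`.
#' @return list with `dosages` (n x m matrix, columns named by variant),
#'   `mafs` (configured), and `r2` (realized squared-correlation matrix).
#' @export
simulateGenotypes <- function(config, n = config@nExposure,
                              seed = config@seed) {
  stopifnot(is(config, "SimConfig"))
  truth <- .resolve_truth(config)
  dos <- with_seed(seed, {
    .sim_haplotype(n, truth$mafs, config@ldRho) +
      .sim_haplotype(n, truth$mafs, config@ldRho)
  })
  colnames(dos) <- truth$ids
  sds <- apply(dos, 2, stats::sd)
  r2 <- if (all(sds > 0)) stats::cor(dos)^2 else
    matrix(NA_real_, ncol(dos), ncol(dos))
  diag(r2) <- 1
  dimnames(r2) <- list(truth$ids, truth$ids)
  list(dosages = dos, mafs = truth$mafs, r2 = r2)
}

#' Simulate the ln-scale biomarker from genotypes
#'
#' `ln_trait_i = lnTraitMean + sum_j a_j * (dos_ij - 2 * maf_j) + e_i`,
#' `e ~ N(0, exposureSd^2)`. Centering the dosages keeps
#' `exp(lnTraitMean)` the trait median, so proportional decrements read
#' directly off the ln scale. The positive-scale trait is
#' `exp(ln_trait)`.
#'
#' @param genotypes dosage matrix (individuals x variants).
#' @param config a [SimConfig-class].
#' @param seed seed for the residual draw.
#' @return data.frame with `ln_trait` and `trait` columns.
#' @export
simulateExposure <- function(genotypes, config, seed = config@seed + 1L) {
  stopifnot(is(config, "SimConfig"))
  truth <- .resolve_truth(config)
  centered <- sweep(genotypes, 2, 2 * truth$mafs, "-")
  ln_trait <- config@lnTraitMean + drop(centered %*% truth$a) +
    with_seed(seed, stats::rnorm(nrow(genotypes), 0, config@exposureSd))
  data.frame(ln_trait = ln_trait, trait = exp(ln_trait))
}

#' Simulate binary outcome labels
#'
#' `logit P(case_i) = prevalenceIntercept + theta * ln_trait_i +
#' sum_j gamma_j * dos_ij`; labels drawn independently. `gamma` encodes
#' direct (pleiotropic) variant effects that bypass the biomarker.
#'
#' @param genotypes dosage matrix.
#' @param lnTrait ln-scale biomarker vector.
#' @param config a [SimConfig-class].
#' @param seed seed for the label draw.
#' @return integer vector of 0/1 case labels.
#' @export
simulateOutcome <- function(genotypes, lnTrait, config,
                            seed = config@seed + 2L) {
  stopifnot(is(config, "SimConfig"), nrow(genotypes) == length(lnTrait))
  truth <- .resolve_truth(config)
  eta <- config@prevalenceIntercept + config@theta * lnTrait +
    drop(genotypes %*% truth$gamma)
  with_seed(seed, stats::rbinom(length(eta), 1L, stats::plogis(eta)))
}

# closed-form per-variant simple linear regression (normal-approximation
# p-values, the large-sample GWAS convention)
.scan_quantitative <- function(dos, y) {
  n <- nrow(dos)
  xc <- sweep(dos, 2, colMeans(dos), "-")
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  beta <- colSums(xc * yc) / sxx
  sse <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(sse, 0) / (n - 2) / sxx)
  list(beta = beta, se = se)
}

.scan_binary_one <- function(x, y) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial()))
  beta <- stats::coef(fit)[2]
  cov <- tryCatch(chol2inv(qr.R(fit$qr)), error = function(e) NULL)
  if (is.null(cov) || !fit$converged || abs(beta) > 10)
    return(c(NA_real_, NA_real_))
  c(beta, sqrt(diag(cov))[2])
}

#' Per-variant association scan
#'
#' Produces the summary-statistics table a GWAS would publish for the
#' simulated sample: for a quantitative phenotype, simple least-squares
#' slope, SE, and normal-approximation p per variant; for a binary
#' phenotype, logistic maximum-likelihood log-odds with Wald SE and p.
#' Effect-allele frequency and sample size are filled in. Degenerate
#' variants (zero dosage variance, a perfect fit with `se = 0`, or
#' logistic non-convergence/separation) are excluded and counted in the
#' processing log.
#'
#' @param genotypes dosage matrix with variant column names.
#' @param phenotype numeric (quantitative) or 0/1 (binary) vector.
#' @param type `"quantitative"` or `"binary"`.
#' @param traitLabel trait name for the table.
#' @param variantInfo optional data.frame with `variant_id`, `chrom`,
#'   `pos` (defaults to the column names with placeholder coordinates).
#' @return a [SumStatTable-class].
#' @export
associationScan <- function(genotypes, phenotype,
                            type = c("quantitative", "binary"),
                            traitLabel = "trait", variantInfo = NULL) {
  type <- match.arg(type)
  stopifnot(nrow(genotypes) == length(phenotype))
  m <- ncol(genotypes)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(m))
  if (is.null(variantInfo))
    variantInfo <- data.frame(variant_id = ids, chrom = .SIM_CHROM,
                              pos = seq_len(m), stringsAsFactors = FALSE)
  variantInfo <- variantInfo[match(ids, variantInfo$variant_id), ]

  poly <- apply(genotypes, 2, function(x) stats::var(x) > 0)
  res <- matrix(NA_real_, m, 2)
  if (type == "quantitative") {
    sq <- .scan_quantitative(genotypes[, poly, drop = FALSE], phenotype)
    res[poly, ] <- cbind(sq$beta, sq$se)
  } else {
    if (!all(phenotype %in% c(0, 1))) stop("binary phenotype must be 0/1")
    res[poly, ] <- t(vapply(which(poly), function(j)
      .scan_binary_one(genotypes[, j], phenotype), numeric(2)))
  }
  beta <- res[, 1]; se <- res[, 2]
  ok <- is.finite(beta) & is.finite(se) & se > 0
  log <- list(excluded = c(monomorphic = sum(!poly),
                           degenerate_or_nonconverged = sum(poly & !ok)))
  d <- data.frame(variant_id = ids, chrom = variantInfo$chrom,
                  pos = variantInfo$pos,
                  effect_allele = "C", other_allele = "A",
                  eaf = colMeans(genotypes) / 2, beta = beta, se = se,
                  pvalue = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-320),
                  n = nrow(genotypes), stringsAsFactors = FALSE)[ok, ]
  SumStatTable(d, traitLabel = traitLabel,
               traitType = type, log = log)
}

#' Simulate a complete two-sample MR study
#'
#' Draws two disjoint samples under the shared variant-level truth of the
#' config: an exposure sample scanned for variant-biomarker associations
#' (quantitative) and an outcome sample whose disease labels are generated
#' through the causal/pleiotropic logistic model and scanned with logistic
#' regression (binary). The realized truth is retained for recovery tests.
#'
#' @param config a [SimConfig-class].
#' @return list with `exposure` and `outcome` ([SumStatTable-class]) and
#'   `truth` ([SimTruth-class], realized LD from the exposure sample).
#' @export
makeTwoSampleStudy <- function(config) {
  stopifnot(is(config, "SimConfig"))
  truth <- .resolve_truth(config)
  info <- data.frame(variant_id = truth$ids, chrom = truth$chrom,
                     pos = truth$pos, stringsAsFactors = FALSE)

  gx <- simulateGenotypes(config, config@nExposure, seed = config@seed + 101L)
  expo <- simulateExposure(gx$dosages, config, seed = config@seed + 102L)
  exposure <- associationScan(gx$dosages, expo$ln_trait, "quantitative",
                              traitLabel = "ln_biomarker", variantInfo = info)

  gy <- simulateGenotypes(config, config@nOutcome, seed = config@seed + 103L)
  expo_y <- simulateExposure(gy$dosages, config, seed = config@seed + 104L)
  cases <- simulateOutcome(gy$dosages, expo_y$ln_trait, config,
                           seed = config@seed + 105L)
  outcome <- associationScan(gy$dosages, cases, "binary",
                             traitLabel = "disease", variantInfo = info)

  list(exposure = exposure, outcome = outcome,
       truth = new("SimTruth", a = truth$a, theta = config@theta,
                   gamma = truth$gamma, mafs = truth$mafs, r2 = gx$r2,
                   variantIds = truth$ids))
}

#' Simulate a biobank-style individual-level cohort
#'
#' Genotypes, the log-normal biomarker, and plausible covariates: age
#' ~ N(57.1, 8.1), sex ~ Bernoulli(0.542), ten standard-normal principal
#' components. The genotype class (AA/AC/CC, effect-allele count 0/1/2) of
#' the focal variant — the largest-|a| variant by default — is attached
#' for genotype contrasts.
#'
#' @param config a [SimConfig-class].
#' @param focal index of the focal variant (default `which.max(abs(a))`).
#' @return a [CohortTable-class] with `nCohort` rows.
#' @export
makeCohort <- function(config, focal = NULL) {
  stopifnot(is(config, "SimConfig"))
  truth <- .resolve_truth(config)
  g <- simulateGenotypes(config, config@nCohort, seed = config@seed + 201L)
  expo <- simulateExposure(g$dosages, config, seed = config@seed + 202L)
  n <- config@nCohort
  cov <- with_seed(config@seed + 203L, {
    pcs <- matrix(stats::rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("pc", 1:10)))
    data.frame(age = stats::rnorm(n, 57.1, 8.1),
               sex = stats::rbinom(n, 1, 0.542), pcs)
  })
  if (is.null(focal)) focal <- which.max(abs(truth$a))
  geno_class <- c("AA", "AC", "CC")[g$dosages[, focal] + 1]
  dos <- as.data.frame(g$dosages)
  names(dos) <- paste0("dos_", truth$ids)
  d <- cbind(dos, trait = expo$trait, ln_trait = expo$ln_trait, cov,
             genotype_class = geno_class, stringsAsFactors = FALSE)
  new("CohortTable", data = d, variantIds = truth$ids,
      focalVariant = truth$ids[focal])
}

#' Default cis region matching the synthetic locus
#'
#' The gene window the synthetic generator places its variants around;
#' convenient for exercising [selectCisVariants()] on simulated tables.
#'
#' @param flank flank in base pairs (default 300 kb).
#' @return a [CisRegion-class].
#' @export
simCisRegion <- function(flank = 3e5) {
  cisRegion(.SIM_CHROM, .SIM_GENE_START, .SIM_GENE_END, flank)
}
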