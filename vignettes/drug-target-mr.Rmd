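---
title: "Drug-target Mendelian randomization with cis instruments"
author: "cisMRkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with cis instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome using genetic variants as instrumental variables,
with exposure and outcome associations taken from non-overlapping GWAS
samples. In the *drug-target* variant of the design, the instrument is
restricted to the locus encoding the target protein: `cisMRkit` selects
variants within the gene ± a flank (default 300 kb), associated with a
downstream biomarker of target activity at genome-wide significance
(default p < 5e-8), and prunes them by greedy LD clumping (default
r² < 0.1, smallest-p variant indexed first, ties broken by variant id so
the result is order-independent). Instrument strength is summarized by the
per-variant F statistic `(beta/se)^2` and the additive variance explained
`Σ 2 f_j (1−f_j) beta_j^2 / var(trait)`; the additive sum ignores residual
correlation below the clumping threshold and is documented as an
approximation.

The motivating application is IL-6 signaling: variants near *IL6R* that
lower circulating C-reactive protein (CRP) proxy pharmacological IL-6
receptor inhibition, and their effects on cerebrovascular outcomes are
compared against atherosclerotic positive controls. Causal estimates are
reported per *proportional biomarker decrement*: a per-ln-unit log-odds
`beta` becomes `beta · ln(1 − d/100)` for a d% reduction, so
`exp(beta · ln 0.70)` is the OR per 30% CRP decrement. The scaling assumes
the exposure GWAS coefficients are in natural-log trait units; if they are
in SD units of the ln trait, rescale the decrement accordingly.

## Estimators and diagnostics

All estimators consume harmonized per-variant pairs `(b_X, se_X, b_Y,
se_Y)` expressed on the exposure's effect allele. Harmonization matches
allele pairs directly or after strand complement, negates `b_Y` (and
complements the frequency) for swapped pairs, aligns palindromic (A/T,
C/G) variants by frequency when the minor-allele frequency is below 0.42
in both studies and drops them otherwise (window 0.08 around 0.5 — the
conventional resolution; the harmonization is an involution on
non-palindromic variants), and excludes irreconcilable allele sets with a
reason code.

- *Wald ratio* `b_Y/b_X` with first-order se `se_Y/|b_X|`, for
  single-variant instruments (e.g. a missense variant).
- *Fixed-effect IVW*, the primary estimator: weights `w_j = b_X^2/se_Y^2`
  (first-order, ignoring `se_X` — the default of the MR software family
  this package follows; a documented limitation that slightly
  underestimates uncertainty for weak instruments).
- *Cochran Q* across per-variant ratios (df n−1) as a heterogeneity /
  pleiotropy metric, and a two-estimate Q (df 1) contrasting outcomes
  against a positive control. The latter is computed from decrement-scaled
  estimates but is invariant to common rescaling.
- *MR-Egger*: weighted regression of `b_Y` on `b_X` with a free intercept
  after orienting every variant so `b_X ≥ 0` (Egger is not flip-invariant;
  positive-exposure orientation is the convention). Coefficient SEs come
  from the weighted fit with the residual SD floored at 1, and p-values
  are two-sided normal.
- *Weighted median*: ratios sorted, standardized cumulative weights
  `s_j = (Σ_{i≤j} w_i − w_j/2)/Σw`, linear interpolation at `s = 0.5`;
  consistent when ≥50% of weight is valid. Note that with the
  interpolating definition, a single invalid variant holding just under
  half the weight can still displace the estimate if the valid weight is
  concentrated on few variants; the ≥50% guarantee is exact once the
  last valid variant's weight is below `2(V − 0.5)` of the total, which
  the tests exercise explicitly.
- *Weighted mode*: normal-kernel density over ratios with bandwidth
  `phi · 0.9 · min(sd, IQR/1.34) · n^{−1/5}` (phi default 1), weighted by
  the IVW weights, maximized on a 512-point grid spanning mean ± 4 sd;
  identical ratios short-circuit to the common value.
- *Leave-one-out* IVW refits, flagging single driving variants.

Bootstrap SEs (median, mode) use a seeded parametric bootstrap of
`(b_X, b_Y)` from their normal errors, 1000 replicates by default; a seed
is mandatory so results are bit-reproducible. CIs are normal-theory at
±1.959964·se and all p-values two-sided normal. At the report level a
Bonferroni threshold of 0.05 divided by the number of primary outcomes is
recomputed from the config (8 outcomes → 0.00625).

Power for binary outcomes uses the non-centrality approximation
`z = b·sqrt(N·r²·K(1−K))` (b per ln-unit, N total sample, K case
fraction), giving `power = Φ(z − z_{1−α/2})` and the inverted minimum
detectable OR `exp(−(z_{1−α/2}+z_{pow})/sqrt(N·r²·K(1−K)) · |ln(1−d)|)`.
The published thresholds this mirrors may reflect a different
exposure-unit convention, so they are treated as qualitative anchors, not
exact targets.

## Individual-level analyses

`makeCohort()`-style tables (dosages, biomarker, age, sex, 10 PCs) feed:
genetic risk scores `Σ dosage·weight`; top-vs-bottom percentile biomarker
contrasts (type-7 quantile cuts, boundary values included; percent change
of tail *medians*, since the published phrasing is ambiguous between
means and medians); genotype-class contrasts for a focal variant with
Kruskal–Wallis and Dunn pairwise z tests (tie-corrected, Holm-adjusted by
default — the correction is not specified in the source analyses, so it
is configurable); percentile-bootstrap 95% CIs from 10 000 seeded
iterations by default; and OLS variance explained of the ln biomarker
(univariable R², with an optional age/sex/PC-adjusted coefficient model).

## The synthetic generator

`simConfig()` describes a study with known truth, and every generator is
a pure function of (config, seed):

- *Genotypes*: two haplotypes per individual from a first-order
  autoregressive latent Gaussian (adjacent correlation `ldRho`)
  thresholded at per-variant MAF quantiles — tunable cis LD without a
  reference panel.
- *Exposure*: `ln_trait = lnTraitMean + Σ a_j (dos_j − 2 f_j) + ε`,
  `ε ~ N(0, exposureSd²)`; centering keeps `exp(lnTraitMean)` the trait
  median so decrement scaling reads directly off the ln scale.
- *Outcome*: `logit P(case) = intercept + θ·ln_trait + Σ γ_j dos_j`; γ
  encodes direct (pleiotropic) effects that bypass the biomarker.
- *Scans*: closed-form simple regression (quantitative) or per-variant
  logistic ML (binary), with monomorphic, perfectly-fitting (se = 0), and
  non-converged/separated variants excluded and logged. P-values use the
  large-sample normal approximation and are floored at 1e-320 to stay
  strictly positive in double precision.

Defaults mirror the study conditions the generator emulates: 26 variants,
additive variance explained 0.45% of a log-normal biomarker with median
1.33 mg/L and ln-scale residual SD 1, exposure GWAS n = 575 531,
case-control outcome n = 1 513 117 with ~0.6% case fraction, causal
effect θ = 0.661 (the positive-control magnitude, OR 0.79 per 30%
decrement), no pleiotropy, cohort n = 464 264, age ~ N(57.1, 8.1), 54.2%
female. Tests and the acceptance script scale the sample sizes down
(roughly 1000–8000 per GWAS sample for replicated calibration runs,
50 000–300 000 for single-shot recovery checks) — sizes chosen so each
check's Monte-Carlo error is small relative to its tolerance.

What the generator does *not* emulate: genome-wide background, ancestry
structure and admixture, imputation uncertainty, genotyping error, sample
overlap between exposure and outcome GWAS, case-control ascertainment
beyond an intercept shift, and covariate confounding. Passing calibration
tests therefore demonstrates the estimators' statistical behaviour under
the design's own assumptions, not robustness to these real-data
complications.

Two numerical effects are worth knowing. First, marginal per-variant
logistic effects are attenuated relative to `θ·a_j` by non-collapsibility
(≈ `1/sqrt(1 + 0.346·θ²·σ²)`, a few percent at the default θ and σ), so
pipeline estimates of θ sit slightly below the generating value — visible
in the positive-control odds ratio the acceptance script reports. Second,
IVW treats instruments as independent; simulated variants left unclumped
at `ldRho > 0` violate this and inflate the type-I error, so calibration
scenarios use `ldRho = 0` to represent the post-clumping instrument set,
while LD-aware code paths (clumping, realized r²) are tested separately.

## Design choices on open points

- Cis-window boundaries are inclusive on both ends; the genome build of
  the window is metadata the user owns (the bundled synthetic fixture
  records GRCh37-style coordinates purely for internal consistency).
- The LD matrix is an explicit input (synthetic truth or user-supplied
  panel); no reference panel is bundled.
- Missing numeric fields are written as `"NA"` and parsed from `"NA"`,
  `""`, `"."`; indels and multi-allelic records are rejected at parse
  (SNP-only instruments).
- Rows whose p-value disagrees with `2Φ(−|beta/se|)` by more than 2-fold
  are dropped at parse as internally inconsistent.
- The two-estimate heterogeneity contrast recomputed from *rounded*
  printed CIs reproduces significance for the small-vessel-stroke and
  vascular-dementia comparisons, but not for nonlobar intracerebral
  hemorrhage (p ≈ 0.15 from the rounded row) — the original analysis
  presumably used unrounded estimates, so that contrast is not treated as
  recoverable.
- Where an abstract and a results section print different CIs for the
  same estimate, the results-section values are used.

## Limitations

First-order weights ignore exposure-side uncertainty; no MR-PRESSO,
multivariable MR, or correlated-instrument generalized IVW (residual
r² < 0.1 is treated as independence). The power approximation is not a
replication of any external calculator's internals. The bundled
26-variant instrument file is synthetic: reproducing published odds
ratios requires downloading the deposited GWAS summary statistics and the
published instrument weights, then running `harmonize()` + `ivwFixed()` +
`rescaleEstimate()` exactly as the pipeline does on synthetic data.
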