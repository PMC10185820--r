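---
title: "Methods: two-sample MR for microbiome exposures"
author: "mrbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR for microbiome exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrbiome)
```

## The causal model

Two-sample Mendelian randomization treats SNPs as instrumental variables
for an exposure. For instrument $j$, let $\gamma_j$ ($\sigma_{\gamma j}$) be
its effect on the exposure (here: SD units of a rank-normalized bacterial
abundance) estimated in one GWAS, and $\Gamma_j$ ($\sigma_{\Gamma j}$) its
effect on the outcome (log-odds of disease) estimated in an independent
GWAS. Under the instrumental-variable assumptions — association with the
exposure, no association with confounders, and no effect on the outcome
except through the exposure — each Wald ratio $\beta_j = \Gamma_j/\gamma_j$
estimates the same causal effect $\theta$, and the generating model is

$$\Gamma_j = \theta\,\gamma_j + \alpha_j,$$

where $\alpha_j$ is the (ideally zero) direct, *horizontally pleiotropic*
effect of instrument $j$ on the outcome.

The estimators differ in what they assume about $\alpha_j$:

* **IVW** assumes $\alpha_j = 0$ for all $j$ and takes the
  precision-weighted mean of Wald ratios with first-order weights
  $w_j = \gamma_j^2/\sigma^2_{\Gamma j}$ — identical to the slope of the
  zero-intercept weighted regression of $\Gamma$ on $\gamma$. The
  fixed-effect SE is $(\sum_j w_j)^{-1/2}$; the multiplicative
  random-effects SE inflates it by $\sqrt{\max(1, Q/(J-1))}$, never
  deflates. Mode `auto` switches to random effects when Cochran's Q rejects
  homogeneity at 0.05.
* **MR-Egger** allows directional pleiotropy with mean
  $\mu_\alpha \ne 0$ under the InSIDE assumption (pleiotropy independent of
  instrument strength): after orienting every instrument to
  $\gamma_j > 0$, a free-intercept weighted regression estimates
  $(\mu_\alpha, \theta)$ as (intercept, slope). The intercept test is the
  package's pleiotropy diagnostic.
* **Weighted median** is consistent when instruments carrying at least half
  the total weight are valid. The estimate interpolates the weighted
  cumulative distribution $s_j - p_j/2$ of sorted ratios at $1/2$; the SE
  comes from a seeded parametric bootstrap (default 1,000 replicates)
  resampling $(\hat\gamma_j, \hat\Gamma_j)$ from their sampling normals.

P-values are two-sided standard normal throughout, matching summary-data MR
convention; with few instruments the Egger test is therefore slightly
anti-conservative, which is one reason the intercept is used as a gate
rather than a headline result.

### The two-tier significance rule

IVW is primary: p < 0.05 earns a *nominal* call. A call is upgraded to
*significant* only when (i) at least one of MR-Egger / weighted median is
direction-concordant with IVW at p < 0.05, and (ii) the sensitivity gates
are clean — Egger intercept p ≥ 0.05 and no MR-PRESSO outliers. Whether the
pleiotropy gate is applied before or after outlier correction is not fixed
by the procedure's description; the package computes both gates and applies
them together at classification time.

## Instrument processing

* **Selection threshold** (`pThreshold`): default `1e-5` (locus-wide).
  Microbiome GWAS yield too few genome-wide-significant hits per taxon to
  instrument most taxa; the locus-wide relaxation is standard in this
  literature. For a disease GWAS used as the exposure (reverse direction)
  the default is `5e-8`, since disease GWAS are well powered. The
  comparison is strictly `p < threshold`.
* **Clumping** (`clumpR2 = 0.001`, `clumpKb = 10000`): greedy — keep the
  smallest-p SNP, discard all SNPs with r² ≥ 0.001 within 10,000 kb of it,
  repeat. Ties on p break by lexicographic rsid, making the result
  invariant to input row order. LD always comes from an explicit matrix
  (real or simulated); there is no remote reference panel, which keeps the
  stage deterministic and testable offline.
* **Confounder screening**: a static exclusion-list file (one rsid per
  line, `#` comments) replaces live database queries; the criteria for
  listing a SNP are the analyst's.
* **Instrument strength**: per-SNP variance explained is
  $2\,\mathrm{eaf}(1-\mathrm{eaf})\beta^2$ for a variance-standardized
  exposure (an SE-based fallback $\beta^2/(\beta^2 + n\,\mathrm{se}^2)$
  serves when frequencies are absent); the F-statistic
  $F = R^2(n-k-1)/(k(1-R^2))$ is computed per taxon over its $k$
  instruments — the formula contains $k$ explicitly, so the per-taxon
  granularity is the natural one — and sets with $F < 10$ (strictly) are
  excluded.
* **Harmonization**: palindromic SNPs are always excluded, with no
  frequency-based rescue — with only summary data the strand of an A/T or
  C/G variant cannot be resolved reliably. Allele alignment keeps the
  outcome beta for identical orientation, negates it for swapped alleles,
  and applies the same rule after strand complement; anything else is
  rejected. Proxies (outcome-side only, r² > 0.8, argmax with lexicographic
  tie-break) transfer the proxy's own outcome beta: an r²-only LD matrix
  carries no phase, so no sign inference is attempted. Multi-allelic
  records and indels are rejected at read time; the complement logic is
  defined on SNVs only.

## Sensitivity diagnostics

* **Cochran's Q** about the fixed-effect IVW estimate, $\chi^2_{J-1}$
  upper-tail p.
* **MR-PRESSO**: observed residual sum of squares
  $\mathrm{RSS} = \sum_j \sigma_{\Gamma j}^{-2}(\Gamma_j -
  \hat\beta_{(-j)}\gamma_j)^2$ with leave-one-out IVW estimates
  $\hat\beta_{(-j)}$; the null distribution is simulated parametrically
  (default 1,000 draws), per-SNP terms give outlier p-values flagged below
  the Bonferroni-adjusted 0.05/J, and a distortion p compares the estimate
  shift after outlier removal against removal of random subsets of the same
  size. Empirical p-values use the add-one rule, so the smallest attainable
  value is $1/(n_{sim}+1)$. Per-SNP simulation streams are seeded by
  hashing each rsid with the master seed, making every result invariant to
  instrument order.
* **Leave-one-out** IVW with Cook's distance from the zero-intercept
  weighted regression; the flagging threshold is 0.5 (a fixed, widely used
  convention), configurable.

## Multivariable Bayesian model averaging

With $K$ candidate exposures sharing instruments, the union design is
$y = X\theta + \alpha + \varepsilon$ over the $J$ union SNPs, rows weighted
by $1/\sigma_{\Gamma j}$; a SNP selected for one taxon but not another
contributes a zero entry (counted and logged). All $2^K - 1$ non-empty
subsets are enumerated (exhaustive only; the intended $K$ is small), with
independent-inclusion prior $p^{|S|}(1-p)^{K-|S|}$, default
$p = 0.25$ — one of four candidates expected causal.

**Prior on effects and scale invariance.** The marginal likelihood of each
subset is the closed-form normal evidence with a shrinkage prior on
coefficients. A fixed prior scale on raw weighted-regression coefficients
would make posterior probabilities depend on the units of $y$; the package
therefore normalizes design columns to unit norm and sets the prior SD to
`priorSd` × the weighted-response norm (a unit-information-style prior:
`priorSd` is the fraction of the outcome signal one exposure is expected to
explain, default 0.5). Posterior probabilities are then invariant to a
joint rescaling of outcome effects and SEs, estimates scale linearly, and
as `priorSd` → 0 the posterior collapses to the model prior. Coefficients
are reported on the original scale.

Reported per exposure: MIP (sum of PPs of containing models, ranked
descending with |MACE| as tie-break), MACE (PP-weighted average estimate,
zero where excluded), the best containing model's PP and the estimate in
it, and a permutation p-value — the outcome rows are permuted (y jointly
with its SEs) `nPerm = 100` times and the MIP recomputed, so with the
add-one rule every attainable p is a multiple of 1/101.

**Outlier iteration.** For every model with PP ≥ `ppThreshold` (0.02), the
per-SNP statistic $q_j = ((y_j - \hat y_j)/\sigma_{y j})^2$ flags SNPs with
$q_j > 10$. Cook's distance is evaluated in the *top* model only: in a
barely-qualifying, misspecified model (a weak singleton at PP ≈ 0.03),
high-leverage points routinely exceed any reasonable cutoff even on clean
data — such "influence" reflects that model's misfit, not a deviant
instrument — and including it would make the iteration's clean-data
fixpoint unattainable. The default Cook's cutoff is the median of the
F(|S|, J−|S|) distribution, with a fixed-value override for
reproducible tests. Flagged SNPs are removed and the analysis repeated
until no flags remain or fewer than $3K$ SNPs would survive.

## The synthetic-data generator

The generator emulates the study conditions end to end: exposure GWAS of
n = 18,340 with rank-normalized abundances, outcome GWAS of 538 cases /
341,961 controls, MAF ~ U(0.05, 0.5), and per-instrument variance explained
r² ~ U(0.0015, 0.004) — true association z-scores of about 5–9 at that
sample size, i.e. the strength range of instruments that survive locus-wide
selection with little attrition. Standard errors follow
$\sigma_\gamma = (2p(1-p)n)^{-1/2}$ for the standardized quantitative
exposure and the standard case-control log-odds approximation
$\sigma_\Gamma^2 = (1/n_{case} + 1/n_{control}) / (2p(1-p))$, which at
these scales yields per-taxon IVW standard errors around 0.2–0.4 — the
width regime of the motivating application's reported intervals. The
end-to-end fixture plants four taxa (log-odds 1.244, −0.785, 0, 0; 16
instruments each) plus ten genuine disease loci that are null for every
taxon, so the reverse direction has instruments and a known (absent)
reverse effect.

Pleiotropy modes: `balanced` adds $\alpha_j \sim N(0, \tau)$ (default
$\tau = 0.05$, roughly half the outcome SE scale — moderate, realistic
contamination); `directional` adds $N(\mu_\alpha, \tau)$ *on the
exposure-increasing allele orientation* — directional pleiotropy is only
meaningful relative to an orientation, and this is the orientation MR-Egger
fits in; `inside_violating` correlates $\alpha_j$ with instrument strength
(r = 0.8), the scenario in which Egger's assumptions fail.

What the generator does **not** emulate: LD between instruments and truly
causal variants (instruments are the causal variants), winner's-curse bias
from selecting and estimating in the same sample, sample overlap between
exposure and outcome GWAS, population stratification, and non-normal
effect-size distributions. Passing tests therefore certify the estimators
and pipeline logic under the stated sampling model, not robustness to
those real-data pathologies.

## Numerical and design choices

* 95% CIs use the conventional 1.96 multiplier (matching published tables),
  and `OR = exp(beta)` exactly; reports round effects to 3 decimals and
  p-values to 3 significant figures.
* Empirical p-values (PRESSO, permutations) use $(r+1)/(n+1)$ and can never
  be zero.
* Generated p-values are floored at $10^{-300}$ so extreme z-scores never
  underflow to an invalid zero.
* Cook's distances from numerically perfect fits (residual variance at
  floating-point noise) are defined as zero rather than 0/0.
* Weighted-median interpolation returns a dominant (> 50%-weight)
  instrument's ratio exactly only when its bracket is symmetric; this is a
  property of the standard interpolation rule, not an implementation
  choice.
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; per-SNP and per-taxon streams are derived by hashing
  identifiers with the master seed, so results are independent of row and
  list order.
* Test and acceptance problem sizes — 1,000 replicates for IVW calibration
  and coverage, 500 × 500 for PRESSO calibration, 200 for BMA ranking
  recovery, 100 end-to-end runs — were chosen as the smallest sizes at
  which the Monte-Carlo error is comfortably below the property margins
  being checked.

## Known limitations

* The Egger intercept's normal p is anti-conservative for very small J.
* The MR-PRESSO distortion test's random-subset null is a pragmatic
  stand-in; its calibration is not separately validated.
* Proxy substitution transfers the proxy's outcome effect without phase
  information; with r² near the 0.8 threshold this can attenuate or flip a
  single instrument's contribution (the drop log records every proxy).
* Exhaustive BMA enumeration caps K at 20; no stochastic model search is
  provided.
* The package analyses summary statistics only; individual-level QC,
  imputation and liftover are out of scope.
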