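#' @include AllClasses.R harmonize.R
NULL

#' Wald ratio estimate for a single instrument
#'
#' `beta = Gamma / gamma` with first-order standard error
#' `se = se_Gamma / |gamma|`; the corresponding IVW weight is `1 / se^2 =
#' gamma^2 / se_Gamma^2`.
#'
#' @param gamma SNP-exposure effect (nonzero).
#' @param Gamma SNP-outcome effect.
#' @param seGamma SE of `Gamma`.
#' @return an [MrEstimate-class] with method `"wald"`.
#' @export
waldRatio <- function(gamma, Gamma, seGamma) {
  stopifnot(length(gamma) == 1)
  if (gamma == 0) stopf("gamma = 0: Wald ratio undefined")
  MrEstimate("wald", beta = Gamma / gamma, se = seGamma / abs(gamma),
             nSnps = 1L)
}

waldComponents <- function(set) {
  ins <- instruments(set)
  list(ratio = ins$Gamma / ins$gamma,
       w = ins$gamma^2 / ins$se_Gamma^2)
}

#' Inverse-variance weighted causal estimate
#'
#' Precision-weighted mean of per-SNP Wald ratios, `w_j = gamma_j^2 /
#' se_Gamma_j^2` (first-order weights); equivalently the slope of the
#' zero-intercept weighted regression of `Gamma` on `gamma` with weights
#' `1/se_Gamma^2`. The fixed-effect SE is `(sum w)^-1/2`; the multiplicative
#' random-effects SE inflates it by `sqrt(max(1, Q/(J-1)))` with `Q`
#' Cochran's heterogeneity statistic. Mode `"auto"` uses random effects iff
#' the Q test rejects at 0.05. With a single instrument the estimate
#' degenerates to the Wald ratio.
#'
#' @param set a [HarmonizedSet-class].
#' @param mode `"auto"`, `"fixed"`, or `"random"`.
#' @return an [MrEstimate-class] (`ivw_fixed` or `ivw_random`); `extra`
#'   carries `Q`, `df` and `qPval`.
#' @export
mrIvw <- function(set, mode = c("auto", "fixed", "random")) {
  mode <- match.arg(mode)
  wc <- waldComponents(set)
  J <- length(wc$ratio)
  if (J < 1) stopf("no instruments")
  beta <- sum(wc$w * wc$ratio) / sum(wc$w)
  se_fixed <- 1 / sqrt(sum(wc$w))
  if (J == 1) {
    est <- MrEstimate("ivw_fixed", beta, se_fixed, 1L,
                      extra = list(Q = 0, df = 0, qPval = 1))
    return(est)
  }
  Q <- sum(wc$w * (wc$ratio - beta)^2)
  df <- J - 1
  q_p <- pchisq(Q, df, lower.tail = FALSE)
  random <- switch(mode, fixed = FALSE, random = TRUE, auto = q_p < 0.05)
  se <- if (random) se_fixed * sqrt(max(1, Q / df)) else se_fixed
  MrEstimate(if (random) "ivw_random" else "ivw_fixed", beta, se, J,
             extra = list(Q = Q, df = df, qPval = q_p))
}

eggerFit <- function(set) {
  ins <- instruments(set)
  if (nrow(ins) < 3) stopf("MR-Egger requires >= 3 instruments")
  # orient every instrument to positive exposure effect
  flip <- sign(ins$gamma)
  flip[flip == 0] <- 1
  g <- ins$gamma * flip
  G <- ins$Gamma * flip
  w <- 1 / ins$se_Gamma^2
  fit <- lm(G ~ g, weights = w)
  s <- summary(fit)
  sigma <- s$sigma
  # model-based SEs with multiplicative overdispersion floored at 1
  scale <- max(1, sigma) / sigma
  co <- s$coefficients
  list(fit = fit,
       intercept = co[1, 1], se_intercept = co[1, 2] * scale,
       slope = co[2, 1], se_slope = co[2, 2] * scale,
       nSnps = nrow(ins))
}

#' MR-Egger regression estimate
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept (weights `1/se_Gamma^2`), after orienting all instruments
#' to a positive exposure effect. The slope is the pleiotropy-robust causal
#' estimate; a nonzero intercept indicates directional pleiotropy. SEs use
#' multiplicative overdispersion floored at 1; p-values are two-sided normal.
#'
#' @param set a [HarmonizedSet-class] with >= 3 instruments.
#' @return an [MrEstimate-class] with method `"egger"`; `extra` carries
#'   `intercept`, `seIntercept` and `interceptPval`.
#' @export
mrEgger <- function(set) {
  f <- eggerFit(set)
  MrEstimate("egger", f$slope, f$se_slope, f$nSnps,
             extra = list(intercept = f$intercept,
                          seIntercept = f$se_intercept,
                          interceptPval = 2 * pnorm(-abs(f$intercept) /
                                                      f$se_intercept)))
}

weightedMedianPoint <- function(ratio, w) {
  ord <- order(ratio)
  b <- ratio[ord]
  p <- w[ord] / sum(w)
  s <- cumsum(p)
  H <- s - p / 2
  if (H[1] >= 0.5) return(b[1])
  if (H[length(H)] <= 0.5) return(b[length(b)])
  k <- max(which(H < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - H[k]) / (H[k + 1] - H[k])
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios (consistent when
#' instruments carrying at least half the total weight are valid), computed
#' by linear interpolation of the cumulative weight function `s_j - p_j/2` at
#' 0.5. The SE comes from a seeded parametric bootstrap: each `(gamma_j,
#' Gamma_j)` is resampled from its normal sampling distribution and the
#' median recomputed.
#'
#' @param set a [HarmonizedSet-class] with >= 3 instruments.
#' @param nBoot bootstrap replicate count.
#' @param seed RNG seed for the bootstrap.
#' @return an [MrEstimate-class] with method `"weighted_median"`.
#' @export
mrWeightedMedian <- function(set, nBoot = 1000, seed = 1L) {
  ins <- instruments(set)
  if (nrow(ins) < 3) stopf("weighted median requires >= 3 instruments")
  wc <- waldComponents(set)
  beta <- weightedMedianPoint(wc$ratio, wc$w)
  J <- nrow(ins)
  boots <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      g <- rnorm(J, ins$gamma, ins$se_gamma)
      G <- rnorm(J, ins$Gamma, ins$se_Gamma)
      weightedMedianPoint(G / g, g^2 / ins$se_Gamma^2)
    }, numeric(1))
  })
  MrEstimate("weighted_median", beta, stats::sd(boots), J,
             extra = list(nBoot = nBoot, seed = seed))
}

#' Two-sided Wald p-value reconstructed from an OR confidence interval
#'
#' Reporting-consistency utility: from 95% CI bounds on the odds-ratio scale,
#' the point estimate is the geometric-mean log `b = (ln lo + ln hi)/2`, the
#' SE is `(ln hi - ln lo)/(2 * 1.96)`, and `p = 2 * Phi(-|b|/se)`.
#'
#' @param ciLo,ciHi 95% CI bounds, `0 < ciLo < ciHi`.
#' @return list with `beta`, `se`, `pval`, `orValue`.
#' @export
waldPFromCi <- function(ciLo, ciHi) {
  stopifnot(all(ciLo > 0), all(ciLo < ciHi))
  b <- (log(ciLo) + log(ciHi)) / 2
  se <- (log(ciHi) - log(ciLo)) / (2 * 1.96)
  list(beta = b, se = se, pval = 2 * pnorm(-abs(b) / se), orValue = exp(b))
}

#' Classify the strength of a causal finding
#'
#' The primary IVW p-value below 0.05 earns `nominal` significance; the call
#' is upgraded to `significant` when at least one additional estimator
#' (MR-Egger or weighted median) is direction-concordant with IVW at p < 0.05
#' AND the sensitivity diagnostics are clean (Egger intercept p >= 0.05, no
#' MR-PRESSO outliers).
#'
#' @param ivwEst IVW [MrEstimate-class].
#' @param additional list of additional [MrEstimate-class] objects (Egger,
#'   weighted median).
#' @param sensitivity optional sensitivity report as returned by
#'   [sensitivityReport()]; when `NULL` the sensitivity gate is treated as
#'   clean.
#' @return list with `level` (`"none"`, `"nominal"`, `"significant"`) and
#'   `rationale`.
#' @export
classifySignificance <- function(ivwEst, additional = list(),
                                 sensitivity = NULL) {
  rationale <- character()
  if (pvalue(ivwEst) >= 0.05)
    return(list(level = "none", rationale = sprintf("IVW p = %.3g >= 0.05",
                                                    pvalue(ivwEst))))
  rationale <- sprintf("IVW p = %.3g < 0.05", pvalue(ivwEst))
  support <- vapply(additional, function(e)
    pvalue(e) < 0.05 && sign(e@beta) == sign(ivwEst@beta), logical(1))
  clean <- TRUE
  if (!is.null(sensitivity)) {
    if (!is.null(sensitivity$eggerIntercept) &&
        sensitivity$eggerIntercept$pval < 0.05) {
      clean <- FALSE
      rationale <- c(rationale, "Egger intercept p < 0.05")
    }
    if (!is.null(sensitivity$presso) &&
        length(sensitivity$presso$outliers)) {
      clean <- FALSE
      rationale <- c(rationale, "MR-PRESSO outliers present")
    }
  }
  if (any(support) && clean) {
    rationale <- c(rationale, sprintf(
      "supported by %d additional direction-concordant method(s)",
      sum(support)))
    list(level = "significant", rationale = rationale)
  } else {
    if (!any(support))
      rationale <- c(rationale, "no additional method support")
    list(level = "nominal", rationale = rationale)
  }
}
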