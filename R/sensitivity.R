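#' @include estimators.R
NULL

# Cook's distances with a guard for (numerically) perfect fits, where the
# residual variance is floating-point noise and the ratio is meaningless.
safeCooksDistance <- function(fit) {
  cd <- unname(cooks.distance(fit))
  s <- suppressWarnings(summary(fit)$sigma)  # perfect fits warn harmlessly
  ref <- mean(abs(fitted(fit))) + mean(abs(residuals(fit)))
  if (!is.finite(s) || s <= 1e-8 * max(ref, .Machine$double.eps))
    cd[] <- 0
  cd[!is.finite(cd)] <- 0
  cd
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (ratio_j - beta_IVW)^2` about the fixed-effect IVW estimate,
#' with the IVW weights; `p` is the upper tail of chi-square with `J - 1`
#' degrees of freedom. Large Q signals heterogeneous per-SNP causal
#' estimates, e.g. from pleiotropy.
#'
#' @param set a [HarmonizedSet-class] with >= 2 instruments.
#' @return list with `Q`, `df`, `pval`.
#' @export
cochranQ <- function(set) {
  wc <- waldComponents(set)
  J <- length(wc$ratio)
  if (J < 2) stopf("Cochran's Q requires >= 2 instruments")
  beta <- sum(wc$w * wc$ratio) / sum(wc$w)
  Q <- sum(wc$w * (wc$ratio - beta)^2)
  list(Q = Q, df = J - 1, pval = pchisq(Q, J - 1, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Returns the intercept of the MR-Egger fit with its SE and two-sided normal
#' p-value; pleiotropy is conventionally declared at p < 0.05.
#'
#' @param set a [HarmonizedSet-class] with >= 3 instruments.
#' @return list with `intercept`, `se`, `pval`.
#' @export
eggerInterceptTest <- function(set) {
  f <- eggerFit(set)
  list(intercept = f$intercept, se = f$se_intercept,
       pval = 2 * pnorm(-abs(f$intercept) / f$se_intercept))
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Simulation-based residual-sum-of-squares test for horizontal pleiotropy.
#' The observed RSS is `sum_j w_j (Gamma_j - beta(-j) * gamma_j)^2` with
#' `w_j = 1/se_Gamma_j^2` and `beta(-j)` the leave-one-out IVW estimate. The
#' null distribution is built by parametric simulation (`gamma* ~ N(gamma,
#' se_gamma)`, `Gamma* ~ N(beta(-j) * gamma, se_Gamma)`), recomputing the RSS
#' each time. Empirical p-values use the add-one rule, so the smallest
#' attainable p is `1/(nSim + 1)`. Per-SNP outlier p-values are computed on
#' each term and flagged below the Bonferroni-adjusted `sigLevel / J`. When
#' outliers are found, a distortion p compares the IVW shift after their
#' removal against removal of random subsets of the same size.
#'
#' Per-SNP simulation streams are seeded by hashing each rsid together with
#' the master seed, so results do not depend on instrument order.
#'
#' @param set a [HarmonizedSet-class] with >= 4 instruments.
#' @param nSim simulation count for the null distribution.
#' @param sigLevel per-SNP significance level before Bonferroni adjustment.
#' @param seed master RNG seed.
#' @return list with `globalPval`, `outliers` (rsids), `outlierPvals` (named,
#'   all SNPs), `distortionPval` (`NA` when no outliers), `rssObs`, `nSim`,
#'   `seed`.
#' @export
mrPresso <- function(set, nSim = 1000, sigLevel = 0.05, seed = 1L) {
  ins <- instruments(set)
  J <- nrow(ins)
  if (J < 4) stopf("MR-PRESSO requires >= 4 instruments")
  ins <- ins[order(ins$rsid), , drop = FALSE]
  w_res <- 1 / ins$se_Gamma^2
  wv <- ins$gamma^2 / ins$se_Gamma^2
  ratio <- ins$Gamma / ins$gamma
  Sw <- sum(wv); Swb <- sum(wv * ratio)
  beta_loo <- (Swb - wv * ratio) / (Sw - wv)
  t_obs <- w_res * (ins$Gamma - beta_loo * ins$gamma)^2
  rss_obs <- sum(t_obs)

  # per-SNP streams keyed by rsid
  g_star <- matrix(0, J, nSim)
  G_star <- matrix(0, J, nSim)
  for (j in seq_len(J)) {
    draws <- withSeed(snpStreamSeed(seed, ins$rsid[j]),
                      rnorm(2 * nSim))
    g_star[j, ] <- ins$gamma[j] + ins$se_gamma[j] * draws[seq_len(nSim)]
    G_star[j, ] <- beta_loo[j] * ins$gamma[j] +
      ins$se_Gamma[j] * draws[nSim + seq_len(nSim)]
  }
  ratio_star <- G_star / g_star
  wv_star <- g_star^2 / ins$se_Gamma^2
  Sw_s <- colSums(wv_star)
  Swb_s <- colSums(wv_star * ratio_star)
  beta_loo_star <- sweep(-wv_star * ratio_star, 2, Swb_s, "+") /
    sweep(-wv_star, 2, Sw_s, "+")
  t_star <- w_res * (G_star - beta_loo_star * g_star)^2
  rss_star <- colSums(t_star)

  global_p <- (1 + sum(rss_star >= rss_obs)) / (nSim + 1)
  p_snp <- (1 + rowSums(t_star >= t_obs)) / (nSim + 1)
  names(p_snp) <- ins$rsid
  outliers <- ins$rsid[p_snp < sigLevel / J]

  distortion_p <- NA_real_
  if (length(outliers) && length(outliers) < J - 1) {
    keep <- !ins$rsid %in% outliers
    beta_all <- Swb / Sw
    beta_noout <- sum(wv[keep] * ratio[keep]) / sum(wv[keep])
    d_obs <- beta_all - beta_noout
    n_out <- length(outliers)
    d_null <- withSeed(seed + 1L, vapply(seq_len(nSim), function(b) {
      drop <- sample.int(J, n_out)
      beta_all - sum(wv[-drop] * ratio[-drop]) / sum(wv[-drop])
    }, numeric(1)))
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (nSim + 1)
  }
  list(globalPval = global_p, outliers = outliers, outlierPvals = p_snp,
       distortionPval = distortion_p, rssObs = rss_obs, nSim = nSim,
       seed = seed)
}

#' Leave-one-out IVW analysis with Cook's distance
#'
#' For each instrument, the fixed-effect IVW estimate and SE on the remaining
#' `J - 1` instruments, together with the instrument's Cook's distance from
#' the zero-intercept weighted regression of `Gamma` on `gamma` (weights
#' `1/se_Gamma^2`). Instruments whose distance exceeds `cooksThreshold`
#' (default 0.5) are flagged as influential.
#'
#' @param set a [HarmonizedSet-class] with >= 3 instruments.
#' @param cooksThreshold flagging threshold for Cook's distance.
#' @return list with `table` (`data.frame`: rsid, beta, se, pval, cooksD,
#'   flagged) and `flags` (flagged rsids).
#' @export
leaveOneOut <- function(set, cooksThreshold = 0.5) {
  ins <- instruments(set)
  J <- nrow(ins)
  if (J < 3) stopf("leave-one-out requires >= 3 instruments")
  wv <- ins$gamma^2 / ins$se_Gamma^2
  ratio <- ins$Gamma / ins$gamma
  Sw <- sum(wv); Swb <- sum(wv * ratio)
  beta_loo <- (Swb - wv * ratio) / (Sw - wv)
  se_loo <- 1 / sqrt(Sw - wv)
  fit <- lm(Gamma ~ gamma - 1, data = ins, weights = 1 / ins$se_Gamma^2)
  cd <- safeCooksDistance(fit)
  tab <- data.frame(rsid = ins$rsid, beta = beta_loo, se = se_loo,
                    pval = 2 * pnorm(-abs(beta_loo) / se_loo),
                    cooksD = cd, flagged = cd > cooksThreshold,
                    stringsAsFactors = FALSE)
  list(table = tab, flags = tab$rsid[tab$flagged])
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Bundles Cochran's Q, the Egger intercept test, MR-PRESSO and leave-one-out
#' diagnostics (each run only when the instrument count permits it).
#'
#' @param set a [HarmonizedSet-class].
#' @param nSim MR-PRESSO simulation count.
#' @param cooksThreshold leave-one-out Cook's distance threshold.
#' @param seed RNG seed for MR-PRESSO.
#' @return list with components `heterogeneity`, `eggerIntercept`, `presso`,
#'   `loo` (absent components are `NULL`) plus `exposure`/`outcome` labels.
#' @export
sensitivityReport <- function(set, nSim = 1000, cooksThreshold = 0.5,
                              seed = 1L) {
  J <- nInstruments(set)
  list(exposure = set@exposure, outcome = set@outcome,
       heterogeneity = if (J >= 2) cochranQ(set) else NULL,
       eggerIntercept = if (J >= 3) eggerInterceptTest(set) else NULL,
       presso = if (J >= 4) mrPresso(set, nSim = nSim, seed = seed) else NULL,
       loo = if (J >= 3) leaveOneOut(set, cooksThreshold) else NULL)
}
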