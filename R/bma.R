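#' @include AllClasses.R harmonize.R
NULL

#' Configuration for multivariable MR Bayesian model averaging
#'
#' @param priorInclusion prior probability that any one exposure is causal
#'   (default 0.25, i.e. one of four candidates expected causal).
#' @param priorSd shrinkage prior scale on standardized causal effects,
#'   expressed relative to the weighted outcome signal (a unit-norm-design
#'   coefficient of one response-norm explains the whole signal); default
#'   0.5.
#' @param ppThreshold posterior-probability cut-off defining the "best"
#'   models used for per-SNP diagnostics (default 0.02).
#' @param qThreshold per-SNP Q-statistic outlier flag (default 10).
#' @param cooksRule Cook's distance threshold policy: `"f_median"` uses the
#'   median of the F distribution with (model size, J - model size) degrees
#'   of freedom; a numeric value fixes the threshold.
#' @param nPerm permutation count for empirical p-values (default 100; with
#'   the add-one rule every attainable p is a multiple of 1/101).
#' @param seed RNG seed for permutations.
#' @return a `bma_config` list.
#' @export
bmaConfig <- function(priorInclusion = 0.25, priorSd = 0.5,
                      ppThreshold = 0.02, qThreshold = 10,
                      cooksRule = "f_median", nPerm = 100, seed = 1L) {
  stopifnot(priorInclusion > 0, priorInclusion < 1,
            priorSd > 0, ppThreshold > 0, ppThreshold < 1,
            qThreshold > 0, nPerm >= 1)
  structure(list(priorInclusion = priorInclusion, priorSd = priorSd,
                 ppThreshold = ppThreshold, qThreshold = qThreshold,
                 cooksRule = cooksRule, nPerm = nPerm, seed = seed),
            class = "bma_config")
}

#' Assemble the multivariable exposure matrix
#'
#' Takes the union of instruments across harmonized exposure sets (all
#' harmonized to the same outcome); each SNP's exposure effects fill a row of
#' `X`, with entries set to 0 (and counted) where an instrument was selected
#' for one exposure but carries no selected effect for another. Outcome
#' effects and SEs come from the harmonized sets themselves.
#'
#' @param sets named list of [HarmonizedSet-class], one per exposure, sharing
#'   the outcome.
#' @return list with `snpIds`, `X` (J x K), `y`, `seY`, `exposures`,
#'   `nZeroFilled`.
#' @export
buildExposureMatrix <- function(sets) {
  stopifnot(length(sets) >= 2)
  exposures <- names(sets) %||% vapply(sets, function(s) s@exposure,
                                       character(1))
  all_ids <- sort(unique(unlist(lapply(sets, function(s)
    instruments(s)$rsid))))
  if (!length(all_ids)) stopf("empty instrument union")
  J <- length(all_ids); K <- length(sets)
  X <- matrix(0, J, K, dimnames = list(all_ids, exposures))
  y <- rep(NA_real_, J); se_y <- rep(NA_real_, J)
  for (k in seq_len(K)) {
    ins <- instruments(sets[[k]])
    idx <- match(ins$rsid, all_ids)
    X[idx, k] <- ins$gamma
    y[idx] <- ins$Gamma
    se_y[idx] <- ins$se_Gamma
  }
  if (any(is.na(y))) stopf("outcome effect missing for some union SNPs")
  list(snpIds = all_ids, X = X, y = y, seY = se_y, exposures = exposures,
       nZeroFilled = sum(X == 0))
}

#' Enumerate candidate exposure subsets with prior probabilities
#'
#' All non-empty subsets of the K exposures (exhaustive; K <= 20), with
#' prior `prior(S) ~ p^|S| (1-p)^(K-|S|)` normalized over the enumerated
#' space.
#'
#' @param K exposure count.
#' @param config a [bmaConfig()].
#' @return list with `subsets` (list of integer vectors) and `prior`.
#' @export
enumerateModels <- function(K, config = bmaConfig()) {
  if (K > 20) stopf("exhaustive enumeration limited to K <= 20")
  stopifnot(K >= 1)
  subsets <- list()
  for (m in seq_len(2^K - 1))
    subsets[[m]] <- which(bitwAnd(m, 2^(seq_len(K) - 1)) > 0)
  sz <- lengths(subsets)
  p <- config$priorInclusion
  prior <- p^sz * (1 - p)^(K - sz)
  list(subsets = subsets, prior = prior / sum(prior))
}

# Log marginal likelihood and posterior-mean coefficients of the
# zero-intercept model y_tilde ~ N(Xn_S theta, I) with theta ~ N(0, sd^2 I),
# on rows already standardized by 1/se_y and columns scaled to unit norm
# (norms in `colNorm`); coefficients are mapped back to the unnormalized
# scale. `priorSd` here is the effective scale (config scale times the
# weighted response norm), so posterior probabilities are invariant to a
# joint rescaling of y and se_y. Closed form via the Woodbury identity:
# log|I + sd^2 Xn Xn'| = log|I_p + sd^2 Xn'Xn|.
modelEvidence <- function(Xn, yt, subset, priorSd, colNorm) {
  Xs <- Xn[, subset, drop = FALSE]
  p <- ncol(Xs)
  A <- crossprod(Xs)
  B <- A + diag(p) / priorSd^2
  cb <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(cb)) stopf("singular design for subset {%s}",
                         paste(subset, collapse = ","))
  Xty <- crossprod(Xs, yt)
  z <- backsolve(cb, forwardsolve(t(cb), Xty))
  quad <- sum(yt^2) - sum(Xty * z)
  logdet <- 2 * sum(log(diag(cb))) + p * log(priorSd^2)
  logml <- -0.5 * (length(yt) * log(2 * pi) + logdet + quad)
  list(logml = logml, coef = drop(z) / colNorm[subset])
}

#' Posterior over exposure subsets
#'
#' Fits every enumerated model on the weighted data (rows scaled by
#' `1/se_y`, design columns scaled to unit norm so that posterior
#' probabilities are invariant to a joint rescaling of outcome effects and
#' SEs), computing each subset's closed-form marginal likelihood under the
#' normal shrinkage prior and combining with the subset prior; posterior
#' probabilities are normalized to sum to 1. Coefficients are reported on
#' the original (unnormalized) scale.
#'
#' @param mat exposure matrix from [buildExposureMatrix()].
#' @param config a [bmaConfig()].
#' @return `data.frame` with `model` (comma-joined exposure indices), `size`,
#'   `pp`, plus a list-column-free companion list `coefs` attached as an
#'   attribute (per-model posterior-mean coefficients).
#' @export
modelPosteriors <- function(mat, config = bmaConfig()) {
  K <- ncol(mat$X)
  en <- enumerateModels(K, config)
  Xt <- mat$X / mat$seY
  yt <- mat$y / mat$seY
  colNorm <- sqrt(colSums(Xt^2))
  colNorm[colNorm == 0] <- 1
  Xn <- sweep(Xt, 2, colNorm, "/")
  # prior scale on the unit-norm design, proportional to the weighted
  # response norm (unit-information style): a coefficient of magnitude
  # ||yt|| explains the whole signal, so priorSd is the expected fraction
  sdEff <- config$priorSd * max(sqrt(sum(yt^2)), .Machine$double.eps)
  fits <- lapply(en$subsets, modelEvidence, Xn = Xn, yt = yt,
                 priorSd = sdEff, colNorm = colNorm)
  logml <- vapply(fits, `[[`, numeric(1), "logml")
  logpost <- log(en$prior) + logml
  pp <- exp(logpost - max(logpost))
  pp <- pp / sum(pp)
  out <- data.frame(
    model = vapply(en$subsets, paste, character(1), collapse = ","),
    size = lengths(en$subsets), pp = pp, stringsAsFactors = FALSE)
  attr(out, "subsets") <- en$subsets
  attr(out, "coefs") <- lapply(fits, `[[`, "coef")
  out
}

#' Marginal inclusion probabilities and model-averaged causal effects
#'
#' `MIP_k` is the sum of posterior probabilities of every model containing
#' exposure k; `MACE_k` is the PP-weighted average of k's causal estimate
#' across models (0 where k is excluded). Exposures are ranked by descending
#' MIP (ties broken by descending |MACE|) and by descending best-model PP.
#' The reported `causalEstimate` is the estimate of k in the
#' highest-posterior model containing k.
#'
#' @param models result of [modelPosteriors()].
#' @param exposures exposure labels.
#' @return per-exposure `data.frame` with `exposure`, `mip`, `rankByMip`,
#'   `mace`, `bestModelPp`, `rankByPp`, `causalEstimate`.
#' @export
mipMace <- function(models, exposures) {
  subsets <- attr(models, "subsets")
  coefs <- attr(models, "coefs")
  K <- length(exposures)
  mip <- numeric(K); mace <- numeric(K)
  best_pp <- numeric(K); causal <- numeric(K)
  for (k in seq_len(K)) {
    has <- vapply(subsets, function(s) k %in% s, logical(1))
    mip[k] <- sum(models$pp[has])
    est_k <- vapply(which(has), function(m)
      coefs[[m]][match(k, subsets[[m]])], numeric(1))
    mace[k] <- sum(models$pp[has] * est_k)
    top <- which(has)[which.max(models$pp[has])]
    best_pp[k] <- models$pp[top]
    causal[k] <- coefs[[top]][match(k, subsets[[top]])]
  }
  ord <- order(-mip, -abs(mace))
  rank_mip <- match(seq_len(K), ord)
  rank_pp <- match(seq_len(K), order(-best_pp, -abs(causal)))
  data.frame(exposure = exposures, mip = mip, rankByMip = rank_mip,
             mace = mace, bestModelPp = best_pp, rankByPp = rank_pp,
             causalEstimate = causal, stringsAsFactors = FALSE)
}

cooksCutoff <- function(rule, p, J) {
  if (is.numeric(rule)) return(rule)
  qf(0.5, p, max(J - p, 1))
}

#' Per-SNP outlier diagnostics for the best BMA models
#'
#' For each model with `pp >= ppThreshold`: the per-SNP heterogeneity
#' statistic `q_j = ((y_j - yhat_j)/se_y_j)^2` from the model's
#' (shrinkage-)fitted values. Cook's distance comes from the weighted
#' least-squares fit of the top model only: influence is meaningful in a
#' model that already fits, whereas apparent influence in a low-probability
#' model reflects that model's misspecification rather than a deviant
#' instrument. A SNP is an outlier if `q_j > qThreshold` in any best model
#' or its top-model Cook's distance exceeds the configured rule.
#'
#' @param mat exposure matrix from [buildExposureMatrix()].
#' @param models result of [modelPosteriors()].
#' @param config a [bmaConfig()].
#' @return list with `table` (`data.frame`: rsid, maxQ, maxCooksD, outlier)
#'   and `outliers` (rsids).
#' @export
snpDiagnostics <- function(mat, models, config = bmaConfig()) {
  subsets <- attr(models, "subsets")
  coefs <- attr(models, "coefs")
  best <- which(models$pp >= config$ppThreshold)
  if (!length(best)) best <- which.max(models$pp)
  Xt <- mat$X / mat$seY
  yt <- mat$y / mat$seY
  J <- length(yt)
  maxQ <- rep(0, J); maxCd <- rep(0, J)
  for (m in best) {
    S <- subsets[[m]]
    yhat <- drop(Xt[, S, drop = FALSE] %*% coefs[[m]])
    maxQ <- pmax(maxQ, (yt - yhat)^2)
  }
  topS <- subsets[[best[which.max(models$pp[best])]]]
  fit <- lm(yt ~ Xt[, topS, drop = FALSE] - 1)
  cut <- cooksCutoff(config$cooksRule, length(topS), J)
  maxCd <- safeCooksDistance(fit) / cut  # stored relative to the cutoff
  outlier <- maxQ > config$qThreshold | maxCd > 1
  list(table = data.frame(rsid = mat$snpIds, maxQ = maxQ,
                          cooksRatio = maxCd, outlier = outlier,
                          stringsAsFactors = FALSE),
       outliers = mat$snpIds[outlier])
}

#' Permutation p-values for marginal inclusion probabilities
#'
#' Permutes the outcome vector (jointly with its SEs) across SNPs `nPerm`
#' times and recomputes each exposure's MIP; the empirical p uses the
#' add-one rule `p = (1 + #{MIP_perm >= MIP_obs})/(nPerm + 1)`, so every
#' attainable p is a multiple of `1/(nPerm + 1)`.
#'
#' @param mat exposure matrix from [buildExposureMatrix()].
#' @param mipObs observed per-exposure MIPs.
#' @param config a [bmaConfig()].
#' @return numeric vector of per-exposure permutation p-values.
#' @export
permutationPvalues <- function(mat, mipObs, config = bmaConfig()) {
  K <- ncol(mat$X)
  J <- length(mat$y)
  exceed <- rep(0, K)
  withSeed(config$seed, {
    for (b in seq_len(config$nPerm)) {
      perm <- sample.int(J)
      pm <- list(X = mat$X, y = mat$y[perm], seY = mat$seY[perm],
                 snpIds = mat$snpIds, exposures = mat$exposures)
      mods <- modelPosteriors(pm, config)
      subsets <- attr(mods, "subsets")
      mip_b <- vapply(seq_len(K), function(k)
        sum(mods$pp[vapply(subsets, function(s) k %in% s, logical(1))]),
        numeric(1))
      exceed <- exceed + (mip_b >= mipObs)
    }
  })
  (1 + exceed) / (config$nPerm + 1)
}

#' One round of multivariable MR Bayesian model averaging
#'
#' Enumerates models, computes posterior probabilities, MIP/MACE summaries
#' and permutation p-values for one exposure matrix.
#'
#' @param mat exposure matrix from [buildExposureMatrix()].
#' @param config a [bmaConfig()].
#' @param permutations compute permutation p-values (set `FALSE` to skip the
#'   expensive step inside loops).
#' @return list with `summary` (per-exposure `data.frame` incl. `permPval`),
#'   `models`, `diagnostics`.
#' @export
mrBma <- function(mat, config = bmaConfig(), permutations = TRUE) {
  models <- modelPosteriors(mat, config)
  summ <- mipMace(models, mat$exposures)
  summ$permPval <- if (permutations)
    permutationPvalues(mat, summ$mip, config) else NA_real_
  diag <- snpDiagnostics(mat, models, config)
  list(summary = summ, models = models, diagnostics = diag)
}

#' Iterative BMA with outlier removal
#'
#' Repeats fit -> per-SNP diagnosis -> removal of flagged SNPs -> refit,
#' until no SNP is flagged or fewer than `3 * K` SNPs would remain. Each
#' iteration's summary and the rsids removed before it are recorded.
#'
#' @param mat exposure matrix from [buildExposureMatrix()].
#' @param config a [bmaConfig()].
#' @return a [BmaResult-class].
#' @export
runBmaIterative <- function(mat, config = bmaConfig()) {
  iterations <- list(); excluded <- list()
  removed_now <- character()
  cur <- mat
  repeat {
    res <- mrBma(cur, config)
    iterations[[length(iterations) + 1]] <- res$summary
    excluded[[length(excluded) + 1]] <- removed_now
    out <- res$diagnostics$outliers
    if (!length(out)) break
    keep <- !cur$snpIds %in% out
    if (sum(keep) < 3 * ncol(cur$X)) {
      warnf("stopping outlier removal: only %d SNPs would remain", sum(keep))
      break
    }
    removed_now <- out
    cur <- list(snpIds = cur$snpIds[keep],
                X = cur$X[keep, , drop = FALSE],
                y = cur$y[keep], seY = cur$seY[keep],
                exposures = cur$exposures,
                nZeroFilled = sum(cur$X[keep, ] == 0))
  }
  new("BmaResult", summary = iterations[[length(iterations)]],
      models = res$models, iterations = iterations, excluded = excluded)
}
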