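#' @include AllClasses.R
NULL

#' Instrument-selection configuration
#'
#' Thresholds governing instrument selection and strength filtering. Defaults
#' follow common microbiome-MR practice: the locus-wide significance threshold
#' `1e-5` (the genome-wide `5e-8` is appropriate for well-powered disease
#' GWAS used as exposures in the reverse direction), clumping at r-squared
#' 0.001 within a 10,000 kb window, proxies requiring r-squared > 0.8, and
#' exclusion of instrument sets with F below 10.
#'
#' @param pThreshold p-value cut-off for instrument selection (strict `<`).
#' @param clumpR2 LD pruning r-squared threshold.
#' @param clumpKb clumping distance window in kilobases.
#' @param proxyR2 minimum LD r-squared for a proxy substitute (strict `>`).
#' @param fMin minimum per-taxon F-statistic; sets with `F < fMin` are dropped.
#' @param exclusionList character vector of rsids tied to confounders.
#' @return a `selection_config` list.
#' @export
selectionConfig <- function(pThreshold = 1e-5, clumpR2 = 0.001,
                            clumpKb = 10000, proxyR2 = 0.8, fMin = 10,
                            exclusionList = character()) {
  stopifnot(pThreshold > 0, pThreshold < 1,
            clumpR2 >= 0, clumpR2 <= 1, clumpKb > 0,
            proxyR2 > 0, proxyR2 <= 1, fMin >= 0)
  structure(list(pThreshold = pThreshold, clumpR2 = clumpR2,
                 clumpKb = clumpKb, proxyR2 = proxyR2, fMin = fMin,
                 exclusionList = exclusionList),
            class = "selection_config")
}

newAttrition <- function() {
  data.frame(stage = character(), n_in = integer(), n_out = integer(),
             reason = character(), stringsAsFactors = FALSE)
}

addAttrition <- function(log, stage, n_in, n_out, reason) {
  rbind(log, data.frame(stage = stage, n_in = as.integer(n_in),
                        n_out = as.integer(n_out), reason = reason,
                        stringsAsFactors = FALSE))
}

#' Select candidate instruments by association p-value
#'
#' Retains exactly the records with `pval < pThreshold` (strict inequality).
#' An empty result is not an error: a warning is raised and an empty dataset
#' returned.
#'
#' @param dataset an exposure [GwasDataset-class].
#' @param config a [selectionConfig()].
#' @return the filtered [GwasDataset-class].
#' @export
selectByPvalue <- function(dataset, config = selectionConfig()) {
  stopifnot(is(dataset, "GwasDataset"))
  s <- snps(dataset)
  keep <- s$pval < config$pThreshold
  if (!any(keep))
    warnf("no SNP passes p < %g for trait '%s'", config$pThreshold,
          trait(dataset))
  GwasDataset(s[keep, , drop = FALSE], trait = trait(dataset),
              role = role(dataset))
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the remaining SNP with the smallest p-value and discards
#' all others with r-squared >= `clumpR2` to it that lie within `clumpKb`
#' kilobases of its position (all such SNPs when positions are unavailable).
#' The result is pairwise r-squared < `clumpR2` within windows. Candidates
#' absent from the LD matrix are dropped with a logged reason. Ties on
#' p-value are broken by lexicographic rsid order, so the output does not
#' depend on input row order.
#'
#' @param candidates a [GwasDataset-class] of selected candidates.
#' @param ld an [LdMatrix-class] covering the candidates.
#' @param config a [selectionConfig()].
#' @return the clumped [GwasDataset-class]; dropped SNPs are recorded in the
#'   `rejected` slot with reasons `absent from LD matrix` or
#'   `clumped (r2 >= threshold)`.
#' @export
clumpInstruments <- function(candidates, ld, config = selectionConfig()) {
  stopifnot(is(candidates, "GwasDataset"), is(ld, "LdMatrix"))
  s <- snps(candidates)
  r2 <- ldr2(ld)
  in_ld <- s$rsid %in% rownames(r2)
  rejected <- data.frame(rsid = s$rsid[!in_ld],
                         reason = rep("absent from LD matrix", sum(!in_ld)),
                         stringsAsFactors = FALSE)
  s <- s[in_ld, , drop = FALSE]
  # canonical order: ascending p, rsid breaks ties
  s <- s[order(s$pval, s$rsid), , drop = FALSE]
  pos <- setNames(s$pos, s$rsid)
  chrom <- setNames(s$chrom, s$rsid)
  have_pos <- !any(is.na(pos))
  remaining <- s$rsid
  kept <- character()
  while (length(remaining)) {
    lead <- remaining[1]
    kept <- c(kept, lead)
    others <- remaining[-1]
    if (length(others)) {
      linked <- r2[lead, others] >= config$clumpR2
      if (have_pos) {
        within <- chrom[others] == chrom[lead] &
          abs(pos[others] - pos[lead]) <= config$clumpKb * 1000
        linked <- linked & within
      }
      if (any(linked))
        rejected <- rbind(rejected, data.frame(
          rsid = others[linked], reason = "clumped (r2 >= threshold)",
          stringsAsFactors = FALSE))
      remaining <- others[!linked]
    } else remaining <- character()
  }
  out <- snps(candidates)
  out <- out[out$rsid %in% kept, , drop = FALSE]
  GwasDataset(out, trait = trait(candidates), role = role(candidates),
              rejected = rejected)
}

#' Remove SNPs tied to confounders
#'
#' Drops records whose rsid appears in the configured exclusion list (the
#' offline stand-in for confounder-database screening); each removal is
#' recorded in the `rejected` slot.
#'
#' @param dataset a [GwasDataset-class].
#' @param config a [selectionConfig()].
#' @return the filtered [GwasDataset-class].
#' @export
excludeConfounderSnps <- function(dataset, config = selectionConfig()) {
  stopifnot(is(dataset, "GwasDataset"))
  s <- snps(dataset)
  drop <- s$rsid %in% config$exclusionList
  rejected <- data.frame(rsid = s$rsid[drop],
                         reason = rep("confounder-associated", sum(drop)),
                         stringsAsFactors = FALSE)
  GwasDataset(s[!drop, , drop = FALSE], trait = trait(dataset),
              role = role(dataset), rejected = rejected)
}

#' Per-SNP exposure variance explained
#'
#' For a variance-standardized exposure, the variance explained by one SNP is
#' `2 * eaf * (1 - eaf) * beta^2`. When `eaf` is missing an error directs the
#' caller to the SE-based fallback [snpR2Fallback()].
#'
#' @param beta per-allele effect estimate(s).
#' @param eaf effect-allele frequency(ies).
#' @return non-negative variance explained, vectorized.
#' @export
snpR2 <- function(beta, eaf) {
  if (any(is.na(eaf)))
    stopf("eaf missing; use snpR2Fallback(beta, se, n) instead")
  stopifnot(all(eaf > 0 & eaf < 1))
  2 * eaf * (1 - eaf) * beta^2
}

#' SE-based fallback for per-SNP variance explained
#'
#' `beta^2 / (beta^2 + n * se^2)`, usable when allele frequencies are absent.
#'
#' @param beta per-allele effect estimate(s).
#' @param se standard error(s).
#' @param n exposure GWAS sample size(s).
#' @return variance explained in `[0, 1)`, vectorized.
#' @export
snpR2Fallback <- function(beta, se, n) {
  stopifnot(all(se > 0), all(n > 0))
  beta^2 / (beta^2 + n * se^2)
}

#' Instrument-strength F-statistic
#'
#' `F = R2 * (n - k - 1) / (k * (1 - R2))` with `R2` the total exposure
#' variance explained by the `k` selected instruments and `n` the exposure
#' GWAS sample size.
#'
#' @param r2Total summed variance explained, in `[0, 1)`.
#' @param n exposure sample size; must exceed `k + 1`.
#' @param k instrument count.
#' @return the F-statistic.
#' @export
fStatistic <- function(r2Total, n, k) {
  stopifnot(r2Total >= 0, r2Total < 1, k >= 1)
  if (n <= k + 1) stopf("sample size n = %g must exceed k + 1 = %g", n, k + 1)
  r2Total * (n - k - 1) / (k * (1 - r2Total))
}

#' Instrument strength for a selected exposure dataset
#'
#' Sums per-SNP variance explained (frequency-based where `eaf` is present,
#' SE-based otherwise) and computes the per-taxon F-statistic.
#'
#' @param dataset a selected exposure [GwasDataset-class] with >= 1 SNP.
#' @return list with `r2Total`, `n` (median SNP sample size), `k`, `fStat`.
#' @export
instrumentStrength <- function(dataset) {
  s <- snps(dataset)
  if (!nrow(s)) stopf("no instruments for trait '%s'", trait(dataset))
  r2 <- ifelse(is.na(s$eaf),
               snpR2Fallback(s$beta, s$se, s$n),
               2 * s$eaf * (1 - s$eaf) * s$beta^2)
  r2_total <- min(sum(r2), 1 - 1e-12)
  n <- stats::median(s$n)
  k <- nrow(s)
  list(r2Total = r2_total, n = n, k = k,
       fStat = fStatistic(r2_total, n, k))
}

#' Drop exposures with weak instrument sets
#'
#' Removes from a list of selected exposure datasets every taxon whose
#' per-taxon F-statistic is below `fMin` (strictly); the decision is returned
#' alongside the retained list.
#'
#' @param exposureSets named list of [GwasDataset-class] objects.
#' @param config a [selectionConfig()].
#' @return list with `kept` (filtered list) and `decisions` (`data.frame`
#'   with trait, k, fStat, kept).
#' @export
filterWeak <- function(exposureSets, config = selectionConfig()) {
  strengths <- lapply(exposureSets, instrumentStrength)
  f <- vapply(strengths, `[[`, numeric(1), "fStat")
  k <- vapply(strengths, `[[`, numeric(1), "k")
  kept <- f >= config$fMin
  decisions <- data.frame(trait = names(exposureSets) %||%
                            vapply(exposureSets, trait, character(1)),
                          k = k, fStat = f, kept = kept,
                          stringsAsFactors = FALSE)
  list(kept = exposureSets[kept], decisions = decisions)
}
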