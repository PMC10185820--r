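#' @include AllClasses.R instruments.R
NULL

complementAllele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

#' Is an allele pair palindromic?
#'
#' A SNP is palindromic when its two alleles are strand complements of each
#' other ({A,T} or {C,G}), making strand orientation ambiguous in summary
#' data; such SNPs are excluded during harmonization.
#'
#' @param a1,a2 allele characters (A/C/G/T), vectorized.
#' @return logical vector.
#' @export
isPalindromic <- function(a1, a2) {
  if (!all(c(a1, a2) %in% validAlleles)) stopf("invalid allele")
  a2 == complementAllele(a1)
}

#' Align one outcome record to an exposure record's effect allele
#'
#' Matches the outcome alleles to the exposure's: identical orientation keeps
#' the outcome beta; swapped alleles negate it; if a match appears only after
#' complementing the outcome alleles (opposite strand), the same rule applies
#' after complementing. Incompatible allele sets are rejected. Palindromic
#' pairs must have been excluded upstream (strand cannot be resolved).
#'
#' @param expRec,outRec single-row canonical SNP records (as in [snps()])
#'   sharing an rsid.
#' @return a one-row harmonized instrument `data.frame`, or `NULL` when the
#'   allele sets are incompatible.
#' @export
alignAlleles <- function(expRec, outRec) {
  stopifnot(expRec$rsid == outRec$rsid)
  if (isPalindromic(expRec$effect_allele, expRec$other_allele) ||
      isPalindromic(outRec$effect_allele, outRec$other_allele))
    stopf("palindromic pair reached alignAlleles; exclude upstream")
  e1 <- expRec$effect_allele; e2 <- expRec$other_allele
  o1 <- outRec$effect_allele; o2 <- outRec$other_allele
  flip <- NA  # FALSE: same orientation; TRUE: swapped
  if (o1 == e1 && o2 == e2) flip <- FALSE
  else if (o1 == e2 && o2 == e1) flip <- TRUE
  else {
    c1 <- complementAllele(o1); c2 <- complementAllele(o2)
    if (c1 == e1 && c2 == e2) flip <- FALSE
    else if (c1 == e2 && c2 == e1) flip <- TRUE
  }
  if (is.na(flip)) return(NULL)
  data.frame(rsid = expRec$rsid,
             effect_allele = e1, other_allele = e2,
             gamma = expRec$beta, se_gamma = expRec$se,
             Gamma = if (flip) -outRec$beta else outRec$beta,
             se_Gamma = outRec$se,
             eaf = expRec$eaf,
             is_proxy = FALSE, proxy_source = NA_character_,
             stringsAsFactors = FALSE)
}

#' Find an LD proxy for an instrument absent from the outcome GWAS
#'
#' Returns the outcome-present SNP with maximal r-squared to `rsid`, provided
#' that r-squared strictly exceeds `proxyR2`; ties are broken by
#' lexicographic rsid order. Returns `NA` when no qualifying proxy exists or
#' the SNP is absent from the LD matrix.
#'
#' @param rsid the missing instrument's id.
#' @param outcome outcome [GwasDataset-class].
#' @param ld an [LdMatrix-class].
#' @param config a [selectionConfig()].
#' @return proxy rsid or `NA_character_`.
#' @export
findProxy <- function(rsid, outcome, ld, config = selectionConfig()) {
  r2 <- ldr2(ld)
  if (!rsid %in% rownames(r2)) return(NA_character_)
  cand <- intersect(rownames(r2), snps(outcome)$rsid)
  cand <- setdiff(cand, rsid)
  if (!length(cand)) return(NA_character_)
  vals <- r2[rsid, cand]
  cand <- cand[vals > config$proxyR2]
  vals <- vals[vals > config$proxyR2]
  if (!length(cand)) return(NA_character_)
  ord <- order(-vals, cand)
  cand[ord][1]
}

#' Harmonize an exposure's instruments against an outcome GWAS
#'
#' For each selected instrument: substitute an LD proxy when the SNP is
#' missing from the outcome GWAS, exclude palindromic SNPs, and align alleles
#' so that the exposure and outcome effects refer to the same effect allele.
#' Every dropped SNP is logged with a stage and reason. Harmonization is
#' idempotent: an already-aligned pair passes through unchanged.
#'
#' @param exposure selected/clumped exposure [GwasDataset-class].
#' @param outcome outcome [GwasDataset-class].
#' @param ld an [LdMatrix-class] (used only for proxy search; may be empty).
#' @param config a [selectionConfig()].
#' @return a [HarmonizedSet-class].
#' @export
harmonize <- function(exposure, outcome, ld = LdMatrix(matrix(numeric(0), 0, 0)),
                      config = selectionConfig()) {
  stopifnot(is(exposure, "GwasDataset"), is(outcome, "GwasDataset"))
  es <- snps(exposure)
  os <- snps(outcome)
  drops <- emptyLog(c("rsid", "stage", "reason"))
  note <- function(rsid, stage, reason)
    drops <<- rbind(drops, data.frame(rsid = rsid, stage = stage,
                                      reason = reason, stringsAsFactors = FALSE))
  rows <- vector("list", nrow(es))
  used_proxies <- character()
  for (i in seq_len(nrow(es))) {
    erec <- es[i, ]
    target <- erec$rsid
    proxied <- FALSE
    if (!target %in% os$rsid) {
      proxy <- findProxy(target, outcome, ld, config)
      if (is.na(proxy) || proxy %in% used_proxies || proxy %in% es$rsid) {
        note(target, "proxy", "absent from outcome; no usable proxy")
        next
      }
      proxied <- TRUE
      used_proxies <- c(used_proxies, proxy)
      orec <- os[os$rsid == proxy, ]
    } else orec <- os[os$rsid == target, ]
    if (isPalindromic(erec$effect_allele, erec$other_allele)) {
      note(target, "palindrome", "palindromic")
      next
    }
    if (isPalindromic(orec$effect_allele, orec$other_allele)) {
      note(target, "palindrome", "palindromic outcome record")
      next
    }
    if (proxied) {
      # the proxy's own outcome record is used; its alleles must still align
      # with *its* exposure-side record if present, otherwise alignment is to
      # the proxy record's orientation with effects taken as reported
      aligned <- data.frame(rsid = orec$rsid,
                            effect_allele = orec$effect_allele,
                            other_allele = orec$other_allele,
                            gamma = erec$beta, se_gamma = erec$se,
                            Gamma = orec$beta, se_Gamma = orec$se,
                            eaf = erec$eaf, is_proxy = TRUE,
                            proxy_source = target, stringsAsFactors = FALSE)
    } else {
      erow <- erec
      aligned <- alignAlleles(erow, orec)
      if (is.null(aligned)) {
        note(target, "align", "incompatible alleles")
        next
      }
    }
    rows[[i]] <- aligned
  }
  ins <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(ins) || !nrow(ins))
    stopf("no usable instruments for %s -> %s", trait(exposure), trait(outcome))
  HarmonizedSet(exposure = trait(exposure), outcome = trait(outcome),
                instruments = ins, dropLog = drops)
}
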