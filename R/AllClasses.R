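#' @include utils.R
NULL

canonicalColumns <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                      "beta", "se", "pval", "eaf", "n")

validAlleles <- c("A", "C", "G", "T")

emptySnpTable <- function() {
  data.frame(rsid = character(), chrom = character(), pos = integer(),
             effect_allele = character(), other_allele = character(),
             beta = numeric(), se = numeric(), pval = numeric(),
             eaf = numeric(), n = numeric(), stringsAsFactors = FALSE)
}

emptyLog <- function(cols) {
  as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                stringsAsFactors = FALSE)
}

#' GWAS summary-statistic dataset
#'
#' One trait's SNP association summaries: per SNP the effect and other allele,
#' the per-effect-allele beta (log-odds for a binary trait, SD units for an
#' abundance trait), its standard error, p-value, effect-allele frequency and
#' sample size. The `role` records whether the trait is used as an exposure
#' or as the outcome of a Mendelian-randomization analysis.
#'
#' @slot trait trait label, e.g. a bacterial taxon name or a disease name.
#' @slot role `"exposure"` or `"outcome"`.
#' @slot snps `data.frame` with the canonical columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval`, `eaf`, `n`.
#'   `eaf` may be `NA` (missing frequency); all other fields are required.
#' @slot rejected per-row rejection log (`rsid`, `reason`) from validation at
#'   read time.
#'
#' @seealso [GwasDataset()], [readSummaryTsv()], [snps()]
#' @export
setClass("GwasDataset",
  representation(trait = "character", role = "character",
                 snps = "data.frame", rejected = "data.frame"),
  prototype(trait = NA_character_, role = "exposure",
            snps = emptySnpTable(), rejected = emptyLog(c("rsid", "reason"))))

setValidity("GwasDataset", function(object) {
  msgs <- character()
  if (length(object@role) != 1 || !object@role %in% c("exposure", "outcome"))
    msgs <- c(msgs, "role must be 'exposure' or 'outcome'")
  s <- object@snps
  missing_cols <- setdiff(canonicalColumns, names(s))
  if (length(missing_cols))
    return(paste("missing snp columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(s$rsid))
    msgs <- c(msgs, "duplicate rsids in dataset")
  if (nrow(s)) {
    if (!all(s$effect_allele %in% validAlleles) ||
        !all(s$other_allele %in% validAlleles))
      msgs <- c(msgs, "alleles must be single upper-case nucleotides")
    if (any(s$effect_allele == s$other_allele))
      msgs <- c(msgs, "effect and other allele must differ")
    if (any(!is.finite(s$se) | s$se <= 0))
      msgs <- c(msgs, "se must be > 0")
    if (any(!is.finite(s$pval) | s$pval <= 0 | s$pval > 1))
      msgs <- c(msgs, "pval must lie in (0, 1]")
    eaf <- s$eaf[!is.na(s$eaf)]
    if (any(eaf <= 0 | eaf >= 1))
      msgs <- c(msgs, "eaf must lie in (0, 1) when present")
    if (any(!is.finite(s$n) | s$n <= 0))
      msgs <- c(msgs, "n must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GwasDataset
#'
#' @param snps canonical SNP table (see [GwasDataset-class]); missing optional
#'   columns `eaf`/`n` are filled with `NA`.
#' @param trait trait label.
#' @param role `"exposure"` or `"outcome"`.
#' @param rejected optional rejection log.
#' @return a validated [GwasDataset-class].
#' @export
GwasDataset <- function(snps, trait, role = c("exposure", "outcome"),
                        rejected = emptyLog(c("rsid", "reason"))) {
  role <- match.arg(role)
  if (!"eaf" %in% names(snps)) snps$eaf <- NA_real_
  if (!"n" %in% names(snps)) snps$n <- NA_real_
  snps <- snps[, canonicalColumns, drop = FALSE]
  rownames(snps) <- NULL
  new("GwasDataset", trait = trait, role = role, snps = snps,
      rejected = rejected)
}

#' Pairwise LD matrix
#'
#' Square matrix of pairwise r-squared values over a set of SNPs, used for
#' clumping and proxy search. Optionally carries per-SNP positions so that
#' clumping can honour a physical distance window.
#'
#' @slot r2 symmetric numeric matrix, unit diagonal, entries in `[0, 1]`,
#'   dimnames = SNP ids.
#' @slot positions `data.frame` (`rsid`, `chrom`, `pos`); zero rows when
#'   positions are unknown.
#' @seealso [LdMatrix()], [readLdMatrix()], [clumpInstruments()]
#' @export
setClass("LdMatrix",
  representation(r2 = "matrix", positions = "data.frame"),
  prototype(r2 = matrix(numeric(), 0, 0),
            positions = data.frame(rsid = character(), chrom = character(),
                                   pos = integer(), stringsAsFactors = FALSE)))

setValidity("LdMatrix", function(object) {
  m <- object@r2
  if (nrow(m) != ncol(m)) return("r2 matrix must be square")
  if (nrow(m)) {
    if (is.null(rownames(m)) || is.null(colnames(m)) ||
        !identical(rownames(m), colnames(m)))
      return("r2 matrix must have identical row/column SNP ids")
    if (anyDuplicated(rownames(m))) return("duplicate SNP ids")
    if (any(!is.finite(m) | m < 0 | m > 1))
      return("r2 entries must lie in [0, 1]")
    if (max(abs(m - t(m))) > 1e-8) return("r2 matrix must be symmetric")
    if (max(abs(diag(m) - 1)) > 1e-8) return("r2 diagonal must equal 1")
  }
  TRUE
})

#' Construct an LdMatrix
#'
#' @param r2 square symmetric matrix with SNP ids as dimnames.
#' @param positions optional `data.frame` with `rsid`, `chrom`, `pos`.
#' @return a validated [LdMatrix-class].
#' @export
LdMatrix <- function(r2, positions = NULL) {
  r2 <- (r2 + t(r2)) / 2   # absorb asymmetries below validity tolerance
  diag(r2) <- 1
  if (is.null(positions))
    positions <- data.frame(rsid = character(), chrom = character(),
                            pos = integer(), stringsAsFactors = FALSE)
  new("LdMatrix", r2 = r2, positions = positions)
}

#' Harmonized instrument set for one exposure-outcome pair
#'
#' Instruments with exposure effect `gamma` (SE `se_gamma`) and outcome effect
#' `Gamma` (SE `se_Gamma`) aligned to a shared effect allele; palindromic SNPs
#' are excluded and proxy substitutions are flagged. The drop log records every
#' SNP removed during harmonization with a stage and reason.
#'
#' @slot exposure exposure trait label.
#' @slot outcome outcome trait label.
#' @slot instruments `data.frame` with columns `rsid`, `effect_allele`,
#'   `other_allele`, `gamma`, `se_gamma`, `Gamma`, `se_Gamma`, `eaf`,
#'   `is_proxy`, `proxy_source`.
#' @slot dropLog `data.frame` (`rsid`, `stage`, `reason`).
#' @seealso [harmonize()], [mrIvw()], [instruments()]
#' @export
setClass("HarmonizedSet",
  representation(exposure = "character", outcome = "character",
                 instruments = "data.frame", dropLog = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  ins <- object@instruments
  need <- c("rsid", "effect_allele", "other_allele", "gamma", "se_gamma",
            "Gamma", "se_Gamma", "is_proxy", "proxy_source")
  missing_cols <- setdiff(need, names(ins))
  if (length(missing_cols))
    return(paste("missing instrument columns:",
                 paste(missing_cols, collapse = ", ")))
  msgs <- character()
  if (anyDuplicated(ins$rsid)) msgs <- c(msgs, "duplicate instrument rsids")
  if (nrow(ins)) {
    if (any(ins$se_gamma <= 0) || any(ins$se_Gamma <= 0))
      msgs <- c(msgs, "instrument SEs must be > 0")
    if (any(isPalindromic(ins$effect_allele, ins$other_allele)))
      msgs <- c(msgs, "palindromic allele pairs are not allowed")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a HarmonizedSet directly
#'
#' Builds a [HarmonizedSet-class] from an instrument table, for workflows
#' that harmonize outside this package or for constructing test fixtures.
#' Missing `is_proxy`/`proxy_source`/`eaf` columns are filled with defaults;
#' validity (positive SEs, no palindromic pairs, unique rsids) is enforced.
#'
#' @param exposure,outcome trait labels.
#' @param instruments `data.frame` with at least `rsid`, `effect_allele`,
#'   `other_allele`, `gamma`, `se_gamma`, `Gamma`, `se_Gamma`.
#' @param dropLog optional drop log (`rsid`, `stage`, `reason`).
#' @return a validated [HarmonizedSet-class].
#' @export
HarmonizedSet <- function(exposure, outcome, instruments,
                          dropLog = emptyLog(c("rsid", "stage", "reason"))) {
  if (!"is_proxy" %in% names(instruments)) instruments$is_proxy <- FALSE
  if (!"proxy_source" %in% names(instruments))
    instruments$proxy_source <- NA_character_
  if (!"eaf" %in% names(instruments)) instruments$eaf <- NA_real_
  rownames(instruments) <- NULL
  new("HarmonizedSet", exposure = exposure, outcome = outcome,
      instruments = instruments, dropLog = dropLog)
}

#' A single causal estimate
#'
#' One estimator's causal effect of exposure on outcome on the log-odds scale,
#' with its standard error, two-sided normal p-value and instrument count.
#' The odds ratio and 95% CI are derived: `OR = exp(beta)`,
#' `CI = exp(beta -+ 1.96 se)`.
#'
#' @slot method one of `wald`, `ivw_fixed`, `ivw_random`, `egger`,
#'   `weighted_median`.
#' @slot beta causal log-odds estimate.
#' @slot se its standard error.
#' @slot pval two-sided normal p-value.
#' @slot nSnps instrument count.
#' @slot extra method-specific fields (e.g. Egger intercept and its SE/p,
#'   Cochran's Q for IVW).
#' @seealso [mrIvw()], [mrEgger()], [mrWeightedMedian()], [orValue()]
#' @export
setClass("MrEstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 pval = "numeric", nSnps = "integer", extra = "list"))

setValidity("MrEstimate", function(object) {
  if (!object@method %in% c("wald", "ivw_fixed", "ivw_random", "egger",
                            "weighted_median"))
    return("unknown method")
  if (length(object@beta) != 1 || length(object@se) != 1) return("scalar beta/se required")
  if (is.finite(object@se) && object@se < 0) return("se must be >= 0")
  TRUE
})

MrEstimate <- function(method, beta, se, nSnps, extra = list()) {
  pval <- 2 * pnorm(-abs(beta) / se)
  new("MrEstimate", method = method, beta = as.numeric(beta),
      se = as.numeric(se), pval = as.numeric(pval),
      nSnps = as.integer(nSnps), extra = extra)
}

#' Bayesian model-averaging result
#'
#' Result of (possibly iterative) multivariable MR Bayesian model averaging:
#' per-iteration exposure summaries (MIP, MACE, best-model PP, top-model causal
#' estimate, permutation p, ranks), the enumerated model posteriors of the final
#' iteration, and the SNPs excluded as outliers at each iteration.
#'
#' @slot summary `data.frame`, final-iteration per-exposure summary.
#' @slot models `data.frame` of enumerated models (`model`, `size`, `pp`) for
#'   the final iteration.
#' @slot iterations list of per-iteration summaries (the last equals
#'   `summary`).
#' @slot excluded list (per iteration) of rsids removed before that iteration.
#' @seealso [runBmaIterative()], [mrBma()]
#' @export
setClass("BmaResult",
  representation(summary = "data.frame", models = "data.frame",
                 iterations = "list", excluded = "list"))
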