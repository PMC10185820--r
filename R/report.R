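#' @include pipeline.R
NULL

methodLabel <- c(wald = "Wald", ivw_fixed = "IVW", ivw_random = "IVW",
                 egger = "MR-egger", weighted_median = "WM")

renderEstimateRow <- function(exposure, outcome, est, direction) {
  ci <- ci95(est)
  data.frame(exposure = exposure, n_snps = est@nSnps, outcome = outcome,
             direction = direction,
             method = unname(methodLabel[est@method]),
             OR = fmt3(orValue(est)),
             `OR_95_CI` = paste0(fmt3(ci[1]), "-", fmt3(ci[2])),
             beta = fmt3(est@beta), p = fmtP(pvalue(est)),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Assemble the per-method results table
#'
#' One row per exposure and method (MR-Egger, WM, IVW), with OR and 95% CI
#' to 3 decimals, CI formatted `lo-hi`, beta to 3 decimals and p to 3
#' significant figures. An FDR (Benjamini-Hochberg across exposures on the
#' IVW p-values) column is appended for reference; the significance calls
#' themselves use unadjusted p-values.
#'
#' @param bundle result of [runForward()] or [runReverse()].
#' @return `data.frame` in display formatting.
#' @export
resultsTable <- function(bundle) {
  rows <- list()
  ivw_p <- vapply(bundle$results, function(r) pvalue(r$ivw), numeric(1))
  fdr <- stats::p.adjust(ivw_p, method = "BH")
  for (nm in names(bundle$results)) {
    r <- bundle$results[[nm]]
    for (est in Filter(Negate(is.null), list(r$egger, r$wm, r$ivw))) {
      row <- renderEstimateRow(nm, r$outcome, est, bundle$direction)
      row$ivw_fdr <- ifelse(est@method %in% c("ivw_fixed", "ivw_random"),
                            fmtP(fdr[nm]), "")
      row$significance <- ifelse(est@method %in% c("ivw_fixed", "ivw_random"),
                                 r$call$level, "")
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Assemble the sensitivity table
#'
#' One row per exposure: Cochran's Q (with df and p), MR-Egger intercept
#' (with p), MR-PRESSO global p and outlier count, and the maximum
#' leave-one-out Cook's distance.
#'
#' @param bundle result of [runForward()] or [runReverse()].
#' @return `data.frame`.
#' @export
sensitivityTable <- function(bundle) {
  do.call(rbind, lapply(names(bundle$results), function(nm) {
    s <- bundle$results[[nm]]$sensitivity
    data.frame(
      exposure = nm, outcome = s$outcome,
      Q = if (!is.null(s$heterogeneity)) fmt3(s$heterogeneity$Q) else "",
      Q_df = if (!is.null(s$heterogeneity)) s$heterogeneity$df else NA,
      Q_p = if (!is.null(s$heterogeneity)) fmtP(s$heterogeneity$pval) else "",
      egger_intercept = if (!is.null(s$eggerIntercept))
        fmt3(s$eggerIntercept$intercept) else "",
      intercept_p = if (!is.null(s$eggerIntercept))
        fmtP(s$eggerIntercept$pval) else "",
      presso_global_p = if (!is.null(s$presso)) fmtP(s$presso$globalPval)
        else "",
      n_outliers = if (!is.null(s$presso)) length(s$presso$outliers) else NA,
      max_cooks_d = if (!is.null(s$loo)) fmt3(max(s$loo$table$cooksD))
        else "",
      stringsAsFactors = FALSE)
  }))
}

#' Assemble the BMA ranking table
#'
#' One block per iteration, each headed by its SNP count and the
#' instruments excluded before it, with per-exposure MIP, rank by MIP, MACE,
#' best-model PP, rank by PP, top-model causal estimate and permutation p.
#'
#' @param bma a [BmaResult-class].
#' @return `data.frame` with a `block` header column.
#' @export
bmaTable <- function(bma) {
  do.call(rbind, lapply(seq_along(bma@iterations), function(i) {
    summ <- bma@iterations[[i]]
    excl <- bma@excluded[[i]]
    header <- if (length(excl))
      sprintf("iteration %d (excluding %s)", i, paste(excl, collapse = ","))
    else sprintf("iteration %d", i)
    data.frame(block = header, exposure = summ$exposure,
               MIP = fmt3(summ$mip), rank_by_MIP = summ$rankByMip,
               MACE = fmt3(summ$mace), PP = fmt3(summ$bestModelPp),
               rank_by_PP = summ$rankByPp,
               causal_estimate = fmt3(summ$causalEstimate),
               p = summ$permPval, stringsAsFactors = FALSE)
  }))
}

#' Write the report tables of a pipeline run
#'
#' Writes `mr_results.tsv`, `sensitivity.tsv`, `attrition.tsv` and (when a
#' BMA stage ran) `bma.tsv` into `dir`, all tab-separated. Repeated runs
#' with the same inputs and seed reproduce the files byte for byte.
#'
#' @param bundle result of [runForward()] or [runReverse()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
reportTables <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(resultsTable(bundle), sprintf("mr_results_%s.tsv", bundle$direction))
  wr(sensitivityTable(bundle), sprintf("sensitivity_%s.tsv",
                                       bundle$direction))
  wr(bundle$attrition, sprintf("attrition_%s.tsv", bundle$direction))
  if (!is.null(bundle$bma)) wr(bmaTable(bundle$bma), "bma.tsv")
  invisible(paths)
}
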