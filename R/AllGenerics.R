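#' @include AllClasses.R
NULL

#' Accessors for mrbiome classes
#'
#' `trait()`, `role()` and `snps()` access a [GwasDataset-class];
#' `instruments()`, `dropLog()` and `nInstruments()` access a
#' [HarmonizedSet-class]; `ldr2()` and `ldPositions()` access an
#' [LdMatrix-class]; `orValue()`, `ci95()` and `pvalue()` derive reporting
#' quantities from an [MrEstimate-class]; `bmaSummary()` and `bmaModels()`
#' access a [BmaResult-class].
#'
#' @param x the object.
#' @return the slot contents (or derived value, see each accessor).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trait", function(x) standardGeneric("trait"))
#' @rdname accessors
#' @export
setGeneric("role", function(x) standardGeneric("role"))
#' @rdname accessors
#' @export
setGeneric("snps", function(x) standardGeneric("snps"))
#' @rdname accessors
#' @export
setGeneric("rejectedRows", function(x) standardGeneric("rejectedRows"))
#' @rdname accessors
#' @export
setGeneric("instruments", function(x) standardGeneric("instruments"))
#' @rdname accessors
#' @export
setGeneric("dropLog", function(x) standardGeneric("dropLog"))
#' @rdname accessors
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))
#' @rdname accessors
#' @export
setGeneric("ldr2", function(x) standardGeneric("ldr2"))
#' @rdname accessors
#' @export
setGeneric("ldPositions", function(x) standardGeneric("ldPositions"))
#' @rdname accessors
#' @export
setGeneric("orValue", function(x) standardGeneric("orValue"))
#' @rdname accessors
#' @export
setGeneric("ci95", function(x) standardGeneric("ci95"))
#' @rdname accessors
#' @export
setGeneric("pvalue", function(x) standardGeneric("pvalue"))
#' @rdname accessors
#' @export
setGeneric("bmaSummary", function(x) standardGeneric("bmaSummary"))
#' @rdname accessors
#' @export
setGeneric("bmaModels", function(x) standardGeneric("bmaModels"))

#' @rdname accessors
#' @export
setMethod("trait", "GwasDataset", function(x) x@trait)
#' @rdname accessors
#' @export
setMethod("role", "GwasDataset", function(x) x@role)
#' @rdname accessors
#' @export
setMethod("snps", "GwasDataset", function(x) x@snps)
#' @rdname accessors
#' @export
setMethod("rejectedRows", "GwasDataset", function(x) x@rejected)

#' @rdname accessors
#' @export
setMethod("instruments", "HarmonizedSet", function(x) x@instruments)
#' @rdname accessors
#' @export
setMethod("dropLog", "HarmonizedSet", function(x) x@dropLog)
#' @rdname accessors
#' @export
setMethod("nInstruments", "HarmonizedSet", function(x) nrow(x@instruments))

#' @rdname accessors
#' @export
setMethod("ldr2", "LdMatrix", function(x) x@r2)
#' @rdname accessors
#' @export
setMethod("ldPositions", "LdMatrix", function(x) x@positions)

#' @rdname accessors
#' @export
setMethod("orValue", "MrEstimate", function(x) exp(x@beta))
#' @rdname accessors
#' @export
setMethod("ci95", "MrEstimate",
          function(x) exp(x@beta + c(-1, 1) * 1.96 * x@se))
#' @rdname accessors
#' @export
setMethod("pvalue", "MrEstimate", function(x) x@pval)

#' @rdname accessors
#' @export
setMethod("bmaSummary", "BmaResult", function(x) x@summary)
#' @rdname accessors
#' @export
setMethod("bmaModels", "BmaResult", function(x) x@models)

setMethod("show", "GwasDataset", function(object) {
  cat(sprintf("GwasDataset '%s' (%s): %d SNPs, %d rejected rows\n",
              object@trait, object@role, nrow(object@snps),
              nrow(object@rejected)))
  if (nrow(object@snps)) {
    print(head(object@snps, 3))
    if (nrow(object@snps) > 3) cat("...\n")
  }
  invisible(object)
})

setMethod("show", "LdMatrix", function(object) {
  cat(sprintf("LdMatrix over %d SNPs (%s positions)\n", nrow(object@r2),
              if (nrow(object@positions)) "with" else "no"))
  invisible(object)
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet: %s -> %s, %d instruments (%d proxied), %d dropped\n",
              object@exposure, object@outcome, nrow(object@instruments),
              sum(object@instruments$is_proxy), nrow(object@dropLog)))
  invisible(object)
})

setMethod("show", "MrEstimate", function(object) {
  ci <- exp(object@beta + c(-1, 1) * 1.96 * object@se)
  cat(sprintf("MrEstimate [%s] beta = %.3f (se %.3f), OR = %.3f (95%% CI %.3f-%.3f), p = %.3g, nSNPs = %d\n",
              object@method, object@beta, object@se, exp(object@beta),
              ci[1], ci[2], object@pval, object@nSnps))
  if (length(object@extra))
    cat("  extra:", paste(names(object@extra), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "BmaResult", function(object) {
  cat(sprintf("BmaResult: %d iteration(s), %d exposures\n",
              length(object@iterations), nrow(object@summary)))
  print(object@summary)
  invisible(object)
})
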