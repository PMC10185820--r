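#' @include AllClasses.R
NULL

# Canonical file dialect: tab-separated, UTF-8, one header line, "." for a
# missing optional field (eaf), 1-based positions, upper-case alleles.

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-separated summary-statistic file into a [GwasDataset-class].
#' Rows violating the record invariants (invalid alleles, non-positive SE,
#' p-value outside (0, 1], frequency outside (0, 1)) are rejected and logged
#' with a machine-readable reason code rather than aborting the read;
#' duplicated rsids are a hard error because downstream keying assumes
#' uniqueness.
#'
#' @param path input file path.
#' @param trait trait label for the dataset.
#' @param role `"exposure"` or `"outcome"`.
#' @param columnMap named character vector mapping canonical field names
#'   (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `pval`, `eaf`, `n`) to the file's column names; defaults to identity.
#' @return a [GwasDataset-class]; rejected rows are available via
#'   [rejectedRows()].
#' @export
readSummaryTsv <- function(path, trait, role = c("exposure", "outcome"),
                           columnMap = NULL) {
  role <- match.arg(role)
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", na.strings = ".",
                    colClasses = "character", check.names = FALSE)
  cmap <- setNames(canonicalColumns, canonicalColumns)
  if (!is.null(columnMap)) cmap[names(columnMap)] <- columnMap
  missing_cols <- setdiff(unname(cmap), names(raw))
  if (length(missing_cols))
    stopf("mapped column(s) absent from header: %s",
          paste(missing_cols, collapse = ", "))
  s <- data.frame(
    rsid = raw[[cmap["rsid"]]],
    chrom = raw[[cmap["chrom"]]],
    pos = suppressWarnings(as.integer(raw[[cmap["pos"]]])),
    effect_allele = toupper(raw[[cmap["effect_allele"]]]),
    other_allele = toupper(raw[[cmap["other_allele"]]]),
    beta = suppressWarnings(as.numeric(raw[[cmap["beta"]]])),
    se = suppressWarnings(as.numeric(raw[[cmap["se"]]])),
    pval = suppressWarnings(as.numeric(raw[[cmap["pval"]]])),
    eaf = suppressWarnings(as.numeric(raw[[cmap["eaf"]]])),
    n = suppressWarnings(as.numeric(raw[[cmap["n"]]])),
    stringsAsFactors = FALSE)
  if (anyDuplicated(s$rsid))
    stopf("duplicate rsid(s): %s",
          paste(unique(s$rsid[duplicated(s$rsid)]), collapse = ", "))
  reason <- rep(NA_character_, nrow(s))
  flag <- function(bad, code) reason[is.na(reason) & bad] <<- code
  flag(is.na(s$beta) | !is.finite(s$beta), "missing beta")
  flag(is.na(s$se) | s$se <= 0, "non-positive se")
  flag(is.na(s$pval) | s$pval <= 0 | s$pval > 1, "pval outside (0,1]")
  flag(!s$effect_allele %in% validAlleles |
         !s$other_allele %in% validAlleles, "invalid allele")
  flag(s$effect_allele == s$other_allele, "identical alleles")
  flag(!is.na(s$eaf) & (s$eaf <= 0 | s$eaf >= 1), "eaf outside (0,1)")
  flag(is.na(s$n) | s$n <= 0, "non-positive n")
  rejected <- data.frame(rsid = s$rsid[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  GwasDataset(s[is.na(reason), , drop = FALSE], trait = trait, role = role,
              rejected = rejected)
}

#' Write GWAS summary statistics to a delimited file
#'
#' Writes the canonical tab-separated format with a fixed header;
#' [readSummaryTsv()] inverts it exactly. Missing `eaf` is written as `"."`.
#'
#' @param dataset a [GwasDataset-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeSummaryTsv <- function(dataset, path) {
  stopifnot(is(dataset, "GwasDataset"))
  s <- snps(dataset)
  out <- s
  out$eaf <- ifelse(is.na(s$eaf), ".", formatC(s$eaf, format = "g", digits = 17))
  for (col in c("beta", "se", "pval", "n"))
    out[[col]] <- formatC(s[[col]], format = "g", digits = 17)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled square LD (r-squared) matrix
#'
#' Expects a tab-separated table whose first column holds SNP ids and whose
#' remaining columns are named by the same ids in the same order. Asymmetries
#' beyond 1e-8, a diagonal differing from 1, or entries outside `[0, 1]` are
#' errors.
#'
#' @param path input file path.
#' @param positions optional `data.frame` (`rsid`, `chrom`, `pos`) attached
#'   for distance-window clumping.
#' @return an [LdMatrix-class].
#' @export
readLdMatrix <- function(path, positions = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) stopf("LD table is not square")
  if (!identical(colnames(m), ids))
    stopf("LD table row ids do not match column ids")
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, ids)
  if (any(!is.finite(m) | m < 0 | m > 1))
    stopf("LD entries outside [0, 1]")
  if (max(abs(m - t(m))) > 1e-8) stopf("LD matrix asymmetric beyond 1e-8")
  if (max(abs(diag(m) - 1)) > 1e-8) stopf("LD diagonal must equal 1")
  LdMatrix(m, positions)
}

#' Write an LD matrix as a labelled square table
#'
#' @param ld an [LdMatrix-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeLdMatrix <- function(ld, path) {
  stopifnot(is(ld, "LdMatrix"))
  m <- ldr2(ld)
  out <- data.frame(rsid = rownames(m),
                    as.data.frame(m, check.names = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a confounder-SNP exclusion list
#'
#' One rsid per line; `#` starts a comment; blank lines ignored. Used in
#' place of live confounder-database screening.
#'
#' @param path input file path.
#' @return character vector of rsids.
#' @export
readExclusionList <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}
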