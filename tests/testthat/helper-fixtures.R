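# Build a HarmonizedSet from effect vectors, with non-palindromic alleles.
makeSet <- function(gamma, Gamma, seGamma = rep(0.01, length(gamma)),
                    seGammaOut = rep(0.02, length(gamma)),
                    rsid = sprintf("rs%03d", seq_along(gamma)),
                    exposure = "taxon", outcome = "disease") {
  HarmonizedSet(exposure, outcome, data.frame(
    rsid = rsid, effect_allele = "A", other_allele = "G",
    gamma = gamma, se_gamma = seGamma, Gamma = Gamma,
    se_Gamma = seGammaOut, stringsAsFactors = FALSE))
}

# Canonical SNP table rows for io/selection tests.
makeSnpTable <- function(n, pval = rep(1e-6, n), beta = rep(0.1, n),
                         se = rep(0.01, n), eaf = rep(0.3, n),
                         rsid = sprintf("rs%03d", seq_len(n)),
                         effect_allele = rep("A", n),
                         other_allele = rep("G", n),
                         chrom = rep("1", n),
                         pos = as.integer(seq_len(n) * 1000)) {
  data.frame(rsid = rsid, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             beta = beta, se = se, pval = pval, eaf = eaf,
             n = rep(18340, n), stringsAsFactors = FALSE)
}

makeDataset <- function(..., trait = "taxon", role = "exposure") {
  GwasDataset(makeSnpTable(...), trait = trait, role = role)
}

# Labelled identity-free LD matrix from an explicit r2 matrix.
makeLd <- function(r2, ids, positions = NULL) {
  dimnames(r2) <- list(ids, ids)
  LdMatrix(r2, positions)
}

# Independent greedy-by-p clumping oracle for small instances: at each step
# pick the remaining SNP with smallest p (rsid breaks ties), remove all
# linked SNPs; written without reference to the package implementation.
clumpOracle <- function(rsid, pval, r2, threshold) {
  names(pval) <- rsid
  kept <- character()
  remaining <- rsid
  while (length(remaining)) {
    ord <- remaining[order(pval[remaining], remaining)]
    lead <- ord[1]
    kept <- c(kept, lead)
    remaining <- setdiff(ord[-1], ord[-1][r2[lead, ord[-1]] >= threshold])
  }
  sort(kept)
}
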