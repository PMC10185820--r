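#' @include AllClasses.R summary-io.R
NULL

#' Define a synthetic GWAS scenario
#'
#' Parameters of the synthetic summary-statistic generator. Defaults emulate
#' the scale of a large microbiome-abundance GWAS meta-analysis (n = 18,340,
#' rank-normalized abundances) used as exposure and a biobank case-control
#' disease GWAS (538 cases / 341,961 controls) used as outcome, with
#' per-instrument variance explained just above what survives locus-wide
#' (p < 1e-5) instrument selection.
#'
#' @param jInstruments instrument count per taxon.
#' @param theta true causal effect (log-odds per SD of exposure).
#' @param pleiotropyMode `"none"`, `"balanced"`, `"directional"`, or
#'   `"inside_violating"` (pleiotropy correlated with instrument strength,
#'   breaking the InSIDE assumption).
#' @param tau pleiotropy SD.
#' @param muAlpha directional pleiotropy mean.
#' @param mafRange range of simulated effect-allele frequencies.
#' @param r2Range per-SNP exposure variance explained range.
#' @param nExposure exposure GWAS sample size.
#' @param nCase,nControl outcome case-control counts.
#' @param jNull additional null background SNPs (true gamma = 0), for
#'   selection-stage tests.
#' @param kExposures exposure count for multivariable designs.
#' @param exposureCor genetic correlation of SNP effects across exposures.
#' @param seed RNG seed.
#' @return a `mr_scenario` list.
#' @export
syntheticScenario <- function(jInstruments = 16, theta = 0,
                              pleiotropyMode = c("none", "balanced",
                                                 "directional",
                                                 "inside_violating"),
                              tau = 0.05, muAlpha = 0.1,
                              mafRange = c(0.05, 0.5),
                              r2Range = c(0.0015, 0.004),
                              nExposure = 18340, nCase = 538,
                              nControl = 341961, jNull = 0,
                              kExposures = 4, exposureCor = 0.6,
                              seed = 1L) {
  pleiotropyMode <- match.arg(pleiotropyMode)
  stopifnot(jInstruments >= 1, tau >= 0,
            mafRange[1] > 0, mafRange[2] <= 0.5, mafRange[1] <= mafRange[2],
            r2Range[1] > 0, r2Range[1] <= r2Range[2],
            nExposure > 1, nCase > 0, nControl > 0, jNull >= 0,
            kExposures >= 1, exposureCor >= 0, exposureCor < 1)
  structure(list(jInstruments = jInstruments, theta = theta,
                 pleiotropyMode = pleiotropyMode, tau = tau,
                 muAlpha = muAlpha, mafRange = mafRange, r2Range = r2Range,
                 nExposure = nExposure, nCase = nCase, nControl = nControl,
                 jNull = jNull, kExposures = kExposures,
                 exposureCor = exposureCor, seed = seed),
            class = "mr_scenario")
}

# two-sided Wald p, floored at 1e-300 so extreme z never underflows to 0
waldPval <- function(z) pmax(2 * pnorm(-abs(z)), 1e-300)

# log-odds SE for an allelic effect in a case-control GWAS:
# var = (1/cases + 1/controls) / (2 maf (1 - maf))
binaryOutcomeSe <- function(maf, nCase, nControl) {
  sqrt((1 / nCase + 1 / nControl) / (2 * maf * (1 - maf)))
}

nonPalindromicPairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                "G", "A", "C", "A", "G", "T", "C", "T"),
                              ncol = 2, byrow = TRUE)

snpScaffold <- function(J, maf) {
  pair <- nonPalindromicPairs[sample.int(nrow(nonPalindromicPairs), J,
                                         replace = TRUE), , drop = FALSE]
  data.frame(rsid = sprintf("rs%07d", sample.int(9999999, J)),
             chrom = as.character(rep_len(1:22, J)),
             pos = as.integer(((seq_len(J) - 1) %/% 22 + 1) * 2e5),
             effect_allele = pair[, 1], other_allele = pair[, 2],
             eaf = maf, stringsAsFactors = FALSE)
}

drawAlpha <- function(scenario, gammaTrue) {
  J <- length(gammaTrue)
  # directional pleiotropy is defined on the exposure-increasing allele
  # orientation (the orientation MR-Egger fits in), hence the sign(gamma)
  switch(scenario$pleiotropyMode,
    none = rep(0, J),
    balanced = rnorm(J, 0, scenario$tau),
    directional = ifelse(gammaTrue < 0, -1, 1) *
      rnorm(J, scenario$muAlpha, scenario$tau),
    inside_violating = {
      rho <- 0.8
      z <- if (stats::sd(gammaTrue) > 0)
        (gammaTrue - mean(gammaTrue)) / stats::sd(gammaTrue)
      else rep(0, J)
      scenario$tau * (rho * z + sqrt(1 - rho^2) * rnorm(J))
    })
}

#' Simulate one taxon's exposure and outcome summary statistics
#'
#' Per SNP: MAF ~ U(mafRange); true exposure effect sized to a per-SNP
#' variance explained drawn from `r2Range` (random sign); exposure SE
#' `1/sqrt(2 maf (1-maf) nExposure)`; observed exposure effect normal around
#' truth. Outcome effects follow `Gamma_j = theta * gamma_j + alpha_j` with
#' the pleiotropy term set by the scenario mode, case-control log-odds SEs,
#' and observed effects normal around truth. P-values are Wald. `jNull`
#' background SNPs with zero true effect can be appended for selection-stage
#' tests. The LD matrix is the identity (use [simulateLdBlocks()] for block
#' structure). Output is bit-identical under a fixed scenario seed.
#'
#' @param scenario a [syntheticScenario()].
#' @param trait exposure trait label.
#' @param outcomeTrait outcome trait label.
#' @return list with `exposure` and `outcome` ([GwasDataset-class]), `ld`
#'   ([LdMatrix-class]) and `truth` (list: `gammaTrue`, `alpha`, `theta`,
#'   `instrumentIds`).
#' @export
simulateTaxonInstruments <- function(scenario = syntheticScenario(),
                                     trait = "taxon",
                                     outcomeTrait = "disease") {
  withSeed(scenario$seed, {
    J <- scenario$jInstruments + scenario$jNull
    maf <- runif(J, scenario$mafRange[1], scenario$mafRange[2])
    scaf <- snpScaffold(J, maf)
    r2 <- runif(J, scenario$r2Range[1], scenario$r2Range[2])
    gamma_true <- sample(c(-1, 1), J, replace = TRUE) *
      sqrt(r2 / (2 * maf * (1 - maf)))
    if (scenario$jNull > 0)
      gamma_true[scenario$jInstruments + seq_len(scenario$jNull)] <- 0
    se_g <- 1 / sqrt(2 * maf * (1 - maf) * scenario$nExposure)
    gamma_hat <- rnorm(J, gamma_true, se_g)
    alpha <- drawAlpha(scenario, gamma_true)
    Gamma_true <- scenario$theta * gamma_true + alpha
    se_G <- binaryOutcomeSe(maf, scenario$nCase, scenario$nControl)
    Gamma_hat <- rnorm(J, Gamma_true, se_G)
    expo <- GwasDataset(
      cbind(scaf, data.frame(beta = gamma_hat, se = se_g,
                             pval = waldPval(gamma_hat / se_g),
                             n = scenario$nExposure))[, canonicalColumns],
      trait = trait, role = "exposure")
    outc <- GwasDataset(
      cbind(scaf, data.frame(beta = Gamma_hat, se = se_G,
                             pval = waldPval(Gamma_hat / se_G),
                             n = scenario$nCase + scenario$nControl))[
                               , canonicalColumns],
      trait = outcomeTrait, role = "outcome")
    r2m <- diag(J)
    dimnames(r2m) <- list(scaf$rsid, scaf$rsid)
    list(exposure = expo, outcome = outc,
         ld = LdMatrix(r2m, scaf[, c("rsid", "chrom", "pos")]),
         truth = list(gammaTrue = gamma_true, alpha = alpha,
                      theta = scenario$theta,
                      instrumentIds = scaf$rsid[seq_len(scenario$jInstruments)]))
  })
}

#' Simulate a block-diagonal LD matrix
#'
#' r-squared equals `withinR2` inside consecutive blocks of `blockSize` SNPs
#' (the last block may be truncated) and 0 between blocks. Positions place
#' each block's SNPs 100 kb apart — well inside a 10,000 kb clumping window —
#' with successive blocks 50,000 kb apart.
#'
#' @param nSnps total SNP count.
#' @param blockSize SNPs per block.
#' @param withinR2 within-block r-squared.
#' @param seed seed for rsid generation.
#' @param snpIds optional explicit SNP ids (length `nSnps`).
#' @return an [LdMatrix-class] with positions.
#' @export
simulateLdBlocks <- function(nSnps, blockSize, withinR2, seed = 1L,
                             snpIds = NULL) {
  stopifnot(nSnps >= 1, blockSize >= 1, withinR2 >= 0, withinR2 <= 1)
  if (is.null(snpIds))
    snpIds <- withSeed(seed, sprintf("rs%07d", sample.int(9999999, nSnps)))
  stopifnot(length(snpIds) == nSnps, !anyDuplicated(snpIds))
  block <- (seq_len(nSnps) - 1) %/% blockSize
  m <- outer(block, block, `==`) * withinR2
  diag(m) <- 1
  dimnames(m) <- list(snpIds, snpIds)
  within_idx <- seq_len(nSnps) - 1 - block * blockSize
  pos <- as.integer(block * 5e7 + within_idx * 1e5 + 1)
  LdMatrix(m, data.frame(rsid = snpIds, chrom = "1", pos = pos,
                         stringsAsFactors = FALSE))
}

#' Simulate a correlated multi-exposure design for BMA
#'
#' Draws SNP effects on `kExposures` exposures with cross-exposure
#' correlation `exposureCor` (shared latent factor per SNP), then outcome
#' effects from the multivariable model `y = X theta + alpha + noise`.
#' Dimensions default to K = 4 exposures and the scenario's instrument count
#' as the SNP union size.
#'
#' @param scenario a [syntheticScenario()]; `jInstruments` is the union SNP
#'   count (e.g. 41).
#' @param trueEffects numeric vector of per-exposure causal effects
#'   (length `kExposures`).
#' @return list with `exposures` (named list of [GwasDataset-class]),
#'   `outcome` ([GwasDataset-class]), `mat` (exposure matrix as from
#'   [buildExposureMatrix()]) and `truth`.
#' @export
simulateMultiExposure <- function(scenario = syntheticScenario(jInstruments = 41),
                                  trueEffects = c(0.7, 0, 0, 0)) {
  K <- length(trueEffects)
  stopifnot(K == scenario$kExposures || K >= 1)
  withSeed(scenario$seed, {
    J <- scenario$jInstruments
    maf <- runif(J, scenario$mafRange[1], scenario$mafRange[2])
    scaf <- snpScaffold(J, maf)
    r2 <- runif(J, scenario$r2Range[1], scenario$r2Range[2])
    scale_j <- sqrt(r2 / (2 * maf * (1 - maf)))
    rho <- scenario$exposureCor
    shared <- rnorm(J)
    Z <- sqrt(rho) * matrix(shared, J, K) +
      sqrt(1 - rho) * matrix(rnorm(J * K), J, K)
    gamma_true <- Z * scale_j
    se_g <- 1 / sqrt(2 * maf * (1 - maf) * scenario$nExposure)
    gamma_hat <- gamma_true + matrix(rnorm(J * K), J, K) * se_g
    alpha <- drawAlpha(scenario, drop(gamma_true %*% rep(1, K)) / K)
    y_true <- drop(gamma_true %*% trueEffects) + alpha
    se_G <- binaryOutcomeSe(maf, scenario$nCase, scenario$nControl)
    y_hat <- rnorm(J, y_true, se_G)
    labels <- paste0("exposure_", seq_len(K))
    exposures <- setNames(lapply(seq_len(K), function(k) {
      GwasDataset(cbind(scaf, data.frame(
        beta = gamma_hat[, k], se = se_g,
        pval = waldPval(gamma_hat[, k] / se_g),
        n = scenario$nExposure))[, canonicalColumns],
        trait = labels[k], role = "exposure")
    }), labels)
    outcome <- GwasDataset(cbind(scaf, data.frame(
      beta = y_hat, se = se_G,
      pval = waldPval(y_hat / se_G),
      n = scenario$nCase + scenario$nControl))[, canonicalColumns],
      trait = "disease", role = "outcome")
    X <- gamma_hat
    dimnames(X) <- list(scaf$rsid, labels)
    list(exposures = exposures, outcome = outcome,
         mat = list(snpIds = scaf$rsid, X = X, y = y_hat, seY = se_G,
                    exposures = labels, nZeroFilled = 0L),
         truth = list(gammaTrue = gamma_true, alpha = alpha,
                      theta = trueEffects))
  })
}

renameFixtureIds <- function(sim, newIds) {
  oldIds <- snps(sim$exposure)$rsid
  stopifnot(length(newIds) == length(oldIds))
  es <- snps(sim$exposure); es$rsid <- newIds
  os <- snps(sim$outcome); os$rsid <- newIds
  pos <- ldPositions(sim$ld); pos$rsid <- newIds
  sim$exposure <- GwasDataset(es, trait = trait(sim$exposure),
                              role = "exposure")
  sim$outcome <- GwasDataset(os, trait = trait(sim$outcome),
                             role = "outcome")
  m <- ldr2(sim$ld); dimnames(m) <- list(newIds, newIds)
  sim$ld <- LdMatrix(m, pos)
  sim$truth$instrumentIds <- newIds[match(sim$truth$instrumentIds, oldIds)]
  sim
}

#' Simulate a complete multi-taxon study fixture
#'
#' Builds the full synthetic study: one exposure GWAS per taxon (each with
#' `jPerTaxon` instruments and its own causal effect on the disease), a
#' merged disease outcome GWAS carrying every taxon instrument plus
#' `jDisease` genuine disease-susceptibility loci (genome-wide significant
#' for the disease, null for every taxon — there is no reverse causation in
#' the generating model), and an identity LD matrix over the union. The
#' disease loci make the reverse direction analysable: they are the
#' instruments [runReverse()] selects at the genome-wide threshold.
#'
#' @param seed master seed; per-taxon seeds are derived from it.
#' @param thetas named vector of per-taxon true causal effects (log-odds per
#'   SD of abundance).
#' @param jPerTaxon instruments per taxon.
#' @param jDisease disease-susceptibility loci for the reverse direction.
#' @return list with `taxa` (named list of exposure [GwasDataset-class],
#'   each also carrying the disease loci as null records), `outcome`
#'   (disease [GwasDataset-class]), `ld` ([LdMatrix-class]), `truth`.
#' @export
simulateStudyFixture <- function(seed = 1L,
                                 thetas = c(taxonA = 1.244,
                                            taxonB = -0.785,
                                            taxonC = 0, taxonD = 0),
                                 jPerTaxon = 16, jDisease = 10) {
  K <- length(thetas)
  if (is.null(names(thetas))) names(thetas) <- paste0("taxon_", seq_len(K))
  dseed <- function(k) as.integer((as.numeric(seed) * 100 + k) %% 2147483647)
  taxa <- list(); out_tabs <- list(); pos_tabs <- list(); truths <- list()
  for (k in seq_len(K)) {
    sim <- simulateTaxonInstruments(
      syntheticScenario(jInstruments = jPerTaxon, theta = thetas[[k]],
                        seed = dseed(k)),
      trait = names(thetas)[k])
    sim <- renameFixtureIds(sim, sprintf("rs%d%05d", k, seq_len(jPerTaxon)))
    taxa[[names(thetas)[k]]] <- sim
    out_tabs[[k]] <- snps(sim$outcome)
    pos_tabs[[k]] <- ldPositions(sim$ld)
    truths[[names(thetas)[k]]] <- sim$truth
  }
  # disease-susceptibility loci: strong on the disease, null for every taxon
  dis <- withSeed(dseed(99), {
    maf <- runif(jDisease, 0.05, 0.5)
    scaf <- snpScaffold(jDisease, maf)
    scaf$rsid <- sprintf("rs9%05d", seq_len(jDisease))
    se_G <- binaryOutcomeSe(maf, 538, 341961)
    z_true <- sample(c(-1, 1), jDisease, TRUE) * runif(jDisease, 6, 10)
    beta_obs <- (z_true + rnorm(jDisease)) * se_G
    se_tax <- 1 / sqrt(2 * maf * (1 - maf) * 18340)
    tax_beta <- matrix(rnorm(jDisease * K, 0, se_tax), jDisease, K)
    list(scaf = scaf, se_G = se_G, beta_obs = beta_obs,
         se_tax = se_tax, tax_beta = tax_beta)
  })
  out_tabs[[K + 1]] <- cbind(dis$scaf, data.frame(
    beta = dis$beta_obs, se = dis$se_G,
    pval = waldPval(dis$beta_obs / dis$se_G),
    n = 538 + 341961))[, canonicalColumns]
  pos_tabs[[K + 1]] <- dis$scaf[, c("rsid", "chrom", "pos")]
  outcome_tab <- do.call(rbind, out_tabs)
  outcome <- GwasDataset(outcome_tab, trait = "disease", role = "outcome")
  taxa_sets <- setNames(lapply(seq_len(K), function(k) {
    own <- snps(taxa[[k]]$exposure)
    disrows <- cbind(dis$scaf, data.frame(
      beta = dis$tax_beta[, k], se = dis$se_tax,
      pval = waldPval(dis$tax_beta[, k] / dis$se_tax),
      n = 18340))[, canonicalColumns]
    GwasDataset(rbind(own, disrows), trait = names(thetas)[k],
                role = "exposure")
  }), names(thetas))
  ids <- outcome_tab$rsid
  m <- diag(length(ids)); dimnames(m) <- list(ids, ids)
  positions <- do.call(rbind, pos_tabs)
  list(taxa = taxa_sets, outcome = outcome,
       ld = LdMatrix(m, positions),
       truth = list(thetas = thetas, perTaxon = truths,
                    diseaseLoci = dis$scaf$rsid))
}
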