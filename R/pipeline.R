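#' @include estimators.R sensitivity.R bma.R simulate.R
NULL

#' Full causal analysis of one harmonized pair
#'
#' Runs IVW (mode auto: random effects when Cochran's Q rejects), MR-Egger
#' and the weighted median (instrument count permitting), the sensitivity
#' suite, and the significance classification.
#'
#' @param set a [HarmonizedSet-class].
#' @param nBoot weighted-median bootstrap count.
#' @param nSim MR-PRESSO simulation count.
#' @param cooksThreshold leave-one-out Cook's distance threshold.
#' @param seed RNG seed.
#' @return list with `ivw`, `egger`, `wm` ([MrEstimate-class] or `NULL`),
#'   `sensitivity`, `call`.
#' @export
mrAnalyzePair <- function(set, nBoot = 1000, nSim = 1000,
                          cooksThreshold = 0.5, seed = 1L) {
  J <- nInstruments(set)
  ivw <- mrIvw(set, mode = "auto")
  egger <- if (J >= 3) mrEgger(set) else NULL
  wm <- if (J >= 3) mrWeightedMedian(set, nBoot = nBoot, seed = seed)
        else NULL
  sens <- sensitivityReport(set, nSim = nSim,
                            cooksThreshold = cooksThreshold, seed = seed)
  additional <- Filter(Negate(is.null), list(egger, wm))
  call <- classifySignificance(ivw, additional, sens)
  list(exposure = set@exposure, outcome = set@outcome,
       ivw = ivw, egger = egger, wm = wm, sensitivity = sens, call = call)
}

selectInstruments <- function(dataset, ld, config) {
  log <- newAttrition()
  n0 <- nrow(snps(dataset))
  sel <- selectByPvalue(dataset, config)
  log <- addAttrition(log, "p_threshold", n0, nrow(snps(sel)),
                      sprintf("p < %g", config$pThreshold))
  cl <- clumpInstruments(sel, ld, config)
  log <- addAttrition(log, "clump", nrow(snps(sel)), nrow(snps(cl)),
                      sprintf("r2 < %g within %g kb", config$clumpR2,
                              config$clumpKb))
  ex <- excludeConfounderSnps(cl, config)
  log <- addAttrition(log, "confounders", nrow(snps(cl)), nrow(snps(ex)),
                      "exclusion list")
  list(dataset = ex, attrition = log)
}

#' Run the forward MR pipeline
#'
#' For each exposure: p-value selection, LD clumping, confounder exclusion,
#' per-taxon F-statistic weak-instrument gate, harmonization to the outcome,
#' causal estimation (IVW + MR-Egger + weighted median), sensitivity suite
#' and significance call. Exposures reaching at least nominal significance
#' are passed to iterative multivariable BMA when two or more qualify.
#'
#' @param exposures named list of exposure [GwasDataset-class] objects.
#' @param outcome outcome [GwasDataset-class].
#' @param ld an [LdMatrix-class].
#' @param config a [selectionConfig()].
#' @param bmaCfg a [bmaConfig()].
#' @param nBoot,nSim,cooksThreshold estimator/sensitivity options.
#' @param seed master seed.
#' @param runBma run the BMA stage (default TRUE).
#' @return list with `results` (per-exposure analysis lists), `attrition`
#'   (`data.frame` with a `trait` column), `fDecisions`, `bma`
#'   ([BmaResult-class] or `NULL`), `direction`, `seed`.
#' @export
runForward <- function(exposures, outcome, ld, config = selectionConfig(),
                       bmaCfg = bmaConfig(), nBoot = 1000, nSim = 1000,
                       cooksThreshold = 0.5, seed = 1L, runBma = TRUE) {
  stopifnot(length(exposures) >= 1, is(outcome, "GwasDataset"))
  if (is.null(names(exposures)))
    names(exposures) <- vapply(exposures, trait, character(1))
  selected <- list(); attr_all <- list()
  for (nm in names(exposures)) {
    st <- selectInstruments(exposures[[nm]], ld, config)
    if (nrow(snps(st$dataset)) == 0) {
      st$attrition <- addAttrition(st$attrition, "empty", 0, 0,
                                   "no instruments survive selection")
      attr_all[[nm]] <- st$attrition
      next
    }
    selected[[nm]] <- st$dataset
    attr_all[[nm]] <- st$attrition
  }
  if (!length(selected)) stopf("no exposure survives instrument selection")
  fw <- filterWeak(selected, config)
  for (nm in names(selected)) {
    dec <- fw$decisions[fw$decisions$trait == nm, ]
    attr_all[[nm]] <- addAttrition(
      attr_all[[nm]], "f_filter", dec$k, if (dec$kept) dec$k else 0,
      sprintf("F = %.2f %s %g", dec$fStat, if (dec$kept) ">=" else "<",
              config$fMin))
  }
  results <- list(); harmonized <- list()
  for (nm in names(fw$kept)) {
    hs <- harmonize(fw$kept[[nm]], outcome, ld, config)
    attr_all[[nm]] <- addAttrition(
      attr_all[[nm]], "harmonize", nrow(snps(fw$kept[[nm]])),
      nInstruments(hs), "proxy/palindrome/alignment drops")
    harmonized[[nm]] <- hs
    results[[nm]] <- mrAnalyzePair(hs, nBoot = nBoot, nSim = nSim,
                                   cooksThreshold = cooksThreshold,
                                   seed = snpStreamSeed(seed, nm))
  }
  attrition <- do.call(rbind, lapply(names(attr_all), function(nm)
    cbind(trait = nm, attr_all[[nm]], stringsAsFactors = FALSE)))
  nominal <- names(results)[vapply(results, function(r)
    r$call$level %in% c("nominal", "significant"), logical(1))]
  bma <- NULL
  if (runBma && length(nominal) >= 2) {
    mat <- buildExposureMatrix(harmonized[nominal])
    bmaCfg$seed <- seed
    bma <- runBmaIterative(mat, bmaCfg)
  }
  list(results = results, attrition = attrition, fDecisions = fw$decisions,
       harmonized = harmonized, bma = bma, direction = "forward",
       seed = seed)
}

#' Run the reverse MR pipeline
#'
#' Swaps the roles: the disease GWAS becomes the exposure (instrumented at
#' the genome-wide threshold 5e-8 by default, appropriate for a well-powered
#' disease GWAS) and each taxon becomes an outcome. The pipeline and report
#' schema are otherwise identical to [runForward()]; no BMA stage is run.
#'
#' @param disease the disease [GwasDataset-class] (forward-direction
#'   outcome).
#' @param taxa named list of taxon [GwasDataset-class] objects (forward
#'   exposures), each analysed as an outcome.
#' @param ld an [LdMatrix-class].
#' @param config a [selectionConfig()]; default threshold 5e-8.
#' @param nBoot,nSim,cooksThreshold,seed as in [runForward()].
#' @return list as [runForward()] (one result per taxon), `direction =
#'   "reverse"`.
#' @export
runReverse <- function(disease, taxa, ld,
                       config = selectionConfig(pThreshold = 5e-8),
                       nBoot = 1000, nSim = 1000, cooksThreshold = 0.5,
                       seed = 1L) {
  if (is.null(names(taxa))) names(taxa) <- vapply(taxa, trait, character(1))
  dis_exp <- GwasDataset(snps(disease), trait = trait(disease),
                         role = "exposure")
  st <- selectInstruments(dis_exp, ld, config)
  if (!nrow(snps(st$dataset)))
    stopf("no disease instruments at p < %g", config$pThreshold)
  strength <- instrumentStrength(st$dataset)
  if (strength$fStat < config$fMin)
    stopf("disease instrument set is weak (F = %.2f)", strength$fStat)
  results <- list(); harmonized <- list(); attr_all <- list()
  for (nm in names(taxa)) {
    outc <- GwasDataset(snps(taxa[[nm]]), trait = trait(taxa[[nm]]),
                        role = "outcome")
    hs <- harmonize(st$dataset, outc, ld, config)
    harmonized[[nm]] <- hs
    log <- addAttrition(st$attrition, "harmonize",
                        nrow(snps(st$dataset)), nInstruments(hs),
                        "proxy/palindrome/alignment drops")
    attr_all[[nm]] <- log
    results[[nm]] <- mrAnalyzePair(hs, nBoot = nBoot, nSim = nSim,
                                   cooksThreshold = cooksThreshold,
                                   seed = snpStreamSeed(seed, nm))
  }
  attrition <- do.call(rbind, lapply(names(attr_all), function(nm)
    cbind(trait = nm, attr_all[[nm]], stringsAsFactors = FALSE)))
  list(results = results, attrition = attrition,
       fDecisions = data.frame(trait = trait(disease), k = strength$k,
                               fStat = strength$fStat, kept = TRUE,
                               stringsAsFactors = FALSE),
       harmonized = harmonized, bma = NULL, direction = "reverse",
       seed = seed)
}
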