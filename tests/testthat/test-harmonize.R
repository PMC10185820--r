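test_that("palindrome detection matches full enumeration", {
  expect_true(isPalindromic("A", "T"))
  expect_false(isPalindromic("A", "G"))
  pairs <- expand.grid(a1 = c("A", "C", "G", "T"), a2 = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a1 != pairs$a2, ]
  # independent definition: the unordered pair is {A,T} or {C,G}
  oracle <- mapply(function(x, y) setequal(c(x, y), c("A", "T")) ||
                     setequal(c(x, y), c("C", "G")), pairs$a1, pairs$a2)
  got <- isPalindromic(pairs$a1, pairs$a2)
  expect_equal(unname(got), unname(oracle))
  expect_equal(sum(got), 4)
  expect_error(isPalindromic("A", "N"), "invalid allele")
})

recAllele <- function(rsid, a1, a2, beta) {
  data.frame(rsid = rsid, chrom = "1", pos = 1L, effect_allele = a1,
             other_allele = a2, beta = beta, se = 0.05, pval = 0.5,
             eaf = 0.3, n = 1000, stringsAsFactors = FALSE)
}

test_that("allele alignment handles identity, swap and strand flips", {
  ex <- recAllele("rs1", "A", "G", 0.10)
  # swap case: outcome effect allele is the exposure's other allele
  h <- alignAlleles(ex, recAllele("rs1", "G", "A", -0.05))
  expect_equal(h$Gamma, 0.05)
  expect_equal(h$effect_allele, "A")
  # identical orientation: unchanged
  h2 <- alignAlleles(ex, recAllele("rs1", "A", "G", -0.05))
  expect_equal(h2$Gamma, -0.05)
  # opposite strand, same orientation after complement (T/C ~ A/G)
  h3 <- alignAlleles(ex, recAllele("rs1", "T", "C", -0.05))
  expect_equal(h3$Gamma, -0.05)
  # incompatible pair is rejected with a reason
  h4 <- alignAlleles(ex, recAllele("rs1", "A", "C", -0.05))
  expect_null(h4)
})

test_that("alignment agrees with brute-force orientation enumeration", {
  # all orientation/strand presentations of a non-palindromic SNP A/G
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ex <- recAllele("rs1", "A", "G", 0.10)
  presentations <- list(
    list(a = "A", b = "G", flip = FALSE), list(a = "G", b = "A", flip = TRUE),
    list(a = "T", b = "C", flip = FALSE), list(a = "C", b = "T", flip = TRUE))
  for (p in presentations) {
    h <- alignAlleles(ex, recAllele("rs1", p$a, p$b, 0.07))
    expect_equal(h$Gamma, if (p$flip) -0.07 else 0.07)
  }
  # every allele pair disjoint from {A,G,T,C-complement structure} rejects
  for (bad in list(c("A", "C"), c("G", "T"), c("C", "A"), c("T", "G"))) {
    expect_null(alignAlleles(ex, recAllele("rs1", bad[1], bad[2], 0.07)))
  }
})

test_that("proxy search returns the best-correlated outcome SNP above 0.8", {
  ids <- c("rsX", "rsA", "rsB", "rsC")
  r2 <- diag(4)
  r2[1, 2] <- r2[2, 1] <- 0.9
  r2[1, 3] <- r2[3, 1] <- 0.95
  r2[1, 4] <- r2[4, 1] <- 0.75
  ld <- makeLd(r2, ids)
  outcome <- GwasDataset(makeSnpTable(3, rsid = c("rsA", "rsB", "rsC")),
                         "disease", "outcome")
  cfg <- selectionConfig()
  expect_equal(findProxy("rsX", outcome, ld, cfg), "rsB")   # argmax
  # 0.85 qualifies (> 0.8), 0.75 does not
  r2b <- diag(2); r2b[1, 2] <- r2b[2, 1] <- 0.85
  out1 <- GwasDataset(makeSnpTable(1, rsid = "rsA"), "d", "outcome")
  expect_equal(findProxy("rsX", out1, makeLd(r2b, c("rsX", "rsA")), cfg),
               "rsA")
  r2c <- diag(2); r2c[1, 2] <- r2c[2, 1] <- 0.75
  expect_true(is.na(findProxy("rsX", out1, makeLd(r2c, c("rsX", "rsA")),
                              cfg)))
  # ties break lexicographically
  r2d <- diag(3); r2d[1, 2] <- r2d[2, 1] <- 0.9; r2d[1, 3] <- r2d[3, 1] <- 0.9
  out2 <- GwasDataset(makeSnpTable(2, rsid = c("rsB", "rsA")), "d", "outcome")
  expect_equal(findProxy("rsX", out2, makeLd(r2d, c("rsX", "rsB", "rsA")),
                         cfg), "rsA")
  # absent from LD matrix: none
  expect_true(is.na(findProxy("rsZ", outcome, ld, cfg)))
})

test_that("harmonize maps shared same-orientation SNPs through unchanged", {
  sim <- simulateTaxonInstruments(syntheticScenario(jInstruments = 6,
                                                    seed = 9))
  hs <- harmonize(sim$exposure, sim$outcome, sim$ld)
  expect_equal(nInstruments(hs), 6)
  ins <- instruments(hs)
  es <- snps(sim$exposure); os <- snps(sim$outcome)
  expect_equal(ins$gamma, es$beta[match(ins$rsid, es$rsid)])
  expect_equal(ins$Gamma, os$beta[match(ins$rsid, os$rsid)])
  expect_false(any(ins$is_proxy))
})

test_that("palindromic SNPs are excluded and logged", {
  tab <- makeSnpTable(3)
  tab$effect_allele[2] <- "A"; tab$other_allele[2] <- "T"
  expo <- GwasDataset(tab, "taxon", "exposure")
  outc <- GwasDataset(tab, "disease", "outcome")
  hs <- harmonize(expo, outc)
  expect_false("rs002" %in% instruments(hs)$rsid)
  dl <- dropLog(hs)
  expect_equal(dl$reason[dl$rsid == "rs002"], "palindromic")
})

test_that("missing outcome SNPs are proxied when LD allows", {
  sim <- simulateTaxonInstruments(syntheticScenario(jInstruments = 6,
                                                    seed = 10))
  os <- snps(sim$outcome)
  missing2 <- os$rsid[1:2]
  # add a proxy partner for the first missing SNP only
  proxy_row <- os[1, ]
  proxy_row$rsid <- "rs_proxy"
  os2 <- rbind(os[-(1:2), ], proxy_row)
  outcome <- GwasDataset(os2, "disease", "outcome")
  ids <- c(os$rsid, "rs_proxy")
  r2 <- diag(length(ids)); dimnames(r2) <- list(ids, ids)
  r2[missing2[1], "rs_proxy"] <- r2["rs_proxy", missing2[1]] <- 0.9
  hs <- harmonize(sim$exposure, outcome, LdMatrix(r2))
  expect_equal(nInstruments(hs), 5)   # J - 1: one proxied, one dropped
  ins <- instruments(hs)
  expect_equal(sum(ins$is_proxy), 1)
  expect_equal(ins$proxy_source[ins$is_proxy], missing2[1])
  expect_true(missing2[2] %in% dropLog(hs)$rsid)
})

test_that("harmonization is idempotent", {
  sim <- simulateTaxonInstruments(syntheticScenario(jInstruments = 8,
                                                    seed = 11))
  hs1 <- harmonize(sim$exposure, sim$outcome, sim$ld)
  # re-present the harmonized pair as datasets and harmonize again
  ins <- instruments(hs1)
  es <- snps(sim$exposure); es <- es[match(ins$rsid, es$rsid), ]
  os <- snps(sim$outcome); os <- os[match(ins$rsid, os$rsid), ]
  hs2 <- harmonize(GwasDataset(es, "taxon", "exposure"),
                   GwasDataset(os, "disease", "outcome"), sim$ld)
  expect_equal(instruments(hs2), instruments(hs1))
})

test_that("joint sign flips of an instrument leave estimates unchanged", {
  sim <- simulateTaxonInstruments(syntheticScenario(jInstruments = 8,
                                                    theta = 0.8, seed = 12))
  hs <- harmonize(sim$exposure, sim$outcome, sim$ld)
  ins <- instruments(hs)
  flip <- c(1, 3, 5)
  ins2 <- ins
  ins2$gamma[flip] <- -ins2$gamma[flip]
  ins2$Gamma[flip] <- -ins2$Gamma[flip]
  hs2 <- HarmonizedSet("taxon", "disease", ins2)
  expect_equal(mrIvw(hs2, "fixed")@beta, mrIvw(hs, "fixed")@beta)
  expect_equal(mrEgger(hs2)@beta, mrEgger(hs)@beta)
  expect_equal(mrWeightedMedian(hs2, nBoot = 10, seed = 1)@beta,
               mrWeightedMedian(hs, nBoot = 10, seed = 1)@beta)
})
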