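test_that("model enumeration covers all non-empty subsets with proper priors", {
  en2 <- enumerateModels(2, bmaConfig())
  expect_equal(length(en2$subsets), 3)
  expect_setequal(vapply(en2$subsets, paste, character(1), collapse = ","),
                  c("1", "2", "1,2"))
  expect_equal(sum(en2$prior), 1)
  en4 <- enumerateModels(4, bmaConfig())
  expect_equal(length(en4$subsets), 15)
  expect_equal(sum(en4$prior), 1)
  expect_error(enumerateModels(21, bmaConfig()), "K <= 20")
})

test_that("the union exposure matrix fills missing effects with zeros", {
  s1 <- makeSet(gamma = c(0.1, 0.12, 0.08), Gamma = c(0.05, 0.06, 0.04),
                rsid = c("rs1", "rs2", "rs3"), exposure = "A")
  s2 <- makeSet(gamma = c(0.2, 0.18, 0.22), Gamma = c(0.01, 0.02, 0.01),
                rsid = c("rs4", "rs5", "rs6"), exposure = "B")
  mat <- buildExposureMatrix(list(A = s1, B = s2))
  expect_equal(dim(mat$X), c(6, 2))
  expect_equal(mat$nZeroFilled, 6)
  expect_equal(sum(mat$X[, "A"] != 0), 3)
  # identical instrument sets: no zero fill
  s2b <- makeSet(gamma = c(0.2, 0.18, 0.22), Gamma = c(0.05, 0.06, 0.04),
                 rsid = c("rs1", "rs2", "rs3"), exposure = "B")
  mat2 <- buildExposureMatrix(list(A = s1, B = s2b))
  expect_equal(mat2$nZeroFilled, 0)
  # the study-scale shape: 4 exposures, 41 union SNPs
  sim <- simulateMultiExposure(syntheticScenario(jInstruments = 41, seed = 3),
                               trueEffects = c(0.7, 0, 0, 0))
  expect_equal(dim(sim$mat$X), c(41, 4))
})

test_that("posterior probabilities normalize and identify the true model", {
  sim <- simulateMultiExposure(syntheticScenario(jInstruments = 40, seed = 5),
                               trueEffects = c(0.7, 0, 0, 0))
  models <- modelPosteriors(sim$mat, bmaConfig())
  expect_equal(sum(models$pp), 1, tolerance = 1e-10)
  top <- attr(models, "subsets")[[which.max(models$pp)]]
  expect_true(1 %in% top)
})

test_that("MIP equals the sum of containing-model PPs (arithmetic oracle)", {
  sim <- simulateMultiExposure(syntheticScenario(jInstruments = 30, seed = 6),
                               trueEffects = c(0.5, 0, 0))
  models <- modelPosteriors(sim$mat, bmaConfig())
  summ <- mipMace(models, sim$mat$exposures)
  subsets <- attr(models, "subsets")
  for (k in 1:3) {
    oracle <- sum(models$pp[vapply(subsets, function(s) k %in% s,
                                   logical(1))])
    expect_equal(summ$mip[k], oracle, tolerance = 1e-12)
    expect_true(summ$mip[k] >= 0 && summ$mip[k] <= 1)
  }
  expect_setequal(summ$rankByMip, 1:3)
  # hand-summed toy check on 3 models over 2 exposures
  toy <- data.frame(model = c("1", "2", "1,2"), size = c(1, 1, 2),
                    pp = c(0.5, 0.3, 0.2))
  attr(toy, "subsets") <- list(1L, 2L, c(1L, 2L))
  attr(toy, "coefs") <- list(0.4, 0.1, c(0.35, 0.05))
  ts <- mipMace(toy, c("A", "B"))
  expect_equal(ts$mip, c(0.7, 0.5))
  expect_equal(ts$mace, c(0.5 * 0.4 + 0.2 * 0.35, 0.3 * 0.1 + 0.2 * 0.05))
  expect_equal(ts$causalEstimate, c(0.4, 0.1))  # top containing model
})

test_that("duplicating an exposure column splits its inclusion mass", {
  sim <- simulateMultiExposure(syntheticScenario(jInstruments = 40, seed = 8),
                               trueEffects = c(0.7, 0))
  mat <- sim$mat
  models <- modelPosteriors(mat, bmaConfig())
  mip1 <- mipMace(models, mat$exposures)$mip[1]
  dup <- mat
  dup$X <- cbind(mat$X, dup1 = mat$X[, 1])
  dup$exposures <- c(mat$exposures, "dup1")
  mips <- mipMace(modelPosteriors(dup, bmaConfig()), dup$exposures)$mip
  expect_true(mips[1] < mip1)
  expect_true(mips[3] < mip1)
  expect_true(sum(mips[c(1, 3)]) > 0.8 * mip1)
})

test_that("joint scaling of outcome and SEs leaves PPs and ranks unchanged", {
  sim <- simulateMultiExposure(syntheticScenario(jInstruments = 30, seed = 9),
                               trueEffects = c(0.5, 0, 0))
  m1 <- modelPosteriors(sim$mat, bmaConfig())
  sc <- sim$mat
  sc$y <- sc$y * 3.7; sc$seY <- sc$seY * 3.7
  m2 <- modelPosteriors(sc, bmaConfig())
  expect_equal(m2$pp, m1$pp, tolerance = 1e-10)
  s1 <- mipMace(m1, sim$mat$exposures); s2 <- mipMace(m2, sc$exposures)
  expect_equal(s2$rankByMip, s1$rankByMip)
})

test_that("shrinkage limit: as the prior scale vanishes, the prior dominates", {
  sim <- simulateMultiExposure(syntheticScenario(jInstruments = 30, seed = 10),
                               trueEffects = c(0.5, 0, 0))
  cfg <- bmaConfig(priorSd = 1e-8)
  models <- modelPosteriors(sim$mat, cfg)
  en <- enumerateModels(3, cfg)
  expect_equal(models$pp, en$prior, tolerance = 1e-4)
})

test_that("per-SNP diagnostics compute squared standardized residuals", {
  # exact fit: all q_j = 0 under a near-flat prior
  X <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.05, 0.1, 0.02, 0.3), 4, 2)
  y <- X %*% c(0.5, 0)
  mat <- list(snpIds = sprintf("rs%d", 1:4), X = X, y = drop(y),
              seY = rep(0.05, 4), exposures = c("A", "B"), nZeroFilled = 0L)
  cfg <- bmaConfig()
  models <- modelPosteriors(mat, cfg)
  # restrict diagnostics to the top model: exact fit leaves all q tiny
  top <- bmaConfig(ppThreshold = max(models$pp) - 1e-9)
  d <- snpDiagnostics(mat, models, top)
  expect_true(all(d$table$maxQ < 0.5))
  expect_equal(length(d$outliers), 0)
  # a residual of 4 SEs gives q = 16 > 10 and flags the SNP
  mat2 <- mat
  mat2$y[2] <- mat2$y[2] + 4 * mat2$seY[2]
  models2 <- modelPosteriors(mat2, cfg)
  d2 <- snpDiagnostics(mat2, models2, cfg)
  expect_true(d2$table$maxQ[2] > 10)
  expect_true("rs2" %in% d2$outliers)
})

test_that("permutation p-values land on the 1/(nPerm+1) grid", {
  sim <- simulateMultiExposure(syntheticScenario(jInstruments = 25, seed = 11),
                               trueEffects = c(0.7, 0, 0))
  cfg <- bmaConfig(nPerm = 100, seed = 11)
  res <- mrBma(sim$mat, cfg)
  p <- res$summary$permPval
  expect_true(all(abs(p * 101 - round(p * 101)) < 1e-9))
  expect_true(all(p >= 1 / 101))
  # a dominant exposure beats every permutation: p = 1/101
  expect_equal(min(p), 1 / 101)
})

test_that("iterative BMA stops immediately on clean data", {
  sim <- simulateMultiExposure(syntheticScenario(jInstruments = 30, seed = 12),
                               trueEffects = c(0.6, 0, 0))
  res <- runBmaIterative(sim$mat, bmaConfig(nPerm = 20, seed = 12, cooksRule = 0.5))
  expect_equal(length(res@iterations), 1)
  expect_equal(res@excluded, list(character()))
})

test_that("iterative BMA removes a planted outlier in one extra round", {
  sim <- simulateMultiExposure(syntheticScenario(jInstruments = 30, seed = 13),
                               trueEffects = c(0.6, 0, 0))
  mat <- sim$mat
  j <- 7
  mat$y[j] <- mat$y[j] + 8 * mat$seY[j]
  res <- runBmaIterative(mat, bmaConfig(nPerm = 20, seed = 13, cooksRule = 0.5))
  expect_equal(length(res@iterations), 2)
  expect_true(mat$snpIds[j] %in% res@excluded[[2]])
  # second iteration runs on J - removed SNPs
  expect_equal(length(bmaSummary(res)$exposure), 3)
})
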