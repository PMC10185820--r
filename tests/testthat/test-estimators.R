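test_that("Wald ratio arithmetic and derived OR/CI are consistent", {
  e <- waldRatio(gamma = 0.1, Gamma = 0.2, seGamma = 0.05)
  expect_equal(e@beta, 2.0)
  expect_equal(e@se, 0.5)
  expect_equal(waldRatio(0.1, 0, 0.05)@beta, 0)
  expect_error(waldRatio(0, 0.1, 0.05), "gamma = 0")
  # sign(beta) = sign(Gamma) * sign(gamma) on a random grid
  set.seed(1)
  g <- runif(50, -1, 1); G <- runif(50, -1, 1)
  g[g == 0] <- 0.1
  b <- mapply(function(x, y) waldRatio(x, y, 0.1)@beta, g, G)
  expect_equal(sign(b), sign(G) * sign(g))
  # OR = exp(beta) and log-symmetric CI
  expect_equal(orValue(e), exp(e@beta))
  ci <- ci95(e)
  expect_equal(ci[1], orValue(e)^2 / ci[2], tolerance = 1e-12)
})

test_that("IVW degenerates to the Wald ratio for one instrument", {
  s <- makeSet(0.1, 0.05, seGammaOut = 0.02)
  e <- mrIvw(s)
  w <- waldRatio(0.1, 0.05, 0.02)
  expect_equal(e@beta, w@beta)
  expect_equal(e@se, w@se)
})

test_that("IVW reproduces the hand-computed equal-ratio instance", {
  s <- makeSet(gamma = c(0.1, 0.2, 0.15), Gamma = c(0.05, 0.10, 0.075),
               seGamma = rep(0.01, 3), seGammaOut = rep(0.02, 3))
  e <- mrIvw(s, mode = "fixed")
  expect_equal(e@beta, 0.5)
  expect_equal(e@extra$Q, 0)
  expect_equal(cochranQ(s)$pval, 1)
})

test_that("IVW equals the precision-weighted mean and the WLS slope", {
  set.seed(7)
  for (rep in 1:10) {
    J <- sample(3:12, 1)
    g <- runif(J, 0.02, 0.2) * sample(c(-1, 1), J, TRUE)
    G <- 0.4 * g + rnorm(J, 0, 0.05)
    sG <- runif(J, 0.02, 0.1)
    s <- makeSet(g, G, seGammaOut = sG)
    e <- mrIvw(s, mode = "fixed")
    # oracle 1: precision-weighted mean of Wald ratios
    w <- g^2 / sG^2
    expect_equal(e@beta, sum(w * (G / g)) / sum(w), tolerance = 1e-12)
    # oracle 2: zero-intercept WLS of Gamma on gamma, weights 1/sG^2
    fit <- lm(G ~ g - 1, weights = 1 / sG^2)
    expect_equal(e@beta, unname(coef(fit)), tolerance = 1e-12)
  }
})

test_that("random-effects IVW inflates the SE only under heterogeneity", {
  s <- makeSet(gamma = c(0.1, 0.2, 0.15, 0.12), Gamma = c(0.09, 0.02, 0.11, -0.06),
               seGammaOut = rep(0.02, 4))
  ef <- mrIvw(s, mode = "fixed"); er <- mrIvw(s, mode = "random")
  expect_equal(er@beta, ef@beta)
  expect_true(er@se >= ef@se)
  # homogeneous ratios: random-effects floor keeps the fixed SE
  s0 <- makeSet(gamma = c(0.1, 0.2, 0.15), Gamma = c(0.05, 0.10, 0.075))
  expect_equal(mrIvw(s0, mode = "random")@se, mrIvw(s0, mode = "fixed")@se)
})

test_that("Egger recovers exact linear and affine generating models", {
  g <- c(0.05, 0.1, 0.15, 0.2, 0.25)
  s <- makeSet(g, 0.3 * g)
  e <- mrEgger(s)
  expect_equal(e@beta, 0.3, tolerance = 1e-10)
  expect_equal(e@extra$intercept, 0, tolerance = 1e-10)
  s2 <- makeSet(g, 0.05 + 0.3 * g)
  e2 <- mrEgger(s2)
  expect_equal(e2@beta, 0.3, tolerance = 1e-10)
  expect_equal(e2@extra$intercept, 0.05, tolerance = 1e-10)
  expect_error(mrEgger(makeSet(g[1:2], g[1:2])), ">= 3")
})

test_that("Egger matches a generic two-parameter WLS oracle", {
  set.seed(11)
  for (rep in 1:10) {
    J <- sample(4:15, 1)
    g <- runif(J, 0.03, 0.2)     # positive: orientation is identity
    G <- 0.02 + 0.5 * g + rnorm(J, 0, 0.03)
    sG <- runif(J, 0.02, 0.08)
    s <- makeSet(g, G, seGammaOut = sG)
    e <- mrEgger(s)
    fit <- lm(G ~ g, weights = 1 / sG^2)
    expect_equal(e@beta, unname(coef(fit)[2]), tolerance = 1e-12)
    expect_equal(e@extra$intercept, unname(coef(fit)[1]), tolerance = 1e-12)
  }
})

test_that("weighted median interpolates the cumulative weight at one half", {
  # equal weights, ratios {1, 2, 9}: the middle value
  s <- makeSet(gamma = rep(0.1, 3), Gamma = c(0.1, 0.2, 0.9))
  expect_equal(mrWeightedMedian(s, nBoot = 10, seed = 1)@beta, 2)
  # dominant middle instrument (60% of weight, symmetric bracket): its ratio
  w_target <- c(0.2, 0.6, 0.2)
  sG <- 0.1 / sqrt(w_target)    # weight = gamma^2/sG^2 with gamma = 0.1
  s2 <- makeSet(gamma = rep(0.1, 3), Gamma = c(0.1, 0.25, 0.9),
                seGammaOut = sG)
  expect_equal(mrWeightedMedian(s2, nBoot = 10, seed = 1)@beta, 2.5)
})

test_that("weighted-median bootstrap SE is stable across implementations", {
  set.seed(5)
  J <- 8
  g <- runif(J, 0.05, 0.2)
  G <- 0.4 * g + rnorm(J, 0, 0.03)
  sg <- rep(0.012, J); sG <- rep(0.04, J)
  s <- makeSet(g, G, seGamma = sg, seGammaOut = sG)
  est <- mrWeightedMedian(s, nBoot = 2000, seed = 42)
  # independent high-rep bootstrap oracle with its own median routine
  wmed <- function(b, w) {
    o <- order(b); b <- b[o]; p <- w[o] / sum(w)
    H <- cumsum(p) - p / 2
    if (H[1] >= 0.5) return(b[1])
    if (H[length(b)] <= 0.5) return(b[length(b)])
    k <- max(which(H < 0.5))
    b[k] + (b[k + 1] - b[k]) * (0.5 - H[k]) / (H[k + 1] - H[k])
  }
  set.seed(99)
  reps <- replicate(10000, {
    gs <- rnorm(J, g, sg); Gs <- rnorm(J, G, sG)
    wmed(Gs / gs, gs^2 / sG^2)
  })
  expect_equal(est@beta, wmed(G / g, g^2 / sG^2), tolerance = 1e-12)
  expect_equal(est@se, sd(reps), tolerance = 0.15 * sd(reps))
  # same seed reproduces the SE exactly
  expect_equal(mrWeightedMedian(s, nBoot = 2000, seed = 42)@se, est@se)
})

test_that("Wald p reconstructed from a 95% CI matches reported precision", {
  expect_equal(round(waldPFromCi(1.671, 7.209)$pval, 4), 8e-04)
  expect_equal(round(waldPFromCi(0.238, 0.875)$pval, 3), 0.018)
  sym <- waldPFromCi(0.5, 2.0)
  expect_equal(sym$beta, 0)
  expect_equal(sym$pval, 1)
  expect_error(waldPFromCi(2, 1))
})

test_that("significance classification follows the two-tier rule", {
  mk <- function(p, sgn = 1) {
    se <- 0.3
    b <- sgn * qnorm(1 - p / 2) * se
    waldRatio(1, b, se)
  }
  clean <- list(eggerIntercept = list(pval = 0.9), presso = list(outliers = character()))
  # IVW p=0.018, WM p=0.023 same direction, clean -> significant
  expect_equal(classifySignificance(mk(0.018), list(mk(0.023)), clean)$level,
               "significant")
  # IVW p=0.038, WM p=0.155, Egger p=0.645 -> nominal only
  expect_equal(classifySignificance(mk(0.038), list(mk(0.155), mk(0.645)),
                                    clean)$level, "nominal")
  # IVW p=0.20 -> none
  expect_equal(classifySignificance(mk(0.20), list(mk(0.01)), clean)$level,
               "none")
  # discordant direction does not count as support
  expect_equal(classifySignificance(mk(0.01), list(mk(0.01, sgn = -1)),
                                    clean)$level, "nominal")
  # dirty sensitivity blocks the upgrade
  dirty <- list(eggerIntercept = list(pval = 0.01),
                presso = list(outliers = character()))
  expect_equal(classifySignificance(mk(0.01), list(mk(0.01)), dirty)$level,
               "nominal")
})
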