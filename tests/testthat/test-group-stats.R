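randomTable <- function(seed, n = 6, a = 4, b = 5) {
  set.seed(seed)
  d <- expand.grid(subject = paste0("s", seq_len(n)),
                   condition = paste0("c", seq_len(a)),
                   threshold = paste0("t", seq_len(b)))
  d$value <- rnorm(nrow(d)) + rep(rnorm(n), a * b)
  d
}

test_that("two-way RM-ANOVA F values match the aov error-strata oracle", {
  for (s in 1:10) {
    d <- randomTable(s)
    res <- rmAnova(d)
    oF <- oracleRmAnovaF(d)
    expect_equal(res$effects$F, unname(oF), tolerance = 1e-8)
  }
})

test_that("degenerate tables are flagged rather than mis-reported", {
  d <- randomTable(1)
  d$value <- 1
  res <- rmAnova(d)
  expect_equal(res$effects$F, c(0, 0, 0))

  ## constant condition offset with zero residual: F explodes, flagged
  d2 <- randomTable(2)
  d2$value <- as.numeric(d2$condition == "c1")
  res2 <- rmAnova(d2)
  expect_true(is.infinite(res2$effects$F[1]))
  expect_true(res2$effects$degenerate[1])
  expect_equal(res2$effects$p[1], 0)
})

test_that("sphericity epsilons respect their defining inequalities", {
  triv <- sphericityEpsilons(matrix(2, 1, 1), n = 10)
  expect_equal(triv$ggEpsilon, 1)
  expect_equal(triv$hfEpsilon, 1)
  expect_true(is.na(triv$p))

  idt <- sphericityEpsilons(diag(3), n = 12)
  expect_equal(idt$ggEpsilon, 1, tolerance = 1e-12)
  expect_gt(idt$p, 0.99)

  for (s in 1:20) {
    set.seed(s)
    k <- sample(3:6, 1)
    x <- matrix(rnorm(40 * (k - 1)), 40)
    cc <- cov(x %*% matrix(rnorm((k - 1)^2), k - 1))
    eps <- sphericityEpsilons(cc, n = 40)
    expect_gte(eps$ggEpsilon, 1 / (k - 1) - 1e-12)
    expect_lte(eps$ggEpsilon, 1 + 1e-12)
    expect_gte(eps$hfEpsilon, eps$ggEpsilon - 1e-12)
    expect_true(eps$p >= 0 && eps$p <= 1)
  }
})

test_that("partial omega-squared follows its closed form", {
  expect_equal(partialOmegaSquared(1, 3, 48), 0)
  expect_equal(partialOmegaSquared(10, 3, 48), 27 / 75)
  expect_equal(partialOmegaSquared(1e9, 3, 48), 1, tolerance = 1e-6)
  expect_equal(partialOmegaSquared(0.2, 3, 48), 0)   # clipped at 0
})

test_that("Sidak adjustment matches its closed form and is monotone", {
  set.seed(3)
  scores <- matrix(rnorm(40), 10, 4)
  pw <- sidakPairwise(scores)
  expect_equal(nrow(pw), 6)
  expect_equal(pw$pSidak, 1 - (1 - pw$p)^6, tolerance = 1e-12)
  expect_true(all(pw$pSidak >= pw$p))
  expect_true(all(pw$pSidak <= 1))
  ## m = 1 leaves p unchanged
  one <- sidakPairwise(scores[, 1:2])
  expect_equal(one$pSidak, one$p)
  ## closed form at p = 0.01, m = 6
  expect_equal(1 - (1 - 0.01)^6, 0.0585198506, tolerance = 1e-9)
})

test_that("per-threshold follow-ups produce one calibrated test per level", {
  d <- randomTable(4)
  res <- perThresholdAnovas(d)
  expect_length(res, 5)
  expect_true(all(vapply(res, function(r)
    r$effects$effect[1] == "condition", logical(1))))

  ## null calibration of the condition test across simulated tables
  hits <- 0; total <- 0
  for (s in 1:80) {
    res <- perThresholdAnovas(randomTable(100 + s, n = 12))
    ps <- vapply(res, function(r) r$effects$p[1], numeric(1))
    hits <- hits + sum(ps < 0.05)
    total <- total + length(ps)
  }
  rate <- hits / total
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / total))
})

test_that("node-wise FDR reproduces the Benjamini-Yekutieli oracle", {
  expect_true(all(nodewiseFdr(rep(0, 5))$rejected))
  expect_identical(nodewiseFdr(0.04, q = 0.05)$rejected, TRUE)
  expect_identical(nodewiseFdr(0.06, q = 0.05)$rejected, FALSE)
  for (s in 1:20) {
    set.seed(s)
    p <- runif(30)^sample(1:3, 1)
    res <- nodewiseFdr(p, q = 0.05)
    expect_identical(res$rejected, oracleBY(p, 0.05))
    expect_true(all(res$adjustedP >= p - 1e-12))
    expect_true(all(res$adjustedP <= 1))
    expect_true(all(diff(res$adjustedP[order(p)]) >= -1e-12))  # order-preserving
  }
})

test_that("the distance ANCOVA recovers planted condition and distance nulls", {
  a <- makeAtlas(40, seed = 6)
  d <- euclideanDistances(a)
  ident <- lapply(conditionLevels(), effectSpec)
  names(ident) <- conditionLevels()
  mkBins <- function(tr, gainS = 1, seed) {
    eff <- ident
    eff$S <- effectSpec("S", globalGain = gainS)
    trx <- makeGroundTruth(a, nModules = 3, lambda = tr, effects = eff,
                           seed = 6)
    st <- suppressWarnings(simulateStudy(a, trx, nSubjects = 8,
                                         nTimepoints = 150, seed = seed))
    m <- studyConnectivity(st)
    mf <- studyManifest(st)
    bt <- NULL
    for (k in seq_along(m)) {
      bb <- binByDistance(m[[k]], d, binWidth = 18, nBins = 8)
      bt <- rbind(bt, data.frame(subject = mf$subject[k],
                                 condition = mf$condition[k], bb))
    }
    names(bt)[names(bt) == "meanR"] <- "meanR"
    bt
  }
  ## distance decay present: strong distance effect
  bt <- suppressWarnings(mkBins(60, gainS = 0.7, seed = 10))
  res <- suppressWarnings(rmAncovaDistance(bt))
  eff <- res$ancova
  expect_equal(sort(eff$effect),
               sort(c("condition", "center", "condition:center")))
  expect_lt(eff$p[eff$effect == "center"], 0.01)
  expect_lt(eff$p[eff$effect == "condition"], 0.01)
  expect_length(res$perBin, length(res$binsUsed))

  ## lambda -> Inf: distance effect at the null rate (not significant here)
  btI <- suppressWarnings(mkBins(Inf, gainS = 1, seed = 11))
  resI <- suppressWarnings(rmAncovaDistance(btI))
  expect_gt(resI$ancova$p[resI$ancova$effect == "center"], 0.01)

  ## empty bins dropped with a warning
  btE <- bt
  btE$meanR[btE$bin == 7] <- NA
  expect_warning(rmAncovaDistance(btE), "empty")
})
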