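test_that("feature vectorization is the row-major upper triangle", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.12
  m[1, 3] <- m[3, 1] <- 0.13
  m[2, 3] <- m[3, 2] <- 0.23
  expect_equal(vectorizeFeatures(m), c(0.12, 0.13, 0.23))
  m4 <- matrix(rnorm(16), 4); m4 <- m4 + t(m4); diag(m4) <- 0
  v <- vectorizeFeatures(m4)
  expect_equal(v, c(m4[1, 2], m4[1, 3], m4[1, 4], m4[2, 3], m4[2, 4], m4[3, 4]))
  expect_equal(devectorizeFeatures(v, 4), m4)
  expect_equal(length(vectorizeFeatures(matrix(0, 194, 194))), 18721)
})

test_that("leave-one-subject-out SVM separates a strong planted effect", {
  st <- toyStudy(nROI = 20, nSubjects = 12, nT = 120, seed = 5)
  m <- studyConnectivity(st)
  mf <- studyManifest(st)
  gA <- m[mf$condition == "S"]
  gB <- m[mf$condition == "LOC"]
  res <- loocvClassify(gA, gB)
  expect_equal(nrow(res@folds), 24)
  expect_equal(length(unique(res@folds$subject)), 12)
  expect_gte(res@accuracy, 90)
  expect_equal(res@accuracy, 100 * mean(res@folds$correct))
  expect_equal(res@comparison, "S vs LOC")
  expect_lt(max(abs(res@weightMatrix - t(res@weightMatrix))), 1e-10)

  ## label symmetry: swapping groups swaps sensitivity/specificity and
  ## negates the hyperplane (up to solver tolerance)
  rev <- loocvClassify(gB, gA)
  expect_equal(res@sensitivity, rev@specificity)
  expect_equal(res@specificity, rev@sensitivity)
  expect_lt(max(abs(res@weightMatrix + rev@weightMatrix)),
            0.05 * max(abs(res@weightMatrix)) + 1e-8)

  expect_error(loocvClassify(gA, gB[1:6]), "equal size")
  gBad <- gB
  gBad[[1]]@subject <- "nobody"
  expect_error(loocvClassify(gA, gBad), "paired")
})

test_that("permutation test is valid, smoothed and seed-deterministic", {
  st <- toyStudy(nROI = 16, nSubjects = 6, nT = 100, seed = 9)
  m <- studyConnectivity(st)
  mf <- studyManifest(st)
  gA <- m[mf$condition == "S"]
  gB <- m[mf$condition == "LOC"]
  res <- loocvClassify(gA, gB)
  p1 <- permutationTest(res, gA, gB, nPerm = 60, seed = 3, familySize = 4)
  p2 <- permutationTest(res, gA, gB, nPerm = 60, seed = 3, familySize = 4)
  expect_identical(p1@pPerm, p2@pPerm)
  expect_gte(p1@pPerm, 1 / 61)
  expect_lte(p1@pPerm, 1)
  expect_equal(p1@pBonferroni, min(1, p1@pPerm * 4))
  expect_error(permutationTest(res, gA, gB, nPerm = 0), "nPerm")
})

test_that("no-effect studies give chance accuracy and calibrated p values", {
  ident <- lapply(conditionLevels(), effectSpec)
  names(ident) <- conditionLevels()
  nSim <- 100
  acc <- numeric(nSim)
  pv <- numeric(nSim)
  for (s in seq_len(nSim)) {
    st <- toyStudy(nROI = 12, nSubjects = 6, nT = 40, seed = 1000 + s,
                   effects = ident)
    m <- studyConnectivity(st)
    mf <- studyManifest(st)
    gA <- m[mf$condition == "W"]
    gB <- m[mf$condition == "S"]
    res <- loocvClassify(gA, gB)
    acc[s] <- res@accuracy
    pv[s] <- permutationTest(res, gA, gB, nPerm = 99, seed = s)@pPerm
  }
  ## accuracy distribution centred on 50%
  expect_lt(abs(mean(acc) - 50), 6)
  ## empirical type-I error at alpha = 0.05 within a 3-sigma binomial band
  rate <- mean(pv <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nSim) + 1 / nSim)
})

test_that("importance maps partition the weight support by contribution", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.6            # single positive entry
  res <- new("ClassificationResult", comparison = "A vs B",
             folds = data.frame(subject = c("s1", "s2", "s1", "s2"),
                                class = c("A", "A", "B", "B"),
                                predicted = c("A", "A", "B", "B"),
                                correct = rep(TRUE, 4)),
             accuracy = 100, sensitivity = 100, specificity = 100,
             weightMatrix = w, pPerm = NA_real_, pBonferroni = NA_real_,
             nPerm = 0L, cost = 1)
  mk <- function(v, sub, cond) {
    m <- matrix(v, 4, 4); diag(m) <- 1
    new("ConnectivityMatrix", values = m, subject = sub, condition = cond)
  }
  gA <- list(mk(0.5, "s1", "W"), mk(0.4, "s2", "W"))
  gB <- list(mk(0.3, "s1", "S"), mk(0.2, "s2", "S"))
  maps <- importanceMaps(res, gA, gB)
  expect_equal(sum(maps$mapA != 0), 2)  # the single edge, symmetric
  expect_equal(maps$mapA[1, 2], 0.6 * 0.45)
  expect_equal(sum(maps$mapB != 0), 0)

  ## random weights: supports are disjoint and cover the weight support
  st <- toyStudy(nROI = 14, nSubjects = 5, nT = 60, seed = 21)
  m <- studyConnectivity(st)
  mf <- studyManifest(st)
  gA2 <- m[mf$condition == "S"]
  gB2 <- m[mf$condition == "LOC"]
  r2 <- loocvClassify(gA2, gB2)
  mp <- importanceMaps(r2, gA2, gB2)
  sa <- mp$mapA != 0
  sb <- mp$mapB != 0
  expect_false(any(sa & sb))
  expect_equal(sa | sb, r2@weightMatrix != 0)
})

test_that("top edges and the anatomical taxonomy are exact and conserved", {
  set.seed(8)
  w <- matrix(rnorm(194^2), 194)
  w <- w + t(w); diag(w) <- 0
  top <- topEdges(w, 0.01)
  expect_equal(nrow(top), 187)                       # round(0.01 * 18721)
  vAbs <- sort(abs(w[upper.tri(w)]), decreasing = TRUE)
  expect_equal(min(abs(top$weight)), vAbs[187])
  expect_identical(top, topEdges(w, 0.01))           # deterministic
  allE <- topEdges(w, 1)
  expect_equal(nrow(allE), sum(w[upper.tri(w)] != 0))

  a <- ROIAtlas(0:3, letters[1:4], c("Thl", "Fcx", "Pcx", "BG"),
                x = 1:4, y = 1:4, z = 1:4)
  edges <- data.frame(i = c(1, 2, 2), j = c(2, 3, 4), weight = c(1, -1, 0.5))
  sgn <- matrix(1, 4, 4)
  sgn[2, 3] <- sgn[3, 2] <- -1
  kinds <- classifyEdgeKinds(edges, a, sgn)
  expect_equal(sum(kinds$count), 3)
  expect_true("thalamo-cortical, positive" %in% kinds$kind)
  expect_true("cortico-cortical, negative" %in% kinds$kind)
  expect_true("striato-cortical, positive" %in% kinds$kind)
})

test_that("edge-kind distributions compare by plain Pearson chi-square", {
  k1 <- data.frame(kind = c("a", "b"), count = c(5, 7))
  same <- compareEdgeDistributions(k1, k1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  k2 <- data.frame(kind = c("a", "b"), count = c(10, 0))
  k3 <- data.frame(kind = c("a", "b"), count = c(0, 10))
  res <- compareEdgeDistributions(k2, k3)
  expect_equal(res$chi2, 20)                         # sum (O-E)^2 / E by hand
  expect_equal(res$df, 1)

  k4 <- data.frame(kind = c("a", "b", "c", "zz"), count = c(3, 4, 5, 0))
  k5 <- data.frame(kind = c("a", "b", "c", "zz"), count = c(5, 2, 6, 0))
  expect_equal(compareEdgeDistributions(k4, k5)$df, 2)  # zero kind dropped
})
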