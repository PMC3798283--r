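test_that("makeAtlas apportions subdivisions and is seed-deterministic", {
  a <- makeAtlas(194, seed = 5)
  expect_equal(nROI(a), 194)
  expect_true(all(table(subdivisions(a)) > 0))

  eq <- makeAtlas(8, subdivisionFractions = setNames(rep(1 / 8, 8),
                                                     subdivisionLevels()),
                  seed = 1)
  expect_equal(as.vector(table(subdivisions(eq))), rep(1L, 8))

  expect_identical(as.data.frame(makeAtlas(50, seed = 9)),
                   as.data.frame(makeAtlas(50, seed = 9)))
  expect_false(identical(coords(makeAtlas(50, seed = 9)),
                         coords(makeAtlas(50, seed = 10))))

  badFrac <- setNames(rep(0.2, 8), subdivisionLevels())
  expect_error(makeAtlas(50, subdivisionFractions = badFrac), "sum to 1")
})

test_that("simulated studies are reproducible and correctly shaped", {
  a <- makeAtlas(20, seed = 2)
  tr <- makeGroundTruth(a, nModules = 3, seed = 2)
  s1 <- suppressWarnings(simulateStudy(a, tr, nSubjects = 3,
                                       nTimepoints = 50, seed = 4))
  s2 <- suppressWarnings(simulateStudy(a, tr, nSubjects = 3,
                                       nTimepoints = 50, seed = 4))
  expect_identical(lapply(panels(s1), slot, "data"),
                   lapply(panels(s2), slot, "data"))
  expect_equal(length(panels(s1)), 12)
  expect_true(all(vapply(panels(s1), function(p) dim(p@data), c(1L, 1L)) ==
                    c(50L, 20L)))
  expect_true(sum(tabulate(tr$moduleAssignment)) == 20)

  s3 <- suppressWarnings(simulateStudy(a, tr, nSubjects = 3,
                                       nTimepoints = 50, seed = 5))
  expect_false(identical(panels(s1)[[1]]@data, panels(s3)[[1]]@data))
})

test_that("identity effects make the four conditions exchangeable", {
  a <- makeAtlas(16, seed = 3)
  ident <- lapply(conditionLevels(), effectSpec)
  names(ident) <- conditionLevels()
  tr <- makeGroundTruth(a, nModules = 2, effects = ident, seed = 3)
  deltas <- vapply(c(120L, 600L), function(nT) {
    st <- suppressWarnings(simulateStudy(a, tr, nSubjects = 8,
                                         nTimepoints = nT, seed = 6))
    m <- studyConnectivity(st)
    mf <- studyManifest(st)
    mw <- meanConnectivity(m[mf$condition == "W"])
    ml <- meanConnectivity(m[mf$condition == "LOC"])
    max(abs(mw - ml))
  }, numeric(1))
  expect_lt(deltas[2], deltas[1])     # max |delta r| shrinks as T grows
  expect_lt(deltas[2], 0.25)
})

test_that("planted negative fraction meets its target in expectation", {
  a <- makeAtlas(194, seed = 2)
  ## expected (noiseless) fraction over many anti-set draws
  tr <- makeGroundTruth(a, seed = 2)
  base <- stateFC:::.baseCouplings(a, tr, 99L)
  fracs <- vapply(1:20, function(s) {
    app <- stateFC:::.applyEffect(base, tr$effects$LOC, a, tr, s)
    mean(stateFC:::.upperValues(app$coupling) < 0)
  }, numeric(1))
  expect_true(all(abs(fracs - 0.14) < 0.03))
  ## observed fraction in the mean LOC matrix at long T
  st <- suppressWarnings(simulateStudy(a, tr, nSubjects = 2,
                                       nTimepoints = 2000, seed = 31))
  m <- studyConnectivity(st)
  mf <- studyManifest(st)
  obs <- correlationSummary(m[mf$condition == "LOC"])$propNegative
  expect_true(abs(obs - 0.14) < 0.03)
})

test_that("generated correlations decay with distance when lambda is finite", {
  a <- makeAtlas(60, seed = 4)
  ident <- lapply(conditionLevels(), effectSpec)
  names(ident) <- conditionLevels()
  trF <- makeGroundTruth(a, nModules = 3, lambda = 60, effects = ident,
                         seed = 4)
  trI <- makeGroundTruth(a, nModules = 3, lambda = Inf, effects = ident,
                         seed = 4)
  d <- euclideanDistances(a)
  binMeans <- function(tr) {
    st <- suppressWarnings(simulateStudy(a, tr, nSubjects = 6,
                                         nTimepoints = 400, seed = 8))
    m <- studyConnectivity(st)
    bt <- binByDistance(asConn(meanConnectivity(m)), d, binWidth = 9,
                        nBins = 15)
    bt$meanR[!is.na(bt$meanR) & bt$nPairs > 10]
  }
  bF <- binMeans(trF)
  ## monotone decreasing trend over the well-populated bins
  expect_lt(stats::cor(seq_along(bF), bF, method = "spearman"), -0.8)
  bI <- binMeans(trI)
  expect_lt(diff(range(bI)), 0.15)   # flat when lambda -> Inf
})
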