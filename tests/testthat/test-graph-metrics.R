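mkGraph <- function(w, density = 0.5) {
  new("BrainGraph", weights = w, density = density, subject = "s",
      condition = "W", provenance = list())
}

test_that("shortest functional paths invert weights and handle disconnection", {
  tri <- matrix(0, 3, 3)
  tri[upper.tri(tri)] <- 1
  tri <- tri + t(tri)
  d <- shortestFunctionalPaths(mkGraph(tri))
  expect_equal(d[upper.tri(d)], rep(1, 3))

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  dp <- shortestFunctionalPaths(mkGraph(path))
  expect_equal(dp[1, 3], 2)

  dyads <- matrix(0, 4, 4)
  dyads[1, 2] <- dyads[2, 1] <- 0.5
  dyads[3, 4] <- dyads[4, 3] <- 0.5
  dd <- shortestFunctionalPaths(mkGraph(dyads))
  expect_equal(dd[1, 2], 2)
  expect_true(is.infinite(dd[1, 3]))
})

test_that("path length, efficiency and strength match closed forms", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(charPathLength(mkGraph(tri))$L, 1)
  expect_equal(globalEfficiency(mkGraph(tri)), 1)

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  expect_equal(charPathLength(mkGraph(path))$L, 4 / 3)   # (1+1+2)/3

  ## halving all weights doubles L (ell = 1/w scaling law)
  g <- randomWeightedGraph(10, 0.6, seed = 3)
  expect_equal(charPathLength(mkGraph(g / 2))$L,
               2 * charPathLength(mkGraph(g))$L, tolerance = 1e-12)

  dyads <- matrix(0, 4, 4)
  dyads[1, 2] <- dyads[2, 1] <- 1
  dyads[3, 4] <- dyads[4, 3] <- 1
  expect_equal(globalEfficiency(mkGraph(dyads)), 4 / 12)  # cross pairs give 0
  cl <- suppressWarnings(charPathLength(mkGraph(dyads)))
  expect_equal(cl$fractionUnreachable, 8 / 12)
  expect_warning(charPathLength(mkGraph(dyads)), "unreachable")

  expect_equal(nodalStrength(mkGraph(dyads)), c(1, 1, 1, 1))
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.3
  expect_equal(nodalStrength(mkGraph(w))[1], 0.8)
  expect_equal(sum(nodalStrength(mkGraph(g))), 2 * sum(g[upper.tri(g)]))
})

test_that("clustering and local efficiency hit their boundary cases", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  cc <- clusteringOnnela(mkGraph(tri))
  expect_equal(cc$Ci, rep(1, 3))

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 0.7
  expect_equal(clusteringOnnela(mkGraph(star))$Ci, rep(0, 5))

  comp <- matrix(0.6, 6, 6); diag(comp) <- 0
  expect_equal(localEfficiency(mkGraph(comp)), rep(1, 6), tolerance = 1e-12)
  pend <- matrix(0, 3, 3)
  pend[1, 2] <- pend[2, 1] <- 0.9
  expect_equal(localEfficiency(mkGraph(pend)), c(0, 0, 0))
})

test_that("weighted metrics match brute-force oracles on random graphs", {
  for (s in 1:20) {
    n <- sample(8:12, 1)
    w <- randomWeightedGraph(n, 0.5, seed = s)
    if (sum(w) == 0) next
    d <- shortestFunctionalPaths(mkGraph(w))
    expect_equal(d, oracleFloydWarshall(w), tolerance = 1e-10)
    expect_equal(clusteringOnnela(mkGraph(w))$Ci, oracleClustering(w),
                 tolerance = 1e-10)
    expect_equal(localEfficiency(mkGraph(w)), oracleLocalEfficiency(w),
                 tolerance = 1e-10)
  }
})

test_that("C and E are invariant under uniform weight rescaling", {
  w <- randomWeightedGraph(12, 0.5, seed = 11)
  expect_equal(clusteringOnnela(mkGraph(w))$C,
               clusteringOnnela(mkGraph(w * 3.7))$C, tolerance = 1e-12)
  expect_equal(globalEfficiency(mkGraph(w)) / globalEfficiency(mkGraph(w * 2)),
               0.5, tolerance = 1e-12)   # E scales as 1/ell = w
  expect_equal(localEfficiency(mkGraph(w)),
               localEfficiency(mkGraph(w * 0.25)), tolerance = 1e-12)
})

test_that("modularity recovers planted structure and is seed-deterministic", {
  ## two disconnected equal cliques: Q = 0.5 exactly, 2 modules
  cl <- matrix(0, 10, 10)
  cl[1:5, 1:5] <- 0.8
  cl[6:10, 6:10] <- 0.8
  diag(cl) <- 0
  mq <- modularityWeighted(mkGraph(cl), nRestarts = 10, seed = 1)
  expect_equal(mq$Q, 0.5, tolerance = 1e-12)
  expect_equal(mq$nModules, 2)

  ## single clique: Q <= 0, one module
  one <- matrix(0.5, 6, 6); diag(one) <- 0
  m1 <- modularityWeighted(mkGraph(one), nRestarts = 5, seed = 2)
  expect_lte(m1$Q, 1e-12)
  expect_equal(m1$nModules, 1)

  expect_identical(modularityWeighted(mkGraph(cl), nRestarts = 8, seed = 7)$Q,
                   modularityWeighted(mkGraph(cl), nRestarts = 8, seed = 7)$Q)
  expect_error(modularityWeighted(mkGraph(matrix(0, 4, 4))), "no edges")
})

test_that("binary graphs reproduce unweighted textbook metrics", {
  ## all weights equal: weighted metrics coincide with binary counterparts
  set.seed(13)
  adj <- matrix(0, 9, 9)
  adj[upper.tri(adj)] <- rbinom(36, 1, 0.5)
  adj <- adj + t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  d <- shortestFunctionalPaths(mkGraph(adj))
  expect_equal(d, unname(igraph::distances(g)), tolerance = 1e-10)
  ci <- clusteringOnnela(mkGraph(adj))$Ci
  itr <- igraph::transitivity(g, type = "local", isolates = "zero")
  deg <- rowSums(adj)
  itr[deg < 2] <- 0
  expect_equal(ci, itr, tolerance = 1e-10)
})
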