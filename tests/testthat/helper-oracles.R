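## Independent brute-force oracles and small fixture builders.
## These deliberately use naive enumeration / dynamic programming so that
## they share no code path with the package implementations they check.

## random symmetric weighted graph (weights in (0.1, 1)), approx density d
randomWeightedGraph <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  edges <- stats::runif(sum(up)) < density
  vals <- stats::runif(sum(up), 0.1, 1) * edges
  w[up] <- vals
  w + t(w)
}

## Floyd-Warshall all-pairs shortest paths with edge lengths 1/w
oracleFloydWarshall <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

## Onnela clustering by explicit triple enumeration
oracleClustering <- function(w) {
  n <- nrow(w)
  wh <- w / max(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      j <- nb[a]; h <- nb[b]
      s <- s + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    }
    ci[i] <- 2 * s / (k * (k - 1))
  }
  ci
}

## weighted local efficiency by brute-force neighbour-subgraph paths
oracleLocalEfficiency <- function(w) {
  n <- nrow(w)
  wh <- w / max(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    dsub <- oracleFloydWarshall(wh[nb, nb, drop = FALSE])
    s <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a == b) next
      if (is.finite(dsub[a, b]))
        s <- s + (wh[i, nb[a]] * wh[i, nb[b]] / dsub[a, b])^(1 / 3)
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

## Benjamini-Yekutieli step-up, followed literally
oracleBY <- function(p, q) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  thr <- q * seq_len(m) / (m * cm)
  passed <- which(p[o] <= thr)
  rej <- logical(m)
  if (length(passed)) rej[o[seq_len(max(passed))]] <- TRUE
  rej
}

## two-pointer ECDF scan for the two-sample KS statistic
oracleKS <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), numeric(1))))
}

## RM-ANOVA F values via stats::aov error strata (independent of the
## package's sums-of-squares decomposition)
oracleRmAnovaF <- function(d) {
  fit <- stats::aov(value ~ condition * threshold +
                      Error(subject / (condition * threshold)), data = d)
  sm <- summary(fit)
  c(condition = sm[["Error: subject:condition"]][[1]]["condition", "F value"],
    threshold = sm[["Error: subject:threshold"]][[1]]["threshold", "F value"],
    interaction = sm[["Error: subject:condition:threshold"]][[1]][
      "condition:threshold", "F value"])
}

## tiny deterministic atlas for unit tests
toyAtlas <- function(n = 10) {
  subs <- rep(subdivisionLevels(), length.out = n)
  ROIAtlas(seq_len(n) - 1L, sprintf("roi%02d", seq_len(n)), subs,
           x = seq_len(n) * 7, y = rev(seq_len(n)) * 5, z = (seq_len(n) %% 4) * 11)
}

## small synthetic study used across classification tests
toyStudy <- function(nROI = 20, nSubjects = 6, nT = 80, seed = 7,
                     effects = defaultEffects()) {
  a <- makeAtlas(nROI, seed = 3)
  tr <- makeGroundTruth(a, nModules = 3, effects = effects, seed = 3)
  suppressWarnings(simulateStudy(a, tr, nSubjects = nSubjects,
                                 nTimepoints = nT, seed = seed))
}

## ConnectivityMatrix wrapper around a plain matrix (clamped to [-1, 1])
asConn <- function(m, subject = "s1", condition = "W") {
  m <- pmin(pmax((m + t(m)) / 2, -1), 1)
  diag(m) <- 1
  new("ConnectivityMatrix", values = m, subject = subject,
      condition = condition)
}
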