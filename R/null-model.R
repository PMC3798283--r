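#' Degree-preserving rewiring of a weighted graph
#'
#' Repeated double edge swaps (a-b, c-d -> a-d, c-b), rejecting any swap that
#' would create a self-loop or multi-edge. Weights travel with their original
#' edges, so the exact degree sequence and the exact weight multiset are
#' preserved while the topology is randomized. The target number of
#' successful swaps is `swapsPerEdge * |E|`; if it cannot be reached within a
#' 10x attempt budget, a warning reports the achieved count.
#'
#' @param graph a [BrainGraph-class] (or weight matrix) with at least 2
#'   edges.
#' @param swapsPerEdge successful swaps per edge (default 10; 0 returns the
#'   graph unchanged).
#' @param seed integer seed.
#' @return a rewired [BrainGraph-class].
#' @export
rewireGraph <- function(graph, swapsPerEdge = 10L, seed = 1L) {
  bg <- is(graph, "BrainGraph")
  w <- if (bg) graphWeights(graph) else graph
  n <- nrow(w)
  pairs <- .upperPairs(n)
  vals <- .upperValues(w)
  keep <- vals > 0
  m <- sum(keep)
  .assert(m >= 2L, "graph needs at least 2 edges to rewire")
  prov <- list(method = "double edge swap", swapsPerEdge = swapsPerEdge,
               seed = as.integer(seed))
  if (swapsPerEdge > 0L) {
    set.seed(seed)
    res <- .doubleEdgeSwap(pairs[keep, 1L] - 1L, pairs[keep, 2L] - 1L,
                           vals[keep], n, as.integer(swapsPerEdge * m))
    target <- as.integer(swapsPerEdge * m)
    if (res$achieved < target)
      warning(sprintf("rewiring achieved %d of %d target swaps",
                      res$achieved, target))
    w2 <- matrix(0, n, n)
    w2[cbind(res$i + 1L, res$j + 1L)] <- res$w
    w2 <- w2 + t(w2)
    prov$achievedSwaps <- res$achieved
    w <- w2
  } else {
    prov$achievedSwaps <- 0L
  }
  new("BrainGraph", weights = w,
      density = if (bg) graph@density else m / nrow(pairs),
      subject = if (bg) graph@subject else NA_character_,
      condition = if (bg) graph@condition else NA_character_,
      provenance = prov)
}

#' Null-normalized global metrics and small-worldness
#'
#' Each requested metric X in {C, L, E, Q} is normalized by the mean of the
#' same metric over `nNull` degree-preserving rewired null networks:
#' nX = X(graph) / mean(X(null)). Small-worldness is sigma = nC / nL. Null
#' metrics are computed with exactly the same engines and settings as the
#' real graph (including the modularity seed), so a 0-swap ensemble gives
#' every ratio exactly 1. The (seed, nNull) pair fixes the ensemble and all
#' ratios bit-identically.
#'
#' @param graph a [BrainGraph-class].
#' @param nNull number of null networks (default 100).
#' @param seed integer seed for the ensemble.
#' @param metrics subset of c("C", "L", "E", "Q").
#' @param swapsPerEdge rewiring intensity (default 10).
#' @param modularityRestarts restarts used for Q on the real graph and on
#'   every null (default 10).
#' @param pTune probabilistic-tuning fraction for Q.
#' @return a [NormalizedMetrics-class].
#' @export
normalizeMetrics <- function(graph, nNull = 100L, seed = 1L,
                             metrics = c("C", "L", "E", "Q"),
                             swapsPerEdge = 10L, modularityRestarts = 10L,
                             pTune = 0.45) {
  .assert(nNull >= 1L, "nNull must be at least 1")
  metrics <- match.arg(metrics, c("C", "L", "E", "Q"), several.ok = TRUE)
  modSeed <- deriveSeed(seed, 777L)
  evalOne <- function(g) {
    out <- c()
    if (any(c("L", "E") %in% metrics)) {
      d <- shortestFunctionalPaths(g)
      if ("L" %in% metrics)
        out["L"] <- suppressWarnings(charPathLength(g, paths = d)$L)
      if ("E" %in% metrics) out["E"] <- globalEfficiency(g, paths = d)
    }
    if ("C" %in% metrics) out["C"] <- clusteringOnnela(g)$C
    if ("Q" %in% metrics)
      out["Q"] <- modularityWeighted(g, nRestarts = modularityRestarts,
                                     seed = modSeed, pTune = pTune)$Q
    out[metrics]
  }
  raw <- evalOne(graph)
  nulls <- matrix(NA_real_, nNull, length(metrics),
                  dimnames = list(NULL, metrics))
  for (k in seq_len(nNull)) {
    ng <- rewireGraph(graph, swapsPerEdge = swapsPerEdge,
                      seed = deriveSeed(seed, k))
    nulls[k, ] <- evalOne(ng)
  }
  nullMeans <- colMeans(nulls)
  if (any(nullMeans == 0)) stop("null metric mean of zero", call. = FALSE)
  ratios <- raw / nullMeans
  names(ratios) <- paste0("n", metrics)
  sigma <- if (all(c("nC", "nL") %in% names(ratios)))
    ratios[["nC"]] / ratios[["nL"]] else NA_real_
  new("NormalizedMetrics", raw = raw, nullMeans = nullMeans, ratios = ratios,
      sigma = sigma, nNull = as.integer(nNull), seed = as.integer(seed),
      provenance = list(swapsPerEdge = swapsPerEdge,
                        modularityRestarts = as.integer(modularityRestarts),
                        nullQ = if ("Q" %in% metrics) nulls[, "Q"] else NULL))
}
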