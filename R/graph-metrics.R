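#' Shortest functional paths of a weighted graph
#'
#' Edges represent statistical association, so stronger correlations are
#' functionally closer: each retained edge gets length 1/w and the matrix of
#' shortest path lengths is computed by Dijkstra from every source.
#' Unreachable pairs are `+Inf`; disconnection is represented, not raised.
#'
#' @param graph a [BrainGraph-class] (or plain non-negative weight matrix).
#' @return N x N matrix of shortest functional path lengths, zero diagonal.
#' @export
shortestFunctionalPaths <- function(graph) {
  w <- if (is(graph, "BrainGraph")) graphWeights(graph) else graph
  .dijkstraAllPairs(w)
}

#' Characteristic path length
#'
#' Mean shortest functional path over ordered pairs i != j with finite
#' distance; the fraction of unreachable pairs is reported alongside (with a
#' warning when positive).
#'
#' @param graph a [BrainGraph-class], weight matrix, or a precomputed path
#'   matrix from [shortestFunctionalPaths()] (passed via `paths`).
#' @param paths optional precomputed path-length matrix.
#' @return list with `L` and `fractionUnreachable`.
#' @export
charPathLength <- function(graph, paths = NULL) {
  d <- if (is.null(paths)) shortestFunctionalPaths(graph) else paths
  off <- !diag(nrow(d))
  v <- d[off]
  fin <- is.finite(v)
  if (!any(fin)) stop("all node pairs are unreachable", call. = FALSE)
  fu <- mean(!fin)
  if (fu > 0) warning(sprintf("%.1f%% of node pairs unreachable", 100 * fu))
  list(L = mean(v[fin]), fractionUnreachable = fu)
}

#' Global efficiency
#'
#' Mean inverse shortest functional path over ordered pairs i != j, with
#' 1/Inf = 0; robust to disconnection.
#'
#' @inheritParams charPathLength
#' @return scalar E.
#' @export
globalEfficiency <- function(graph, paths = NULL) {
  d <- if (is.null(paths)) shortestFunctionalPaths(graph) else paths
  off <- !diag(nrow(d))
  mean(ifelse(is.finite(d[off]), 1 / d[off], 0))
}

#' Weighted clustering coefficient (Onnela)
#'
#' With weights rescaled by the network maximum, w-hat = w / max(w):
#' C_i = (2 / (k_i (k_i - 1))) * sum over j < h of
#' (w-hat_ij w-hat_ih w-hat_jh)^(1/3), where k_i is the binary neighbour
#' count; C_i = 0 when k_i < 2. The network value is the node mean. C is
#' invariant under uniform rescaling of all weights.
#'
#' @param graph a [BrainGraph-class] or weight matrix.
#' @return list with per-node `Ci` and the mean `C`.
#' @export
clusteringOnnela <- function(graph) {
  w <- if (is(graph, "BrainGraph")) graphWeights(graph) else graph
  mx <- max(w)
  n <- nrow(w)
  if (mx == 0) return(list(Ci = numeric(n), C = 0))
  w3 <- (w / mx)^(1 / 3)
  k <- rowSums(w > 0)
  cyc <- diag(w3 %*% w3 %*% w3)      # 2 * sum over j<h of geometric triads
  ci <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
  list(Ci = ci, C = mean(ci))
}

#' Nodal strength
#'
#' s_i = sum_j w_ij, the weighted generalization of degree.
#'
#' @param graph a [BrainGraph-class] or weight matrix.
#' @return numeric vector of per-node strengths.
#' @export
nodalStrength <- function(graph) {
  w <- if (is(graph, "BrainGraph")) graphWeights(graph) else graph
  rowSums(w)
}

#' Weighted local efficiency
#'
#' With max-rescaled weights as in [clusteringOnnela()],
#' E_loc,i = (1/(k_i (k_i - 1))) * sum over ordered neighbour pairs j != h of
#' (w-hat_ij w-hat_ih / d_jh(N_i))^(1/3), where d_jh(N_i) is the shortest
#' path between j and h using only paths through neighbours of i (edge
#' lengths 1 / w-hat). E_loc,i = 0 when k_i < 2. Captures the communication
#' efficiency among the first neighbours of i when i is removed.
#'
#' @param graph a [BrainGraph-class] or weight matrix.
#' @return numeric vector of per-node local efficiencies.
#' @export
localEfficiency <- function(graph) {
  w <- if (is(graph, "BrainGraph")) graphWeights(graph) else graph
  mx <- max(w)
  n <- nrow(w)
  out <- numeric(n)
  if (mx == 0) return(out)
  wh <- w / mx
  for (i in seq_len(n)) {
    nb <- which(wh[i, ] > 0)
    k <- length(nb)
    if (k < 2L) next
    sub <- wh[nb, nb, drop = FALSE]
    dsub <- .dijkstraAllPairs(sub)
    wi <- wh[i, nb]
    prod3 <- (outer(wi, wi) / dsub)^(1 / 3)
    diag(prod3) <- 0
    prod3[!is.finite(prod3)] <- 0
    out[i] <- sum(prod3) / (k * (k - 1))
  }
  out
}

## weighted Newman modularity of a partition:
## Q = (1/l) sum_ij [w_ij - s_i s_j / l] delta(c_i, c_j), l = sum(W)
.modularityQ <- function(w, comm, l = sum(w), s = rowSums(w)) {
  q <- 0
  for (cc in unique(comm)) {
    idx <- comm == cc
    q <- q + sum(w[idx, idx]) / l - (sum(s[idx]) / l)^2
  }
  q
}

## deterministic fine-tuning: single-node moves while Q strictly increases
.fineTune <- function(w, comm, l, s, maxMoves = 500L) {
  n <- length(comm)
  repeat {
    labs <- sort(unique(comm))
    cmat <- outer(comm, labs, "==") + 0
    S <- w %*% cmat                       # node-to-community strengths
    Sc <- as.vector(s %*% cmat)           # community total strengths
    D <- (2 / l) * (S - outer(s, Sc) / l)
    cur <- D[cbind(seq_len(n), match(comm, labs))]
    gain <- D - cur + (2 / l) * (s^2 / l) # credit for vacating own community
    gain[cbind(seq_len(n), match(comm, labs))] <- 0
    best <- which.max(gain)
    if (gain[best] <= 1e-12) break
    i <- (best - 1L) %% n + 1L
    b <- (best - 1L) %/% n + 1L
    comm[i] <- labs[b]
    maxMoves <- maxMoves - 1L
    if (maxMoves <= 0L) break
  }
  comm
}

#' Weighted modularity with fine and probabilistic tuning
#'
#' Each restart runs (1) weighted Q-maximizing community detection (Louvain,
#' via igraph, on a random vertex permutation), (2) a deterministic
#' fine-tuning pass moving single nodes while Q strictly increases, and
#' (3) a probabilistic tuning pass that randomly reassigns a fraction
#' `pTune` of nodes and re-fine-tunes, keeping the better partition.
#' Because the community heuristic is stochastic, the mean Q and mean module
#' count over restarts are reported (deterministic given `seed`), together
#' with the best partition found.
#'
#' @param graph a [BrainGraph-class] or weight matrix with at least one edge.
#' @param nRestarts restarts (default 50).
#' @param seed integer seed.
#' @param pTune fraction of nodes reassigned by the probabilistic pass
#'   (default 0.45).
#' @return list with `Q` (mean over restarts), `nModules` (mean count),
#'   `bestQ`, `bestPartition`, per-restart `restartQ`, and `engine`.
#' @export
modularityWeighted <- function(graph, nRestarts = 50L, seed = 1L,
                               pTune = 0.45) {
  w <- if (is(graph, "BrainGraph")) graphWeights(graph) else graph
  .assert(nRestarts >= 1L, "nRestarts must be at least 1")
  n <- nrow(w)
  l <- sum(w)
  if (l <= 0) stop("graph has no edges", call. = FALSE)
  s <- rowSums(w)
  qs <- numeric(nRestarts)
  mods <- numeric(nRestarts)
  bestQ <- -Inf
  bestPart <- rep(1L, n)
  set.seed(seed)
  for (r in seq_len(nRestarts)) {
    ord <- sample.int(n)
    g <- igraph::graph_from_adjacency_matrix(w[ord, ord], mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    memb <- igraph::membership(igraph::cluster_louvain(g))
    comm <- integer(n)
    comm[ord] <- as.integer(memb)
    comm <- .fineTune(w, comm, l, s)
    q <- .modularityQ(w, comm, l, s)
    ## probabilistic tuning: perturb and re-refine, keep the better
    labs <- unique(comm)
    pick <- which(stats::runif(n) < pTune)
    if (length(pick) && length(labs) > 1L) {
      pert <- comm
      pert[pick] <- sample(labs, length(pick), replace = TRUE)
      pert <- .fineTune(w, pert, l, s)
      qp <- .modularityQ(w, pert, l, s)
      if (qp > q) { comm <- pert; q <- qp }
    }
    qs[r] <- q
    mods[r] <- length(unique(comm))
    if (q > bestQ) { bestQ <- q; bestPart <- comm }
  }
  list(Q = mean(qs), nModules = mean(mods), bestQ = bestQ,
       bestPartition = match(bestPart, unique(bestPart)),
       restartQ = qs,
       engine = "igraph Louvain + deterministic fine-tuning + probabilistic tuning")
}

#' All global and nodal metrics of one graph
#'
#' Convenience wrapper computing the selected metrics with shared
#' intermediate results (one all-pairs path computation).
#'
#' @param graph a [BrainGraph-class].
#' @param metrics subset of c("C", "L", "E", "Q", "strength", "localEff").
#' @param nRestarts,seed,pTune passed to [modularityWeighted()].
#' @return named list with the requested entries (plus `fractionUnreachable`
#'   and `nModules` where applicable).
#' @export
graphMetrics <- function(graph, metrics = c("C", "L", "E", "Q", "strength",
                                            "localEff"),
                         nRestarts = 50L, seed = 1L, pTune = 0.45) {
  out <- list()
  if (any(c("L", "E") %in% metrics)) {
    d <- shortestFunctionalPaths(graph)
    if ("L" %in% metrics) {
      cl <- charPathLength(graph, paths = d)
      out$L <- cl$L
      out$fractionUnreachable <- cl$fractionUnreachable
    }
    if ("E" %in% metrics) out$E <- globalEfficiency(graph, paths = d)
  }
  if ("C" %in% metrics) {
    cc <- clusteringOnnela(graph)
    out$C <- cc$C
    out$Ci <- cc$Ci
  }
  if ("Q" %in% metrics) {
    mq <- modularityWeighted(graph, nRestarts = nRestarts, seed = seed,
                             pTune = pTune)
    out$Q <- mq$Q
    out$nModules <- mq$nModules
  }
  if ("strength" %in% metrics) out$strength <- nodalStrength(graph)
  if ("localEff" %in% metrics) out$localEff <- localEfficiency(graph)
  out
}
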