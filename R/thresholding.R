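#' Proportional density thresholding of a connectivity matrix
#'
#' Upper-triangle entries are ranked descending by signed value; the top
#' `round(density * M)` entries (M = N(N-1)/2, round half away from zero)
#' are retained with their original weights, all others — including every
#' negative correlation — are set to zero. Ties at the cutoff are broken by
#' (lower i, lower j) index order, which makes the retained edge set at a
#' lower density a subset of that at any higher density.
#'
#' @param matrix a [ConnectivityMatrix-class] (or plain symmetric matrix).
#' @param density proportion of edges to retain, in (0, 1].
#' @return a [BrainGraph-class].
#' @export
proportionalThreshold <- function(matrix, density) {
  .assert(density > 0 && density <= 1, "density must lie in (0, 1]")
  cm <- is(matrix, "ConnectivityMatrix")
  v <- if (cm) connectivityValues(matrix) else matrix
  n <- nrow(v)
  vals <- .upperValues(v)
  m <- length(vals)
  k <- roundHalfUp(density * m)
  nPos <- sum(vals > 0)
  if (k > nPos)
    stop(sprintf(paste0("only %d positive entries available for %d requested ",
                        "edges; maximum achievable density is %.4f"),
                 nPos, k, nPos / m), call. = FALSE)
  ## stable sort: descending value, ties by row-major (i, j) order
  keep <- order(-vals)[seq_len(k)]
  w <- numeric(m)
  w[keep] <- vals[keep]
  new("BrainGraph", weights = .fromUpperValues(w, n), density = density,
      subject = if (cm) matrix@subject else NA_character_,
      condition = if (cm) matrix@condition else NA_character_,
      provenance = list(method = "proportional", nEdges = k,
                        maxDensity = nPos / m))
}

#' Degree and small-worldness diagnostics over a density grid
#'
#' For each candidate density (percent) and condition, computes the mean
#' binary degree of the thresholded graphs (a closed form of the retained
#' edge count: 2 round(d M) / N) and the mean small-worldness sigma from
#' [normalizeMetrics()] (clustering and path length only).
#'
#' @param matrices list of [ConnectivityMatrix-class] with condition slots.
#' @param grid candidate densities in percent, ascending.
#' @param nNull null networks per graph for sigma (default 20).
#' @param seed integer seed for the null ensembles.
#' @param swapsPerEdge rewiring intensity for the nulls (default 10).
#' @return data.frame with `densityPct`, `condition`, `meanDegree`,
#'   `meanSigma`.
#' @export
densityDiagnostics <- function(matrices, grid, nNull = 20L, seed = 1L,
                               swapsPerEdge = 10L) {
  conds <- unique(vapply(matrices, function(m) m@condition, ""))
  out <- NULL
  for (g in seq_along(grid)) {
    d <- grid[g] / 100
    for (cn in conds) {
      idx <- which(vapply(matrices, function(m) m@condition, "") == cn)
      sig <- numeric(length(idx))
      deg <- numeric(length(idx))
      for (ii in seq_along(idx)) {
        bg <- proportionalThreshold(matrices[[idx[ii]]], d)
        n <- nROI(bg)
        deg[ii] <- 2 * bg@provenance$nEdges / n
        nm <- normalizeMetrics(bg, nNull = nNull,
                               seed = deriveSeed(seed, g * 1000L + idx[ii]),
                               metrics = c("C", "L"),
                               swapsPerEdge = swapsPerEdge)
        sig[ii] <- nm@sigma
      }
      out <- rbind(out, data.frame(densityPct = grid[g], condition = cn,
                                   meanDegree = mean(deg),
                                   meanSigma = mean(sig)))
    }
  }
  out
}

#' Select the analysis density range from diagnostics
#'
#' The lower bound is the smallest grid density whose mean degree is at
#' least `2 ln(N)` in every condition (network estimability); the upper
#' bound is the largest grid density whose mean small-worldness is at least
#' `sigmaMin` in every condition. The returned densities sample the
#' admissible interval from the lower bound in `step` increments.
#'
#' @param diagnostics data.frame from [densityDiagnostics()].
#' @param nNodes number of nodes N (for the 2 ln N rule).
#' @param step grid step in percent (default 5).
#' @param degreeRule minimum mean degree; default `2 * log(nNodes)`
#'   (natural logarithm).
#' @param sigmaMin minimum mean small-worldness (default 1.0).
#' @return list with `densitiesPct`, `lowerPct`, `upperPct`, `degreeRule`.
#' @export
selectThresholdRange <- function(diagnostics, nNodes, step = 5,
                                 degreeRule = 2 * log(nNodes),
                                 sigmaMin = 1.0) {
  .assert(step > 0, "step must be positive")
  grid <- sort(unique(diagnostics$densityPct))
  degOK <- vapply(grid, function(g) {
    all(diagnostics$meanDegree[diagnostics$densityPct == g] >= degreeRule)
  }, logical(1L))
  sigOK <- vapply(grid, function(g) {
    all(diagnostics$meanSigma[diagnostics$densityPct == g] >= sigmaMin)
  }, logical(1L))
  if (!any(degOK) || !any(sigOK) || min(grid[degOK]) > max(grid[sigOK]))
    stop(sprintf(paste0("empty admissible density range: degree rule (>= %.2f) ",
                        "first met at %s%%; small-worldness (>= %.2f) last met ",
                        "at %s%%"),
                 degreeRule,
                 if (any(degOK)) min(grid[degOK]) else "none",
                 sigmaMin,
                 if (any(sigOK)) max(grid[sigOK]) else "none"),
         call. = FALSE)
  lower <- min(grid[degOK])
  upper <- max(grid[sigOK])
  dens <- seq(lower, upper, by = step)
  dens <- dens[dens %in% grid]
  list(densitiesPct = dens, lowerPct = lower, upperPct = upper,
       degreeRule = degreeRule)
}
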