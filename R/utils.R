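#' @useDynLib stateFC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Condition levels of the four-state design
#'
#' Ordinal order used in every table and report: wakefulness (W), sedation (S),
#' loss of consciousness (LOC), recovery (R).
#' @export
conditionLevels <- function() c("W", "S", "LOC", "R")

#' Anatomical subdivision labels
#'
#' The eight-way subdivision used by the ROI atlas: frontal, temporal,
#' parietal and occipital cortex, basal ganglia, thalamus, brainstem,
#' cerebellum.
#' @export
subdivisionLevels <- function() c("Fcx", "Tcx", "Pcx", "Ocx", "BG", "Thl", "BS", "Crbl")

## Coarse classes used by the edge taxonomy: the four cortical lobes collapse
## to "cortex"; the remaining subdivisions stand alone.
.subdivisionClass <- function(subdivision) {
  map <- c(Fcx = "cortex", Tcx = "cortex", Pcx = "cortex", Ocx = "cortex",
           BG = "basal ganglia", Thl = "thalamus", BS = "brainstem",
           Crbl = "cerebellum")
  unname(map[as.character(subdivision)])
}

## round() half-away-from-zero (base round is banker's rounding)
roundHalfUp <- function(x) floor(x + 0.5)

## Deterministic child seeds below 2^31 derived from a master seed.
deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647L)
}

## indices of the upper triangle in row-major order (i < j)
.upperPairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

## extract upper triangle (i < j) in row-major order
.upperValues <- function(m) {
  tm <- t(m)
  tm[lower.tri(tm)]
}

## rebuild a symmetric zero-diagonal matrix from row-major upper values
.fromUpperValues <- function(v, n) {
  m <- matrix(0, n, n)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m + t(m)
}

.assert <- function(ok, ...) {
  if (!ok) stop(..., call. = FALSE)
  invisible(TRUE)
}
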