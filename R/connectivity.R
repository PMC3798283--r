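#' Temporal cleaning of an ROI time-series panel
#'
#' Applies, in order: removal of the first `trim` volumes, per-ROI removal of
#' linear and quadratic trends (least squares), partialling-out of nuisance
#' regressors by linear regression, and zero-phase (forward-backward)
#' Butterworth band-pass filtering. Global-signal regression is deliberately
#' not performed.
#'
#' @param panel a [TimeSeriesPanel-class].
#' @param band band-pass edges in Hz, `c(low, high)` with
#'   0 < low < high < Nyquist = 1/(2 tr). Default c(0.01, 0.1), the standard
#'   resting-state band. `NULL` skips filtering.
#' @param nuisance optional T x m matrix of nuisance regressors (after
#'   trimming, i.e. with `T - trim` rows, or T rows which are then trimmed
#'   alike). Rank-deficient matrices are handled by the pseudo-inverse with a
#'   warning.
#' @param trim number of initial volumes removed (default 4).
#' @param filterOrder Butterworth order (default 2; applied forward and
#'   backward).
#' @return a cleaned [TimeSeriesPanel-class].
#' @export
cleanTimeSeries <- function(panel, band = c(0.01, 0.1), nuisance = NULL,
                            trim = 4L, filterOrder = 2L) {
  x <- panel@data
  .assert(trim < nrow(x), "trim must be smaller than T")
  if (trim > 0L) x <- x[-seq_len(trim), , drop = FALSE]
  nT <- nrow(x)
  nyq <- 1 / (2 * panel@tr)
  if (!is.null(band)) {
    .assert(length(band) == 2L && band[1L] > 0 && band[1L] < band[2L] &&
              band[2L] < nyq,
            "band must satisfy 0 < low < high < Nyquist = ", signif(nyq, 4), " Hz")
  }
  ## linear + quadratic detrend (includes intercept)
  tt <- seq_len(nT)
  dm <- cbind(1, tt, tt^2)
  x <- as.matrix(stats::lm.fit(dm, x)$residuals)
  if (!is.null(nuisance)) {
    nu <- as.matrix(nuisance)
    if (trim > 0L && nrow(nu) == nT + trim)
      nu <- nu[-seq_len(trim), , drop = FALSE]
    .assert(nrow(nu) == nT, "nuisance must have T (or T - trim) rows")
    ## the polynomial basis stays in the design so that regressors carrying
    ## trends are partialled out consistently with the detrending step
    nu <- cbind(dm, nu)
    if (qr(nu)$rank < ncol(nu)) {
      warning("rank-deficient nuisance matrix; using pseudo-inverse")
      beta <- MASS::ginv(nu) %*% x
      x <- x - nu %*% beta
    } else {
      x <- as.matrix(stats::lm.fit(nu, x)$residuals)
    }
  }
  if (!is.null(band)) {
    bf <- signal::butter(filterOrder, band / nyq, type = "pass")
    x <- apply(x, 2L, function(col) signal::filtfilt(bf, col))
  }
  new("TimeSeriesPanel", data = unname(x), subject = panel@subject,
      condition = panel@condition, tr = panel@tr)
}

#' Pearson connectivity matrix of a panel
#'
#' Pairwise Pearson correlation between all ROI time series; diagonal set to
#' exactly 1.
#'
#' @param panel a [TimeSeriesPanel-class] with T >= 3 and no constant column.
#' @return a [ConnectivityMatrix-class].
#' @export
correlationMatrix <- function(panel) {
  x <- panel@data
  .assert(nrow(x) >= 3L, "need at least 3 timepoints")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop("constant time series for ROI(s): ", paste(bad - 1L, collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(x)
  r <- (r + t(r)) / 2
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  new("ConnectivityMatrix", values = unname(r), subject = panel@subject,
      condition = panel@condition)
}

#' Connectivity matrices for a whole study
#'
#' @param dataset a [StudyDataset-class].
#' @return list of [ConnectivityMatrix-class], in manifest order.
#' @export
studyConnectivity <- function(dataset) {
  lapply(dataset@panels[studyManifest(dataset)$index], correlationMatrix)
}

#' Mean connectivity matrix of a set of matrices
#' @param matrices list of [ConnectivityMatrix-class] of equal size.
#' @return plain numeric matrix (elementwise mean).
#' @export
meanConnectivity <- function(matrices) {
  .assert(length(matrices) >= 1L, "need at least one matrix")
  Reduce(`+`, lapply(matrices, connectivityValues)) / length(matrices)
}

#' Descriptive summary of a correlation distribution
#'
#' Computed on the upper triangle of the condition-mean matrix: median r,
#' proportion of negative correlations, proportion above 0.4, proportion in
#' [0, 0.4], and histogram counts.
#'
#' @param matrices list of [ConnectivityMatrix-class] (e.g. one condition's
#'   subjects); the summary is taken on their mean.
#' @param breaks histogram breaks (default width 0.1 on [-1, 1]).
#' @return list with elements `median`, `propNegative`, `propAbove04`,
#'   `propWithin04`, `histogram` (counts) and `breaks`.
#' @export
correlationSummary <- function(matrices, breaks = seq(-1, 1, by = 0.1)) {
  m <- meanConnectivity(matrices)
  v <- .upperValues(m)
  list(median = stats::median(v),
       propNegative = mean(v < 0),
       propAbove04 = mean(v > 0.4),
       propWithin04 = mean(v >= 0 & v <= 0.4),
       histogram = as.vector(table(cut(v, breaks = breaks, right = FALSE))),
       breaks = breaks)
}

#' Two-sample Kolmogorov-Smirnov comparison of correlation samples
#'
#' D is the maximum gap between the two empirical CDFs; p uses the
#' asymptotic KS distribution.
#'
#' @param sampleA,sampleB non-empty numeric vectors of correlation values.
#' @return list with `D` and `p`.
#' @export
ksCompare <- function(sampleA, sampleB) {
  .assert(length(sampleA) > 0L && length(sampleB) > 0L, "empty sample")
  kt <- suppressWarnings(stats::ks.test(sampleA, sampleB, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Mean correlation per inter-ROI distance bin
#'
#' Upper-triangle pairs are assigned to half-open bins
#' `[k w, (k+1) w)`; the last bin absorbs all larger distances.
#'
#' @param matrix a [ConnectivityMatrix-class] (or plain matrix).
#' @param dist distance matrix from [euclideanDistances()].
#' @param binWidth bin width in mm (default 9).
#' @param nBins number of bins (default 15).
#' @return data.frame with `bin`, `center` (mm, midpoint of the nominal bin),
#'   `meanR` and `nPairs`.
#' @export
binByDistance <- function(matrix, dist, binWidth = 9, nBins = 15L) {
  .assert(binWidth > 0, "binWidth must be positive")
  .assert(nBins >= 1L, "nBins must be at least 1")
  v <- if (is(matrix, "ConnectivityMatrix")) connectivityValues(matrix) else matrix
  r <- .upperValues(v)
  d <- .upperValues(dist)
  bin <- pmin(floor(d / binWidth), nBins - 1L)
  counts <- tabulate(bin + 1L, nbins = nBins)
  sums <- vapply(seq_len(nBins) - 1L, function(b) sum(r[bin == b]), numeric(1L))
  if (sum(counts > 0L) == 1L)
    warning("all ROI pairs fall into a single distance bin")
  data.frame(bin = seq_len(nBins) - 1L,
             center = (seq_len(nBins) - 0.5) * binWidth,
             meanR = ifelse(counts > 0L, sums / counts, NA_real_),
             nPairs = counts)
}
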