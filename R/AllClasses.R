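#' ROIAtlas: region-of-interest atlas
#'
#' Node labels, eight-way anatomical subdivision and 3-D barycenter
#' coordinates (mm) for every region of interest. The row order of the atlas
#' is the canonical node order of every matrix in a study; internal ids are
#' 0-based and contiguous.
#'
#' @slot roiId integer vector, 0..N-1 in atlas order.
#' @slot roiName character vector of region names.
#' @slot subdivision factor with the eight levels of [subdivisionLevels()].
#' @slot coords N x 3 numeric matrix of barycenter coordinates in mm
#'   (columns x, y, z).
#' @export
setClass("ROIAtlas",
  representation(roiId = "integer", roiName = "character",
                 subdivision = "factor", coords = "matrix"))

setValidity("ROIAtlas", function(object) {
  n <- length(object@roiId)
  msg <- character()
  if (!identical(object@roiId, seq_len(n) - 1L))
    msg <- c(msg, "roiId must be contiguous 0..N-1 in atlas order")
  if (length(object@roiName) != n) msg <- c(msg, "roiName length mismatch")
  if (length(object@subdivision) != n) msg <- c(msg, "subdivision length mismatch")
  if (!identical(levels(object@subdivision), subdivisionLevels()))
    msg <- c(msg, "subdivision must use the 8 canonical levels")
  if (anyNA(object@subdivision)) msg <- c(msg, "unknown subdivision label")
  if (!is.numeric(object@coords) || nrow(object@coords) != n ||
      ncol(object@coords) != 3L)
    msg <- c(msg, "coords must be an N x 3 numeric matrix")
  else if (!all(is.finite(object@coords)))
    msg <- c(msg, "coords must be finite")
  if (length(msg)) msg else TRUE
})

#' TimeSeriesPanel: one subject-by-condition ROI time-series matrix
#'
#' @slot data T x N numeric matrix (rows timepoints, columns ROIs in atlas
#'   order), BOLD-like arbitrary units.
#' @slot subject subject identifier.
#' @slot condition one of W, S, LOC, R.
#' @slot tr repetition time in seconds.
#' @export
setClass("TimeSeriesPanel",
  representation(data = "matrix", subject = "character",
                 condition = "character", tr = "numeric"))

setValidity("TimeSeriesPanel", function(object) {
  msg <- character()
  if (!is.numeric(object@data) || nrow(object@data) < 2L)
    msg <- c(msg, "data must be a numeric matrix with T >= 2")
  if (!all(is.finite(object@data))) msg <- c(msg, "data contains non-finite values")
  if (!object@condition %in% conditionLevels())
    msg <- c(msg, "condition must be one of W, S, LOC, R")
  if (length(object@tr) != 1L || object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (length(msg)) msg else TRUE
})

#' StudyDataset: panel of per-subject-per-condition time series
#'
#' @slot atlas the [ROIAtlas-class] defining node order.
#' @slot panels list of [TimeSeriesPanel-class] objects.
#' @slot manifest data.frame with columns subject, condition and the index of
#'   the corresponding panel.
#' @slot groundTruth list of generator ground truth (effect specs, module
#'   assignment, seed) or empty when the data were loaded from files.
#' @export
setClass("StudyDataset",
  representation(atlas = "ROIAtlas", panels = "list", manifest = "data.frame",
                 groundTruth = "list"))

setValidity("StudyDataset", function(object) {
  msg <- character()
  n <- nROI(object@atlas)
  for (p in object@panels) {
    if (!is(p, "TimeSeriesPanel")) { msg <- c(msg, "panels must be TimeSeriesPanel"); break }
    if (ncol(p@data) != n) { msg <- c(msg, "panel width must equal atlas size"); break }
  }
  if (nrow(object@manifest) != length(object@panels))
    msg <- c(msg, "manifest must have one row per panel")
  tab <- table(object@manifest$subject, factor(object@manifest$condition, conditionLevels()))
  if (nrow(tab) && any(tab != 1L))
    msg <- c(msg, "paired design required: every subject needs all four conditions exactly once")
  if (length(msg)) msg else TRUE
})

#' ConnectivityMatrix: Pearson correlation graph of one panel
#'
#' @slot values N x N symmetric matrix of Pearson r, unit diagonal.
#' @slot subject,condition provenance of the source panel.
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", subject = "character", condition = "character"))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  else {
    if (max(abs(v - t(v))) > 1e-10) msg <- c(msg, "values must be symmetric")
    if (any(abs(diag(v) - 1) > 1e-10)) msg <- c(msg, "diagonal must be exactly 1")
    off <- v[upper.tri(v)]
    if (any(off < -1 - 1e-10 | off > 1 + 1e-10))
      msg <- c(msg, "off-diagonal entries must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' BrainGraph: proportionally thresholded positive-weighted graph
#'
#' @slot weights N x N symmetric non-negative matrix, zero diagonal; retained
#'   weights keep their original correlation values.
#' @slot density retained proportion of the N(N-1)/2 possible edges.
#' @slot subject,condition provenance of the source matrix.
#' @slot provenance list recording how the graph was produced.
#' @export
setClass("BrainGraph",
  representation(weights = "matrix", density = "numeric",
                 subject = "character", condition = "character",
                 provenance = "list"))

setValidity("BrainGraph", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
  else {
    if (max(abs(w - t(w))) > 1e-10) msg <- c(msg, "weights must be symmetric")
    if (any(diag(w) != 0)) msg <- c(msg, "diagonal must be zero")
    if (any(w < 0)) msg <- c(msg, "retained weights must be positive")
  }
  if (length(object@density) != 1L || object@density <= 0 || object@density > 1)
    msg <- c(msg, "density must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' NormalizedMetrics: raw and null-normalized global graph metrics
#'
#' Raw metrics of a graph together with the means of the same metrics over an
#' ensemble of degree-preserving rewired null networks, the ratios nC, nL,
#' nE, nQ and small-worldness sigma = nC/nL.
#'
#' @slot raw named numeric vector of raw metrics (subset of C, L, E, Q).
#' @slot nullMeans named numeric vector of null-ensemble means.
#' @slot ratios named numeric vector of normalized metrics (nC, nL, nE, nQ).
#' @slot sigma small-worldness nC/nL (NA when C or L not computed).
#' @slot nNull number of null networks.
#' @slot seed integer seed that fixes the null ensemble.
#' @slot provenance list (swap counts, engines, settings).
#' @export
setClass("NormalizedMetrics",
  representation(raw = "numeric", nullMeans = "numeric", ratios = "numeric",
                 sigma = "numeric", nNull = "integer", seed = "integer",
                 provenance = "list"))

setValidity("NormalizedMetrics", function(object) {
  msg <- character()
  if (any(object@ratios <= 0, na.rm = TRUE)) msg <- c(msg, "ratios must be positive")
  if (all(c("nC", "nL") %in% names(object@ratios)) && !is.na(object@sigma)) {
    if (object@sigma != object@ratios[["nC"]] / object@ratios[["nL"]])
      msg <- c(msg, "sigma must equal nC/nL exactly")
  }
  if (length(msg)) msg else TRUE
})

#' ClassificationResult: leave-one-subject-out SVM classification
#'
#' @slot comparison label such as "S vs LOC" (class A vs class B).
#' @slot folds data.frame of per-fold held-out predictions (subject, class,
#'   predicted, correct).
#' @slot accuracy,sensitivity,specificity percent over held-out samples
#'   (sensitivity = class A, specificity = class B).
#' @slot weightMatrix N x N symmetric hyperplane-weight matrix (class A
#'   coded +1), zero diagonal.
#' @slot pPerm permutation p-value (NA before [permutationTest()]).
#' @slot pBonferroni Bonferroni-adjusted permutation p.
#' @slot nPerm number of permutations.
#' @slot cost SVM cost parameter used.
#' @export
setClass("ClassificationResult",
  representation(comparison = "character", folds = "data.frame",
                 accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", weightMatrix = "matrix",
                 pPerm = "numeric", pBonferroni = "numeric",
                 nPerm = "integer", cost = "numeric"))

setValidity("ClassificationResult", function(object) {
  msg <- character()
  w <- object@weightMatrix
  if (nrow(w) != ncol(w) || max(abs(w - t(w))) > 1e-10 || any(diag(w) != 0))
    msg <- c(msg, "weightMatrix must be symmetric with zero diagonal")
  if (nrow(object@folds) &&
      abs(object@accuracy - 100 * mean(object@folds$correct)) > 1e-8)
    msg <- c(msg, "accuracy must equal the mean of per-fold correctness")
  if (length(msg)) msg else TRUE
})
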