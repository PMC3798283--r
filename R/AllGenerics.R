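#' Number of ROIs in an object
#' @param x a ROIAtlas, StudyDataset, ConnectivityMatrix or BrainGraph.
#' @return integer count of regions.
#' @export
setGeneric("nROI", function(x) standardGeneric("nROI"))

#' @describeIn nROI atlas size
#' @export
setMethod("nROI", "ROIAtlas", function(x) length(x@roiId))
#' @describeIn nROI atlas size of the study
#' @export
setMethod("nROI", "StudyDataset", function(x) nROI(x@atlas))
#' @describeIn nROI matrix dimension
#' @export
setMethod("nROI", "ConnectivityMatrix", function(x) nrow(x@values))
#' @describeIn nROI graph order
#' @export
setMethod("nROI", "BrainGraph", function(x) nrow(x@weights))

#' Accessors for atlas fields
#' @param x a ROIAtlas.
#' @return `roiNames` the region names, `subdivisions` the anatomical factor,
#'   `coords` the N x 3 coordinate matrix.
#' @export
roiNames <- function(x) x@roiName

#' @rdname roiNames
#' @export
subdivisions <- function(x) x@subdivision

#' @rdname roiNames
#' @export
coords <- function(x) x@coords

#' Accessors for study datasets
#' @param x a StudyDataset.
#' @return `panels` the list of TimeSeriesPanel, `studyManifest` the manifest
#'   data.frame, `atlasOf` the ROIAtlas, `groundTruth` the generator truth
#'   (empty list for loaded data), `subjects` the subject ids.
#' @export
panels <- function(x) x@panels

#' @rdname panels
#' @export
studyManifest <- function(x) x@manifest

#' @rdname panels
#' @export
atlasOf <- function(x) x@atlas

#' @rdname panels
#' @export
groundTruth <- function(x) x@groundTruth

#' @rdname panels
#' @export
subjects <- function(x) unique(x@manifest$subject)

#' Retrieve one panel by subject and condition
#' @param x a StudyDataset.
#' @param subject subject id.
#' @param condition one of W, S, LOC, R.
#' @return the matching [TimeSeriesPanel-class].
#' @export
getPanel <- function(x, subject, condition) {
  idx <- which(x@manifest$subject == subject & x@manifest$condition == condition)
  .assert(length(idx) == 1L, "no panel for subject ", subject, " condition ", condition)
  x@panels[[x@manifest$index[idx]]]
}

#' Weight / value matrix accessors
#' @param x a ConnectivityMatrix or BrainGraph.
#' @return the underlying numeric matrix; `graphDensity` the retained edge
#'   proportion of a BrainGraph.
#' @export
connectivityValues <- function(x) x@values

#' @rdname connectivityValues
#' @export
graphWeights <- function(x) x@weights

#' @rdname connectivityValues
#' @export
graphDensity <- function(x) x@density

setMethod("show", "ROIAtlas", function(object) {
  cat("ROIAtlas with", nROI(object), "ROIs across",
      nlevels(droplevels(object@subdivision)), "subdivisions\n")
  print(table(object@subdivision))
})

setMethod("show", "StudyDataset", function(object) {
  cat("StudyDataset:", length(subjects(object)), "subjects x",
      length(unique(object@manifest$condition)), "conditions,",
      nROI(object), "ROIs\n")
  if (length(object@panels))
    cat("  timepoints:", paste(unique(vapply(object@panels, function(p) nrow(p@data), 1L)),
        collapse = ", "), " tr:", object@panels[[1]]@tr, "s\n")
  if (length(object@groundTruth)) cat("  synthetic (ground truth attached)\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix", paste0(object@subject, "/", object@condition),
      "-", nROI(object), "ROIs, median r =",
      signif(stats::median(.upperValues(object@values)), 3), "\n")
})

setMethod("show", "BrainGraph", function(object) {
  n <- nROI(object)
  cat("BrainGraph", paste0(object@subject, "/", object@condition),
      "- density", object@density, ":", sum(object@weights[upper.tri(object@weights)] > 0),
      "of", n * (n - 1) / 2, "edges\n")
})

setMethod("show", "NormalizedMetrics", function(object) {
  cat("NormalizedMetrics (", object@nNull, "nulls, seed", object@seed, ")\n")
  print(round(rbind(raw = object@raw, nullMean = object@nullMeans), 4))
  cat("ratios:", paste(names(object@ratios), round(object@ratios, 3),
      sep = "=", collapse = " "), " sigma:", round(object@sigma, 3), "\n")
})

setMethod("show", "ClassificationResult", function(object) {
  cat("ClassificationResult", object@comparison, "-",
      nrow(object@folds) / 2, "folds\n")
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
      object@accuracy, object@sensitivity, object@specificity))
  if (!is.na(object@pPerm))
    cat(sprintf("  permutation p = %.4g (n_perm = %d, Bonferroni p = %.4g)\n",
        object@pPerm, object@nPerm, object@pBonferroni))
})
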