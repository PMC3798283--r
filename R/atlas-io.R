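#' Construct an ROIAtlas from vectors
#'
#' Ids are remapped to contiguous 0..N-1 preserving input order; the input
#' order defines the canonical node order of the study.
#'
#' @param roiId integer-like ids (arbitrary, must be unique).
#' @param name region names.
#' @param subdivision labels among [subdivisionLevels()].
#' @param x,y,z barycenter coordinates in mm.
#' @return an [ROIAtlas-class].
#' @export
ROIAtlas <- function(roiId, name, subdivision, x, y, z) {
  .assert(!anyDuplicated(roiId), "duplicate roi_id")
  bad <- setdiff(unique(as.character(subdivision)), subdivisionLevels())
  .assert(length(bad) == 0L, "unknown subdivision label: ", paste(bad, collapse = ", "))
  new("ROIAtlas",
      roiId = seq_along(roiId) - 1L,
      roiName = as.character(name),
      subdivision = factor(as.character(subdivision), levels = subdivisionLevels()),
      coords = cbind(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)))
}

#' Read an ROI atlas from tab-separated text
#'
#' Expects header columns `roi_id, name, subdivision, x, y, z`. File order is
#' preserved and ids are remapped to 0..N-1.
#'
#' @param path path to the TSV file.
#' @return an [ROIAtlas-class].
#' @export
loadAtlas <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("roi_id", "name", "subdivision", "x", "y", "z")
  missing <- setdiff(need, names(df))
  .assert(length(missing) == 0L,
          "atlas file lacks column(s): ", paste(missing, collapse = ", "))
  ROIAtlas(df$roi_id, df$name, df$subdivision, df$x, df$y, df$z)
}

#' @rdname loadAtlas
#' @param atlas an [ROIAtlas-class] to write.
#' @export
writeAtlas <- function(atlas, path) {
  df <- as.data.frame(atlas)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.ROIAtlas <- function(x, ...) {
  data.frame(roi_id = x@roiId, name = x@roiName,
             subdivision = as.character(x@subdivision),
             x = x@coords[, 1], y = x@coords[, 2], z = x@coords[, 3],
             stringsAsFactors = FALSE)
}

#' Write / read a square matrix as tab-separated text
#'
#' Full square matrix with a header row of ROI names, 10 significant digits;
#' human-inspectable and diff-able. Round-trips to full printed precision.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @param colNames column header (defaults to existing colnames or V1..VN).
#' @export
writeMatrixTSV <- function(m, path, colNames = colnames(m)) {
  if (is.null(colNames)) colNames <- paste0("V", seq_len(ncol(m)))
  txt <- apply(m, 1L, function(row) paste(formatC(row, digits = 10, format = "g"),
                                          collapse = "\t"))
  writeLines(c(paste(colNames, collapse = "\t"), txt), path)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  dimnames(m) <- list(NULL, colnames(df))
  m
}

#' Inter-ROI Euclidean distance matrix
#'
#' 3-D Euclidean distance (mm) between ROI barycenters,
#' d(i,j) = sqrt((xi-xj)^2 + (yi-yj)^2 + (zi-zj)^2).
#'
#' @param atlas an [ROIAtlas-class] with finite coordinates.
#' @return symmetric N x N matrix with zero diagonal.
#' @export
euclideanDistances <- function(atlas) {
  .assert(all(is.finite(atlas@coords)), "non-finite coordinate in atlas")
  as.matrix(stats::dist(atlas@coords))
}

#' Load a study from a manifest of time-series files
#'
#' The manifest is a TSV with columns `subject, condition, timeseries_path`
#' (paths relative to the manifest unless absolute). Every referenced file is
#' a T x N TSV (rows timepoints, columns ROIs in atlas order). Panels longer
#' than `tMax` timepoints are truncated to the first `tMax`; the paired design
#' requires every subject to have all four conditions.
#'
#' @param manifest path to the manifest TSV.
#' @param atlas the [ROIAtlas-class] defining node order and N.
#' @param tMax maximum number of timepoints retained (default 196).
#' @param tr repetition time in seconds (default 2.46).
#' @return a [StudyDataset-class].
#' @export
loadStudy <- function(manifest, atlas, tMax = 196L, tr = 2.46) {
  mf <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("subject", "condition", "timeseries_path")
  missing <- setdiff(need, names(mf))
  .assert(length(missing) == 0L,
          "manifest lacks column(s): ", paste(missing, collapse = ", "))
  base <- dirname(manifest)
  n <- nROI(atlas)
  panels <- vector("list", nrow(mf))
  for (k in seq_len(nrow(mf))) {
    p <- mf$timeseries_path[k]
    if (!file.exists(p)) p <- file.path(base, p)
    d <- readMatrixTSV(p)
    .assert(ncol(d) == n, "time-series file ", mf$timeseries_path[k],
            " has ", ncol(d), " columns; atlas has ", n, " ROIs")
    if (nrow(d) > tMax) d <- d[seq_len(tMax), , drop = FALSE]
    panels[[k]] <- new("TimeSeriesPanel", data = unname(d),
                       subject = as.character(mf$subject[k]),
                       condition = as.character(mf$condition[k]), tr = tr)
  }
  new("StudyDataset", atlas = atlas, panels = panels,
      manifest = data.frame(subject = as.character(mf$subject),
                            condition = as.character(mf$condition),
                            index = seq_len(nrow(mf)),
                            stringsAsFactors = FALSE),
      groundTruth = list())
}

#' Write a study dataset to a directory
#'
#' Emits one TSV per panel, a `manifest.tsv`, the atlas as `atlas.tsv`, and —
#' for synthetic data — the ground truth as a JSON sidecar.
#'
#' @param dataset a [StudyDataset-class].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeStudy <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeAtlas(atlasOf(dataset), file.path(dir, "atlas.tsv"))
  mf <- studyManifest(dataset)
  paths <- character(nrow(mf))
  for (k in seq_len(nrow(mf))) {
    p <- dataset@panels[[mf$index[k]]]
    paths[k] <- sprintf("ts_%s_%s.tsv", p@subject, p@condition)
    writeMatrixTSV(p@data, file.path(dir, paths[k]),
                   colNames = roiNames(atlasOf(dataset)))
  }
  out <- data.frame(subject = mf$subject, condition = mf$condition,
                    timeseries_path = paths, stringsAsFactors = FALSE)
  utils::write.table(out, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(dataset@groundTruth)) {
    gt <- dataset@groundTruth
    gt$moduleAssignment <- as.integer(gt$moduleAssignment)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(file.path(dir, "manifest.tsv"))
}
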