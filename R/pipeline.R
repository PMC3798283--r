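#' Exclude subjects by head-motion limit
#'
#' Subjects with any scan whose maximum displacement exceeds `limit` in any
#' condition are removed entirely (all four conditions dropped), preserving
#' the paired design and avoiding class imbalance. With no motion table the
#' stage is skipped with a warning.
#'
#' @param dataset a [StudyDataset-class].
#' @param motion data.frame with columns subject, condition,
#'   max_displacement_mm (one row per scan), or NULL.
#' @param limit displacement limit in mm (default 3).
#' @return the filtered [StudyDataset-class]; the exclusion log is attached
#'   as attribute `exclusions`.
#' @export
excludeSubjectsByMotion <- function(dataset, motion, limit = 3) {
  if (is.null(motion)) {
    warning("no motion traces supplied; motion-exclusion stage skipped")
    attr(dataset, "exclusions") <- character()
    return(dataset)
  }
  need <- c("subject", "condition", "max_displacement_mm")
  .assert(all(need %in% names(motion)), "motion table lacks required columns")
  bad <- unique(motion$subject[motion$max_displacement_mm > limit])
  if (!length(bad)) {
    attr(dataset, "exclusions") <- character()
    return(dataset)
  }
  mf <- studyManifest(dataset)
  keep <- !(mf$subject %in% bad)
  .assert(any(keep), "all subjects excluded by the motion limit")
  panels <- dataset@panels[mf$index[keep]]
  out <- new("StudyDataset", atlas = atlasOf(dataset), panels = panels,
             manifest = data.frame(subject = mf$subject[keep],
                                   condition = mf$condition[keep],
                                   index = seq_along(panels),
                                   stringsAsFactors = FALSE),
             groundTruth = dataset@groundTruth)
  attr(out, "exclusions") <- sort(bad)
  out
}

## resolved defaults of every pipeline stage
.defaultConfig <- function() {
  list(
    seed = NULL,
    output_dir = NULL,
    simulation = list(n_subjects = 12L, n_roi = 194L, n_timepoints = 196L,
                      tr = 2.46, n_modules = 6L, lambda = 60, noise_sd = 1,
                      subject_sd = 0.1),
    manifest = NULL,
    motion = list(limit_mm = 3),
    clean = list(enabled = FALSE, band_low_hz = 0.01, band_high_hz = 0.1,
                 trim = 4L),
    thresholds = list(grid_pct = c(11, 16, 21, 26, 31)),
    metrics = c("C", "L", "E", "Q"),
    modularity = list(restarts = 50L, p_tune = 0.45),
    nulls = list(n_null = 100L, swaps_per_edge = 10L,
                 modularity_restarts = 10L),
    classification = list(comparisons = list(c("W", "S"), c("S", "LOC"),
                                             c("LOC", "R"), c("W", "R")),
                          n_perm = 1000L, cost = 1,
                          top_fraction = 0.01),
    distance_bins = list(width_mm = 9, n_bins = 15L),
    local_metrics = list(enabled = FALSE, fdr_q = 0.05),
    write_matrices = FALSE)
}

.mergeConfig <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]])))
      defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, motion exclusion, optional temporal cleaning,
#' connectivity, correlation description (summaries, KS comparisons,
#' distance bins and the distance ANCOVA), proportional thresholding over
#' the density grid, raw and null-normalized graph metrics, pairwise SVM
#' classification with permutation tests, importance maps and edge-kind
#' taxonomy, and the repeated-measures ANOVA framework. All randomness
#' derives from the single master seed; re-running with an identical config
#' is byte-identical.
#'
#' @param config a named list or path to a YAML file. `seed` is required;
#'   every other key falls back to a documented default which is recorded in
#'   the resolved-config dump. Provide either a `simulation` block (the
#'   default synthetic study) or a `manifest` block
#'   (`list(path =, atlas_path =)`).
#' @return invisible list with all stage results; report files are written
#'   to `config$output_dir` when set.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .assert(is.list(config), "config must be a list or a YAML path")
  .assert(!is.null(config$seed), "config error: missing required key 'seed'")
  cfg <- .mergeConfig(.defaultConfig(), config)
  seed <- as.integer(cfg$seed)
  outDir <- cfg$output_dir
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  ## --- stage: data ---------------------------------------------------------
  if (!is.null(cfg$manifest)) {
    atlas <- loadAtlas(cfg$manifest$atlas_path)
    dataset <- loadStudy(cfg$manifest$path, atlas)
  } else {
    sim <- cfg$simulation
    atlas <- makeAtlas(nROI = sim$n_roi, seed = deriveSeed(seed, 1L))
    truth <- makeGroundTruth(atlas, nModules = sim$n_modules,
                             lambda = sim$lambda, noiseSD = sim$noise_sd,
                             subjectSD = sim$subject_sd,
                             seed = deriveSeed(seed, 2L))
    dataset <- simulateStudy(atlas, truth, nSubjects = sim$n_subjects,
                             nTimepoints = sim$n_timepoints, tr = sim$tr,
                             seed = deriveSeed(seed, 3L))
  }
  if (!is.null(cfg$motion$table))
    dataset <- excludeSubjectsByMotion(dataset, cfg$motion$table,
                                       cfg$motion$limit_mm)

  ## --- stage: cleaning + connectivity -------------------------------------
  if (isTRUE(cfg$clean$enabled)) {
    dataset@panels <- lapply(dataset@panels, cleanTimeSeries,
                             band = c(cfg$clean$band_low_hz,
                                      cfg$clean$band_high_hz),
                             trim = cfg$clean$trim)
  }
  matrices <- studyConnectivity(dataset)
  mf <- studyManifest(dataset)
  conds <- intersect(conditionLevels(), unique(mf$condition))
  byCond <- lapply(conds, function(cn) matrices[mf$condition == cn])
  names(byCond) <- conds

  ## --- stage: correlation description --------------------------------------
  summaries <- lapply(byCond, correlationSummary)
  dist <- euclideanDistances(atlasOf(dataset))
  ksPairs <- utils::combn(conds, 2L)
  ks <- lapply(seq_len(ncol(ksPairs)), function(k) {
    a <- .upperValues(meanConnectivity(byCond[[ksPairs[1L, k]]]))
    b <- .upperValues(meanConnectivity(byCond[[ksPairs[2L, k]]]))
    c(list(comparison = paste(ksPairs[1L, k], "vs", ksPairs[2L, k])),
      ksCompare(a, b))
  })
  binTable <- NULL
  for (k in seq_along(matrices)) {
    bt <- binByDistance(matrices[[k]], dist, cfg$distance_bins$width_mm,
                        cfg$distance_bins$n_bins)
    binTable <- rbind(binTable,
                      data.frame(subject = mf$subject[k],
                                 condition = mf$condition[k], bt))
  }
  ancova <- rmAncovaDistance(binTable)

  ## --- stage: thresholding + metrics ---------------------------------------
  grid <- cfg$thresholds$grid_pct
  metricRows <- NULL
  nodal <- NULL
  doLocal <- isTRUE(cfg$local_metrics$enabled)
  mseed <- deriveSeed(seed, 4L)
  for (g in seq_along(grid)) {
    for (k in seq_along(matrices)) {
      bg <- proportionalThreshold(matrices[[k]], grid[g] / 100)
      if (doLocal) {
        nodal <- rbind(nodal,
                       data.frame(subject = mf$subject[k],
                                  condition = mf$condition[k],
                                  densityPct = grid[g],
                                  node = seq_len(nROI(bg)) - 1L,
                                  strength = nodalStrength(bg),
                                  localEff = localEfficiency(bg),
                                  stringsAsFactors = FALSE))
      }
      gm <- graphMetrics(bg, metrics = cfg$metrics,
                         nRestarts = cfg$modularity$restarts,
                         seed = deriveSeed(mseed, g * 1000L + k),
                         pTune = cfg$modularity$p_tune)
      nm <- normalizeMetrics(bg, nNull = cfg$nulls$n_null,
                             seed = deriveSeed(mseed, 500000L + g * 1000L + k),
                             metrics = cfg$metrics,
                             swapsPerEdge = cfg$nulls$swaps_per_edge,
                             modularityRestarts = cfg$nulls$modularity_restarts,
                             pTune = cfg$modularity$p_tune)
      row <- data.frame(subject = mf$subject[k], condition = mf$condition[k],
                        densityPct = grid[g], stringsAsFactors = FALSE)
      for (nm2 in cfg$metrics) row[[nm2]] <- gm[[nm2]]
      if ("Q" %in% cfg$metrics) row$nModules <- gm$nModules
      for (rn in names(nm@ratios)) row[[rn]] <- nm@ratios[[rn]]
      row$sigma <- nm@sigma
      metricRows <- rbind(metricRows, row)
    }
  }
  metricRows$condition <- factor(metricRows$condition, levels = conds)

  ## --- stage: repeated-measures statistics ---------------------------------
  normNames <- c(paste0("n", cfg$metrics),
                 if (all(c("C", "L") %in% cfg$metrics)) "sigma")
  anovas <- lapply(normNames, function(v) {
    d <- data.frame(subject = metricRows$subject,
                    condition = metricRows$condition,
                    threshold = metricRows$densityPct,
                    value = metricRows[[v]])
    list(twoWay = rmAnova(d), perThreshold = perThresholdAnovas(d))
  })
  names(anovas) <- normNames

  ## --- stage: node-wise local metrics --------------------------------------
  localStats <- NULL
  if (doLocal) {
    localStats <- lapply(c("strength", "localEff"), function(v) {
      pvals <- vapply(sort(unique(nodal$node)), function(nd) {
        d <- nodal[nodal$node == nd, , drop = FALSE]
        res <- rmAnova(data.frame(subject = d$subject,
                                  condition = factor(d$condition, conds),
                                  threshold = d$densityPct,
                                  value = d[[v]]))
        res$effects$p[res$effects$effect == "condition"]
      }, numeric(1L))
      fdr <- nodewiseFdr(pvals, q = cfg$local_metrics$fdr_q)
      data.frame(node = sort(unique(nodal$node)), p = pvals,
                 pFdr = fdr$adjustedP, significant = fdr$rejected)
    })
    names(localStats) <- c("strength", "localEff")
  }

  ## --- stage: classification -----------------------------------------------
  cseed <- deriveSeed(seed, 5L)
  classif <- list()
  comparisons <- cfg$classification$comparisons
  for (ci in seq_along(comparisons)) {
    cmp <- comparisons[[ci]]
    gA <- byCond[[cmp[1L]]]
    gB <- byCond[[cmp[2L]]]
    res <- loocvClassify(gA, gB, svmCost = cfg$classification$cost)
    res <- permutationTest(res, gA, gB, nPerm = cfg$classification$n_perm,
                           seed = deriveSeed(cseed, ci),
                           familySize = length(comparisons))
    maps <- importanceMaps(res, gA, gB)
    top <- topEdges(res@weightMatrix, cfg$classification$top_fraction)
    inA <- maps$mapA[cbind(top$i, top$j)] != 0
    kindsA <- classifyEdgeKinds(top[inA, , drop = FALSE],
                                atlasOf(dataset), maps$mapA)
    kindsB <- classifyEdgeKinds(top[!inA, , drop = FALSE],
                                atlasOf(dataset), maps$mapB)
    classif[[paste(cmp, collapse = "_vs_")]] <-
      list(result = res, maps = maps, topEdges = top,
           kindsA = kindsA, kindsB = kindsB)
  }

  out <- list(config = cfg, dataset = dataset, matrices = matrices,
              summaries = summaries, ks = ks, binTable = binTable,
              ancova = ancova, metrics = metricRows, anovas = anovas,
              nodalMetrics = nodal, localStats = localStats,
              classification = classif)

  if (!is.null(outDir)) .writeReports(out, outDir)
  invisible(out)
}

## plain-text report bundle; everything deterministic (no timestamps)
.writeReports <- function(out, outDir) {
  cfgDump <- out$config
  cfgDump$motion$table <- NULL
  cfgDump$output_dir <- NULL    # the dump lives inside it
  yaml::write_yaml(cfgDump, file.path(outDir, "resolved_config.yaml"))
  utils::write.table(out$metrics, file.path(outDir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$binTable, file.path(outDir, "distance_bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out$summaries,
                       file.path(outDir, "correlation_summaries.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(out$ks, file.path(outDir, "ks_tests.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(out$ancova$ancova, file.path(outDir, "ancova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (v in names(out$anovas)) {
    utils::write.table(out$anovas[[v]]$twoWay$effects,
                       file.path(outDir, sprintf("anova_%s.tsv", v)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$anovas[[v]]$twoWay$pairwise,
                       file.path(outDir, sprintf("pairwise_%s.tsv", v)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$localStats)) {
    for (v in names(out$localStats))
      utils::write.table(out$localStats[[v]],
                         file.path(outDir, sprintf("nodewise_%s.tsv", v)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (cmp in names(out$classification)) {
    cl <- out$classification[[cmp]]
    jsonlite::write_json(
      list(comparison = cl$result@comparison,
           accuracy = cl$result@accuracy,
           sensitivity = cl$result@sensitivity,
           specificity = cl$result@specificity,
           p_perm = cl$result@pPerm,
           p_bonferroni = cl$result@pBonferroni,
           n_perm = cl$result@nPerm),
      file.path(outDir, sprintf("classification_%s.json", cmp)),
      auto_unbox = TRUE, digits = NA)
    kindTab <- rbind(if (nrow(cl$kindsA)) cbind(class = "A", cl$kindsA),
                     if (nrow(cl$kindsB)) cbind(class = "B", cl$kindsB))
    if (is.null(kindTab))
      kindTab <- data.frame(class = character(), kind = character(),
                            sign = character(), count = integer(),
                            percent = numeric())
    utils::write.table(kindTab,
                       file.path(outDir, sprintf("edge_kinds_%s.tsv", cmp)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (isTRUE(out$config$write_matrices)) {
    mdir <- file.path(outDir, "matrices")
    dir.create(mdir, showWarnings = FALSE)
    mf <- studyManifest(out$dataset)
    for (k in seq_along(out$matrices))
      writeMatrixTSV(connectivityValues(out$matrices[[k]]),
                     file.path(mdir, sprintf("corr_%s_%s.tsv",
                                             mf$subject[k], mf$condition[k])),
                     colNames = roiNames(atlasOf(out$dataset)))
  }
  manifest <- list(package = "stateFC",
                   version = as.character(utils::packageVersion("stateFC")),
                   master_seed = out$config$seed,
                   n_subjects = length(subjects(out$dataset)),
                   n_roi = nROI(out$dataset),
                   thresholds_pct = out$config$thresholds$grid_pct,
                   n_null = out$config$nulls$n_null,
                   n_perm = out$config$classification$n_perm,
                   modularity_engine = "igraph Louvain + fine/probabilistic tuning")
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
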