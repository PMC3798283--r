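#' Vectorize a connectivity matrix into an edge feature vector
#'
#' Upper triangle (i < j) in row-major order; [devectorizeFeatures()] is the
#' exact inverse (symmetric matrix, zero diagonal).
#'
#' @param matrix a [ConnectivityMatrix-class] or plain symmetric matrix.
#' @return numeric vector of length N(N-1)/2.
#' @export
vectorizeFeatures <- function(matrix) {
  v <- if (is(matrix, "ConnectivityMatrix")) connectivityValues(matrix) else matrix
  .upperValues(v)
}

#' @rdname vectorizeFeatures
#' @param v feature vector of length N(N-1)/2.
#' @param n number of nodes.
#' @export
devectorizeFeatures <- function(v, n) .fromUpperValues(v, n)

## Exact rank reduction for the linear kernel: the thin SVD X = U D V' leaves
## the Gram matrix XX' unchanged when X is replaced by Z = U D, so e1071
## reaches the identical dual solution on the n-dimensional Z; hyperplane
## weights map back exactly as w = V w_z.
.reduceFeatures <- function(x) {
  s <- svd(x)
  list(z = s$u %*% diag(s$d, length(s$d)), v = s$v)
}

## one linear SVM fit; returns the weight vector in z-space, oriented so
## class "A" sits on the positive side, plus a prediction closure
.svmFit <- function(z, y, cost) {
  fit <- e1071::svm(x = z, y = factor(y, levels = c("A", "B")),
                    kernel = "linear", cost = cost, scale = FALSE,
                    type = "C-classification")
  wz <- drop(t(fit$coefs) %*% fit$SV)
  rho <- fit$rho
  dec <- drop(z %*% wz) - rho
  ## orient: decision > 0 must mean class A
  if (mean(dec[y == "A"]) < mean(dec[y == "B"])) {
    wz <- -wz
    rho <- -rho
  }
  list(wz = wz, rho = rho)
}

## leave-one-subject-out accuracy on reduced features (fast core shared by
## classification and the permutation test)
.loocvCore <- function(z, y, subject, cost) {
  pred <- character(length(y))
  for (s in unique(subject)) {
    test <- subject == s
    fit <- .svmFit(z[!test, , drop = FALSE], y[!test], cost)
    dec <- drop(z[test, , drop = FALSE] %*% fit$wz) - fit$rho
    pred[test] <- ifelse(dec > 0, "A", "B")
  }
  pred
}

#' Leave-one-subject-out SVM classification of two matched groups
#'
#' The two groups hold one unthresholded correlation matrix per subject each
#' (paired design). One fold per subject: both of that subject's samples are
#' held out, a linear SVM (cost `svmCost`) is trained on the remaining
#' subjects and both held-out samples are predicted. Accuracy is the percent
#' correct over all held-out samples; sensitivity and specificity are the
#' class-A and class-B percents. The hyperplane weight vector of the
#' full-sample fit is mapped back to an N x N symmetric weight matrix
#' (class A coded positive).
#'
#' @param groupA,groupB lists of [ConnectivityMatrix-class], paired by
#'   subject (equal sizes, same subject set).
#' @param svmCost SVM cost parameter (default 1).
#' @param comparison optional label; defaults to "condA vs condB".
#' @return a [ClassificationResult-class] (permutation p set to NA; see
#'   [permutationTest()]).
#' @export
loocvClassify <- function(groupA, groupB, svmCost = 1, comparison = NULL) {
  prep <- .pairGroups(groupA, groupB)
  red <- .reduceFeatures(prep$x)
  pred <- .loocvCore(red$z, prep$y, prep$subject, svmCost)
  correct <- pred == prep$y
  full <- .svmFit(red$z, prep$y, svmCost)
  w <- drop(red$v %*% full$wz)
  if (is.null(comparison)) comparison <- prep$label
  new("ClassificationResult", comparison = comparison,
      folds = data.frame(subject = prep$subject, class = prep$y,
                         predicted = pred, correct = correct,
                         stringsAsFactors = FALSE),
      accuracy = 100 * mean(correct),
      sensitivity = 100 * mean(correct[prep$y == "A"]),
      specificity = 100 * mean(correct[prep$y == "B"]),
      weightMatrix = devectorizeFeatures(w, prep$n),
      pPerm = NA_real_, pBonferroni = NA_real_, nPerm = 0L, cost = svmCost)
}

## validate pairing and assemble the stacked feature matrix
.pairGroups <- function(groupA, groupB) {
  .assert(length(groupA) == length(groupB) && length(groupA) >= 2L,
          "groups must be non-trivial and of equal size")
  subA <- vapply(groupA, function(m) m@subject, "")
  subB <- vapply(groupB, function(m) m@subject, "")
  .assert(setequal(subA, subB) && !anyDuplicated(subA),
          "groups must be paired by subject")
  groupB <- groupB[match(subA, subB)]
  n <- nROI(groupA[[1L]])
  x <- t(vapply(c(groupA, groupB), vectorizeFeatures,
                numeric(n * (n - 1L) / 2L)))
  condA <- unique(vapply(groupA, function(m) m@condition, ""))
  condB <- unique(vapply(groupB, function(m) m@condition, ""))
  list(x = x, y = rep(c("A", "B"), each = length(groupA)),
       subject = c(subA, subA), n = n,
       label = paste(paste(condA, collapse = "&"), "vs",
                     paste(condB, collapse = "&")))
}

#' Permutation significance of a LOOCV classification
#'
#' Each permutation independently flips each subject's pair of class labels
#' with probability 1/2 (the exchangeable operations under the paired null),
#' reruns the full leave-one-subject-out procedure and records the accuracy.
#' The +1-smoothed p-value is `(1 + #{perm accuracy >= observed}) /
#' (nPerm + 1)`; a Bonferroni-adjusted p is reported for the given family
#' size.
#'
#' @param result the [ClassificationResult-class] from [loocvClassify()].
#' @param groupA,groupB the same groups that produced `result`.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @param familySize number of classifications in the family (Bonferroni).
#' @return `result` with `pPerm`, `pBonferroni`, `nPerm` filled in.
#' @export
permutationTest <- function(result, groupA, groupB, nPerm = 1000L, seed = 1L,
                            familySize = 1L) {
  .assert(nPerm >= 1L, "nPerm must be at least 1")
  prep <- .pairGroups(groupA, groupB)
  red <- .reduceFeatures(prep$x)
  nSub <- length(groupA)
  observed <- result@accuracy
  set.seed(seed)
  permAcc <- numeric(nPerm)
  yA <- prep$y[seq_len(nSub)]
  yB <- prep$y[nSub + seq_len(nSub)]
  for (p in seq_len(nPerm)) {
    flip <- stats::runif(nSub) < 0.5
    y <- c(ifelse(flip, "B", yA), ifelse(flip, "A", yB))
    pred <- .loocvCore(red$z, y, prep$subject, result@cost)
    permAcc[p] <- 100 * mean(pred == y)
  }
  pval <- (1 + sum(permAcc >= observed)) / (nPerm + 1)
  result@pPerm <- pval
  result@pBonferroni <- min(1, pval * familySize)
  result@nPerm <- as.integer(nPerm)
  result
}

#' Importance maps of a classification
#'
#' The hyperplane weight matrix (class A coded positive) is split into two
#' sparse matrices: each edge is assigned to the class whose correct
#' classification it contributes more to, i.e. to A when
#' `w (meanA + meanB) >= 0` and to B otherwise. When both class means are
#' positive — the overwhelmingly common case — this reduces to a plain split
#' by the sign of `w`; edges driven by anticorrelation are credited to the
#' class in which they are negative. Each sparse matrix (in absolute value)
#' is multiplied elementwise by the mean unthresholded correlation matrix
#' over that class's correctly classified samples, so the sign of a map
#' entry reflects the sign of the contributing correlation and its magnitude
#' the contribution strength. The two supports are disjoint and partition
#' the weight support.
#'
#' @param result a [ClassificationResult-class].
#' @param groupA,groupB the groups that produced `result`.
#' @return list with `mapA`, `mapB` (N x N sparse-as-dense matrices),
#'   `meanA`, `meanB` (the class means used).
#' @export
importanceMaps <- function(result, groupA, groupB) {
  prep <- .pairGroups(groupA, groupB)
  folds <- result@folds
  okA <- folds$subject[folds$class == "A" & folds$correct]
  okB <- folds$subject[folds$class == "B" & folds$correct]
  .assert(length(okA) > 0L, "no correctly classified class-A samples")
  .assert(length(okB) > 0L, "no correctly classified class-B samples")
  subA <- vapply(groupA, function(m) m@subject, "")
  subB <- vapply(groupB, function(m) m@subject, "")
  meanA <- meanConnectivity(groupA[subA %in% okA])
  meanB <- meanConnectivity(groupB[subB %in% okB])
  w <- result@weightMatrix
  toA <- w * (meanA + meanB) >= 0 & w != 0
  mapA <- ifelse(toA, abs(w), 0) * meanA
  mapB <- ifelse(!toA & w != 0, abs(w), 0) * meanB
  list(mapA = mapA, mapB = mapB, meanA = meanA, meanB = meanB)
}

#' Top discriminative edges of a weight matrix
#'
#' Edges ranked by absolute hyperplane weight; the top
#' `round(fraction * M)` are returned (ties broken by row-major index
#' order). Deterministic under re-run.
#'
#' @param weightMatrix N x N symmetric weight matrix.
#' @param fraction proportion of the N(N-1)/2 possible edges (default 0.01).
#' @return data.frame with `i`, `j` (1-based, i < j) and `weight`.
#' @export
topEdges <- function(weightMatrix, fraction = 0.01) {
  .assert(fraction > 0 && fraction <= 1, "fraction must lie in (0, 1]")
  n <- nrow(weightMatrix)
  pairs <- .upperPairs(n)
  v <- .upperValues(weightMatrix)
  if (fraction == 1) {
    keep <- which(v != 0)
    keep <- keep[order(-abs(v[keep]))]
  } else {
    k <- roundHalfUp(fraction * length(v))
    keep <- order(-abs(v))[seq_len(k)]
  }
  data.frame(i = pairs[keep, 1L], j = pairs[keep, 2L], weight = v[keep])
}

## canonical names of the 15 unordered subdivision-class pairs
.kindName <- function(a, b) {
  key <- function(x, y) paste(sort(c(x, y)), collapse = "|")
  nm <- c("basal ganglia|basal ganglia" = "striato-striatal",
          "basal ganglia|cortex"        = "striato-cortical",
          "basal ganglia|thalamus"      = "thalamo-striatal",
          "basal ganglia|cerebellum"    = "cerebello-striatal",
          "basal ganglia|brainstem"     = "brainstem-striatal",
          "cortex|cortex"               = "cortico-cortical",
          "cortex|thalamus"             = "thalamo-cortical",
          "cerebellum|cortex"           = "cerebello-cortical",
          "brainstem|cortex"            = "brainstem-cortical",
          "thalamus|thalamus"           = "thalamo-thalamic",
          "cerebellum|thalamus"         = "cerebello-thalamic",
          "brainstem|thalamus"          = "brainstem-thalamic",
          "cerebellum|cerebellum"       = "cerebello-cerebellar",
          "brainstem|cerebellum"        = "cerebello-brainstem",
          "brainstem|brainstem"         = "brainstem-brainstem")
  unname(nm[mapply(key, a, b)])
}

#' Anatomical taxonomy of classifying edges
#'
#' Each edge is assigned the unordered pair of coarse subdivision classes of
#' its endpoints (cortex — collapsing the four lobes —, thalamus, basal
#' ganglia, cerebellum, brainstem; 15 kinds) crossed with the sign of the
#' contributing correlation taken from an importance map.
#'
#' @param edges data.frame from [topEdges()].
#' @param atlas the [ROIAtlas-class].
#' @param signSource N x N matrix whose entry signs give the correlation
#'   sign of each edge (e.g. `mapA + mapB` from [importanceMaps()], whose
#'   supports are disjoint).
#' @return data.frame with `kind`, `sign`, `count`, `percent`; counts sum to
#'   `nrow(edges)`.
#' @export
classifyEdgeKinds <- function(edges, atlas, signSource) {
  if (nrow(edges) == 0L)
    return(data.frame(kind = character(), sign = character(),
                      count = integer(), percent = numeric()))
  cls <- .subdivisionClass(subdivisions(atlas))
  kind <- .kindName(cls[edges$i], cls[edges$j])
  sgn <- ifelse(signSource[cbind(edges$i, edges$j)] < 0, "negative", "positive")
  tab <- table(kind = paste(kind, sgn, sep = ", "))
  df <- data.frame(kind = names(tab), count = as.vector(tab),
                   stringsAsFactors = FALSE)
  df$sign <- ifelse(grepl("negative$", df$kind), "negative", "positive")
  df$percent <- 100 * df$count / sum(df$count)
  df[order(-df$count), c("kind", "sign", "count", "percent")]
}

#' Chi-square comparison of two edge-kind distributions
#'
#' Pearson chi-square (no continuity correction) on the 2 x k contingency
#' table of kind counts; kinds with zero total across both conditions are
#' dropped before testing, so df = k - 1.
#'
#' @param countsA,countsB data.frames from [classifyEdgeKinds()].
#' @return list with `chi2`, `df`, `p` and the `table` used.
#' @export
compareEdgeDistributions <- function(countsA, countsB) {
  kinds <- union(countsA$kind, countsB$kind)
  a <- countsA$count[match(kinds, countsA$kind)]
  b <- countsB$count[match(kinds, countsB$kind)]
  a[is.na(a)] <- 0
  b[is.na(b)] <- 0
  keep <- (a + b) > 0
  tab <- rbind(A = a[keep], B = b[keep])
  colnames(tab) <- kinds[keep]
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}
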