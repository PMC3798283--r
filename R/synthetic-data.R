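#' Planted condition effect on the coupling structure
#'
#' Describes how one scan condition perturbs the baseline inter-ROI coupling
#' matrix of the generator: a global multiplicative gain on all couplings,
#' additive block changes on subdivision-class pairs (e.g. thalamo-cortical
#' hyperconnectivity), a target fraction of negative cortico-cortical
#' couplings, and multipliers that raise local clustering through the
#' module or the triangle-closure pathway.
#'
#' @param condition one of W, S, LOC, R.
#' @param globalGain multiplier (> 0) applied to every off-diagonal coupling.
#' @param blockDeltas list of `list(a =, b =, delta =)` entries; `a`/`b` are
#'   subdivision labels or the coarse classes "cortex", "thalamus",
#'   "basal ganglia", "cerebellum", "brainstem".
#' @param negativeFraction proportion in [0, 1) of all ROI pairs whose
#'   coupling is flipped negative (drawn among cortico-cortical pairs).
#' @param clusteringBoost multiplier on within-module couplings (raises
#'   segregation along the module pathway: clustering and path length move
#'   together).
#' @param triangleBoost triangle-closure multiplier (> 1 strengthens each
#'   coupling in proportion to its normalized two-path support, closing
#'   triangles): raises clustering with little effect on shortest paths.
#' @return a list of class `EffectSpec`.
#' @export
effectSpec <- function(condition, globalGain = 1, blockDeltas = list(),
                       negativeFraction = 0, clusteringBoost = 1,
                       triangleBoost = 1) {
  .assert(condition %in% conditionLevels(), "unknown condition")
  .assert(globalGain > 0, "globalGain must be > 0")
  .assert(negativeFraction >= 0 && negativeFraction < 1,
          "negativeFraction must lie in [0, 1)")
  structure(list(condition = condition, globalGain = globalGain,
                 blockDeltas = blockDeltas,
                 negativeFraction = negativeFraction,
                 clusteringBoost = clusteringBoost,
                 triangleBoost = triangleBoost),
            class = "EffectSpec")
}

#' Default planted effects of the four-condition study
#'
#' The defaults emulate the qualitative condition structure of a propofol
#' multi-stage design: S adds thalamo-cortical (and milder cortico-cortical)
#' hyperconnectivity on top of wakefulness; LOC globally weakens couplings,
#' plants 14% negative cortico-cortical pairs and boosts within-module
#' coupling (elevated clustering and path length); R is at the wakefulness
#' level with a triangle-closure boost (elevated clustering, path length at
#' baseline).
#'
#' @return named list of [effectSpec()] objects, one per condition.
#' @export
defaultEffects <- function() {
  list(
    W = effectSpec("W"),
    S = effectSpec("S", globalGain = 1, clusteringBoost = 1.03,
                   blockDeltas = list(
                     list(a = "thalamus", b = "cortex", delta = 0.25),
                     list(a = "cortex", b = "cortex", delta = 0.03))),
    LOC = effectSpec("LOC", globalGain = 0.50, negativeFraction = 0.14,
                     clusteringBoost = 1.75),
    R = effectSpec("R", globalGain = 1, triangleBoost = 1.3))
}

#' Generator ground truth
#'
#' Fixes everything the synthetic study needs beyond the atlas: the module
#' assignment of ROIs (random, so that module structure and the distance
#' kernel contribute separately identifiable coupling components), the
#' distance-decay length-scale, the baseline coupling constants, the noise
#' level, the between-subject variability and the per-condition effects.
#'
#' @param atlas an [ROIAtlas-class].
#' @param nModules number of planted modules (default 6).
#' @param lambda distance-decay length-scale in mm (default 60; `Inf` removes
#'   the distance dependence).
#' @param noiseSD independent Gaussian noise SD relative to unit signal
#'   variance (default 1).
#' @param subjectSD SD of the multiplicative log-normal subject perturbation
#'   of couplings (default 0.1), shared across a subject's four scans.
#' @param scanSD SD of the additional scan-level log-normal perturbation of
#'   individual couplings (default 0.06): pairwise state fluctuations
#'   between scans of the same subject.
#' @param stateSD SD of the scan-level log-normal fluctuation of the common
#'   within-module coupling factor (default 0.08): a global
#'   segregation-state fluctuation between scans, the dominant
#'   within-subject error source of the graph-level repeated-measures
#'   design.
#' @param effects named list of [effectSpec()]s (default [defaultEffects()]).
#' @param baseCoupling,distCoupling,moduleCoupling covariance contribution of
#'   the global factor, the distance kernel and the module factors.
#' @param factorCoupling,factorRank covariance contribution and rank of the
#'   unstructured latent factors (random loadings shared by all subjects)
#'   that create realistic pair-level coupling heterogeneity. The five
#'   coupling constants are chosen so the wakefulness condition yields
#'   median r near 0.2 with about 80% of correlations in [0, 0.4].
#' @param signalVar variance of the latent signal relative to unit-variance
#'   independent noise when `noiseSD = 1` (default 3): observed correlations
#'   are the signal correlations shrunk by signalVar/(signalVar + noiseSD^2).
#' @param antiGain amplification of the negated global-factor loading of
#'   anti-phase cortical nodes used to plant negative cortico-cortical
#'   couplings (default 2.5; large enough that planted anticorrelations
#'   exceed the corresponding positive couplings of the unaffected
#'   conditions in magnitude).
#' @param seed integer seed fixing the module assignment.
#' @return list of class `GroundTruth`.
#' @export
makeGroundTruth <- function(atlas, nModules = 6L, lambda = 60, noiseSD = 1,
                            subjectSD = 0.1, scanSD = 0.06, stateSD = 0.07,
                            effects = defaultEffects(),
                            baseCoupling = 0.25, distCoupling = 0.5,
                            moduleCoupling = 0.35, factorCoupling = 0.4,
                            factorRank = 5L, signalVar = 3,
                            antiGain = 2.5, seed = 1L) {
  .assert(all(conditionLevels() %in% names(effects)),
          "effects must cover W, S, LOC, R")
  n <- nROI(atlas)
  .assert(nModules >= 1L && nModules <= n, "invalid nModules")
  set.seed(deriveSeed(seed, 7L))
  assign <- sample(rep_len(seq_len(nModules), n))
  structure(list(moduleAssignment = as.integer(assign),
                 nModules = as.integer(nModules), lambda = lambda,
                 noiseSD = noiseSD, subjectSD = subjectSD, scanSD = scanSD,
                 stateSD = stateSD,
                 baseCoupling = baseCoupling, distCoupling = distCoupling,
                 moduleCoupling = moduleCoupling,
                 factorCoupling = factorCoupling,
                 factorRank = as.integer(factorRank), signalVar = signalVar,
                 antiGain = antiGain,
                 effects = effects, seed = as.integer(seed)),
            class = "GroundTruth")
}

#' Generate a synthetic ROI atlas
#'
#' ROIs are allotted to the eight subdivisions in the given proportions
#' (largest-remainder rounding) and placed uniformly inside
#' subdivision-specific boxes of a brain-sized bounding volume.
#'
#' @param nROI number of regions (default 194).
#' @param subdivisionFractions named proportions over [subdivisionLevels()]
#'   summing to 1.
#' @param seed integer seed; identical seeds give identical atlases.
#' @return an [ROIAtlas-class].
#' @export
makeAtlas <- function(nROI = 194L,
                      subdivisionFractions = c(Fcx = 0.28, Tcx = 0.18,
                                               Pcx = 0.16, Ocx = 0.12,
                                               BG = 0.07, Thl = 0.05,
                                               BS = 0.04, Crbl = 0.10),
                      seed = 1L) {
  .assert(nROI >= 8L, "nROI must be at least 8")
  f <- subdivisionFractions[subdivisionLevels()]
  .assert(!anyNA(f), "subdivisionFractions must name all 8 subdivisions")
  .assert(abs(sum(f) - 1) <= 1e-9, "subdivision fractions must sum to 1")
  ## largest-remainder apportionment
  raw <- f * nROI
  counts <- floor(raw)
  left <- nROI - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1L
  }
  boxes <- list(  # mm, MNI-like bounding volumes
    Fcx  = rbind(x = c(-60, 60), y = c(10, 75),    z = c(-20, 60)),
    Tcx  = rbind(x = c(-70, 70), y = c(-50, 15),   z = c(-40, 0)),
    Pcx  = rbind(x = c(-60, 60), y = c(-75, -25),  z = c(20, 70)),
    Ocx  = rbind(x = c(-55, 55), y = c(-105, -60), z = c(-15, 30)),
    BG   = rbind(x = c(-30, 30), y = c(-15, 20),   z = c(-10, 20)),
    Thl  = rbind(x = c(-20, 20), y = c(-30, 0),    z = c(0, 15)),
    BS   = rbind(x = c(-15, 15), y = c(-40, -15),  z = c(-45, -15)),
    Crbl = rbind(x = c(-50, 50), y = c(-80, -40),  z = c(-55, -25)))
  set.seed(deriveSeed(seed, 3L))
  sub <- rep(subdivisionLevels(), times = counts)
  xyz <- t(vapply(sub, function(s) {
    b <- boxes[[s]]
    stats::runif(3L, b[, 1L], b[, 2L])
  }, numeric(3L)))
  ROIAtlas(seq_len(nROI) - 1L,
           sprintf("%s_%03d", sub, stats::ave(seq_along(sub), sub, FUN = seq_along)),
           sub, xyz[, 1L], xyz[, 2L], xyz[, 3L])
}

## Baseline signal correlation implied by the latent-factor model: a global
## factor, one factor per module, a spatial field with exponential kernel,
## and `factorRank` unstructured factors with random loadings (the source of
## pair-level heterogeneity). Every component is PSD, so the normalized sum
## is a valid correlation matrix by construction.
.baseCouplings <- function(atlas, truth, seed) {
  n <- nROI(atlas)
  d <- euclideanDistances(atlas)
  decay <- if (is.infinite(truth$lambda)) matrix(1, n, n)
           else exp(-d / truth$lambda)
  same <- outer(truth$moduleAssignment, truth$moduleAssignment, "==")
  s <- truth$baseCoupling + truth$distCoupling * decay +
    truth$moduleCoupling * same
  diag(s) <- truth$baseCoupling + truth$distCoupling + truth$moduleCoupling
  if (truth$factorCoupling > 0 && truth$factorRank > 0L) {
    set.seed(seed)
    a <- matrix(stats::rnorm(n * truth$factorRank), n)
    s <- s + truth$factorCoupling * tcrossprod(a) / truth$factorRank
  }
  stats::cov2cor(s)
}

## logical matrix of pairs belonging to a subdivision-class block
.blockMask <- function(atlas, a, b) {
  cls <- .subdivisionClass(subdivisions(atlas))
  ca <- if (a %in% subdivisionLevels()) as.character(subdivisions(atlas)) == a else cls == a
  cb <- if (b %in% subdivisionLevels()) as.character(subdivisions(atlas)) == b else cls == b
  m <- outer(ca, cb, "&") | outer(cb, ca, "&")
  diag(m) <- FALSE
  m
}

## Apply one condition's EffectSpec to the baseline coupling matrix.
## Negative cortico-cortical couplings are planted through an anti-phase
## cortical factor (a rank-1 PSD component with mixed-sign loadings), whose
## anti-set is grown until the expected negative-edge fraction meets the
## target; random independent sign flips are geometrically incompatible
## with an otherwise positive correlation structure.
## Returns list(coupling, negPairs) with the planted negative pair indices
## (row-major upper triangle).
.applyEffect <- function(s, effect, atlas, truth, seed) {
  n <- nrow(s)
  off <- !diag(n)
  s[off] <- s[off] * effect$globalGain
  for (bd in effect$blockDeltas) {
    m <- .blockMask(atlas, bd$a, bd$b)
    s[m] <- s[m] + bd$delta
  }
  if (effect$clusteringBoost != 1) {
    same <- outer(truth$moduleAssignment, truth$moduleAssignment, "==")
    diag(same) <- FALSE
    s[same] <- s[same] * effect$clusteringBoost
  }
  if (!is.null(effect$triangleBoost) && effect$triangleBoost != 1) {
    ## strengthen couplings in proportion to their two-path support,
    ## closing triangles without rerouting shortest paths
    pos <- pmax(s, 0); diag(pos) <- 0
    supp <- pos %*% pos
    diag(supp) <- 0
    u <- supp / max(supp)
    s[off] <- s[off] * (1 + (effect$triangleBoost - 1) * u[off])
    s[off] <- pmin(s[off], 0.95)
  }
  negPairs <- integer()
  if (effect$negativeFraction > 0) {
    ## anti-phase cortical set: the selected nodes' loading on the global
    ## factor is negated (and amplified by gamma), turning their long-range
    ## cortico-cortical couplings negative while nearby/same-module pairs
    ## stay weakly positive; the set is grown until the expected
    ## negative-edge fraction meets the target
    gamma <- if (is.null(truth$antiGain)) 2.5 else truth$antiGain
    tot <- truth$baseCoupling + truth$distCoupling + truth$moduleCoupling +
      truth$factorCoupling
    q <- truth$baseCoupling / tot         # global-factor share of couplings
    cortex <- which(.subdivisionClass(subdivisions(atlas)) == "cortex")
    set.seed(seed)
    ord <- sample(cortex)
    target <- effect$negativeFraction
    candidate <- function(k) {
      antiSet <- ord[seq_len(k)]
      isAnti <- seq_len(n) %in% antiSet
      delta <- matrix(0, n, n)
      delta[isAnti, !isAnti] <- -(1 + gamma) * q
      delta[!isAnti, isAnti] <- -(1 + gamma) * q
      delta[isAnti, isAnti] <- (gamma^2 - 1) * q
      d <- ifelse(isAnti, 1 + (gamma^2 - 1) * q, 1)
      cand <- (s + delta) / sqrt(outer(d, d))
      diag(cand) <- 1
      cand
    }
    fracNeg <- function(m) mean(.upperValues(m) < 0)
    lo <- 1L; hi <- floor(length(cortex) / 2)
    .assert(fracNeg(candidate(hi)) >= target,
            "negative fraction target unreachable: maximum expected ",
            "fraction is ", signif(fracNeg(candidate(hi)), 3))
    while (lo < hi) {           # smallest anti-set meeting the target
      mid <- (lo + hi) %/% 2L
      if (fracNeg(candidate(mid)) >= target) hi <- mid else lo <- mid + 1L
    }
    s <- candidate(lo)
    v <- .upperValues(s)
    negPairs <- which(v < 0)
  }
  list(coupling = s, negPairs = negPairs)
}

## smooth unit-variance Gaussian processes, T x n (Gaussian kernel, sd in TRs)
.smoothGP <- function(nT, n, kernelSD = 1.2) {
  half <- ceiling(3 * kernelSD)
  k <- stats::dnorm(seq(-half, half), sd = kernelSD)
  k <- k / sqrt(sum(k^2))
  z <- matrix(stats::rnorm((nT + 2L * half) * n), ncol = n)
  f <- stats::filter(z, k, method = "convolution", sides = 2L)
  f[(half + 1L):(half + nT), , drop = FALSE]
}

## clip eigenvalues to make a symmetric matrix positive semi-definite;
## returns list(mat, clipped)
.psdClip <- function(s, floorEig = 1e-6) {
  e <- eigen(s, symmetric = TRUE)
  if (min(e$values) >= floorEig) return(list(mat = s, clipped = FALSE))
  v <- pmax(e$values, floorEig)
  m <- e$vectors %*% (v * t(e$vectors))
  ## restore unit diagonal so couplings keep their correlation scale
  dd <- sqrt(diag(m))
  m <- m / tcrossprod(dd)
  list(mat = (m + t(m)) / 2, clipped = TRUE)
}

#' Simulate a multi-subject, multi-condition synthetic study
#'
#' For each subject and condition, ROI time series arise from a latent
#' factor model: a global factor, one smooth Gaussian-process signal per
#' module, a spatially correlated field whose coupling decays as
#' exp(-d/lambda), and independent Gaussian noise. The implied inter-ROI
#' coupling matrix is perturbed by the condition's [effectSpec()] (global
#' gain, block deltas, an anti-phase cortical factor planting the target
#' fraction of negative cortico-cortical couplings shared across subjects,
#' within-module boost) and by a multiplicative log-normal subject effect,
#' repaired by eigenvalue clipping when the perturbations break positive
#' semi-definiteness (with a warning), and sampled by mixing smooth Gaussian
#' processes plus white noise.
#'
#' @param atlas an [ROIAtlas-class].
#' @param truth a [makeGroundTruth()] object.
#' @param nSubjects number of subjects (default 12).
#' @param nTimepoints timepoints per scan (default 196).
#' @param tr repetition time, seconds (default 2.46).
#' @param seed integer master seed; identical seeds and parameters give
#'   bit-identical datasets.
#' @return a [StudyDataset-class] with the ground truth attached
#'   (including the planted negative-pair indices per condition).
#' @export
simulateStudy <- function(atlas, truth, nSubjects = 12L, nTimepoints = 196L,
                          tr = 2.46, seed = 1L) {
  .assert(nSubjects >= 2L, "nSubjects must be at least 2")
  .assert(nTimepoints >= 20L, "nTimepoints must be at least 20")
  n <- nROI(atlas)
  conds <- conditionLevels()
  base <- .baseCouplings(atlas, truth, deriveSeed(seed, 9L))
  applied <- lapply(seq_along(conds), function(ci)
    .applyEffect(base, truth$effects[[conds[ci]]], atlas, truth,
                 deriveSeed(seed, 50L + ci)))
  names(applied) <- conds
  condCouplings <- lapply(applied, `[[`, "coupling")
  negPairs <- lapply(applied, `[[`, "negPairs")

  subjectIds <- sprintf("sub%02d", seq_len(nSubjects))
  panels <- vector("list", nSubjects * length(conds))
  manifest <- data.frame(subject = character(), condition = character(),
                         index = integer(), stringsAsFactors = FALSE)
  nClipped <- 0L
  k <- 0L
  for (si in seq_len(nSubjects)) {
    ## subject perturbation shared across the four scans (paired design)
    set.seed(deriveSeed(seed, 100L + si))
    pv <- exp(stats::rnorm(n * (n - 1L) / 2L, sd = truth$subjectSD))
    pert <- .fromUpperValues(pv, n)
    diag(pert) <- 1
    scanSD <- if (is.null(truth$scanSD)) 0 else truth$scanSD
    stateSD <- if (is.null(truth$stateSD)) 0 else truth$stateSD
    same <- outer(truth$moduleAssignment, truth$moduleAssignment, "==")
    for (ci in seq_along(conds)) {
      s <- condCouplings[[ci]]
      off <- !diag(n)
      set.seed(deriveSeed(seed, 5000L + si * 10L + ci))
      scanPert <- if (scanSD > 0) {
        .fromUpperValues(exp(stats::rnorm(n * (n - 1L) / 2L, sd = scanSD)), n)
      } else array(1, dim(s))
      if (stateSD > 0) {     # common segregation-state factor of this scan
        stateFac <- exp(stats::rnorm(1L, sd = stateSD))
        scanPert[same & off] <- scanPert[same & off] * stateFac
      }
      s[off] <- pmin(pmax(s[off] * pert[off] * scanPert[off], -0.95), 0.95)
      rep <- .psdClip(s)
      if (rep$clipped) nClipped <- nClipped + 1L
      u <- chol(rep$mat + diag(1e-8, n))
      set.seed(deriveSeed(seed, 1000L + si * 10L + ci))
      sv <- if (is.null(truth$signalVar)) 1 else truth$signalVar
      y <- sqrt(sv) * (.smoothGP(nTimepoints, n) %*% u) +
        truth$noiseSD * matrix(stats::rnorm(nTimepoints * n), ncol = n)
      k <- k + 1L
      panels[[k]] <- new("TimeSeriesPanel", data = unname(y),
                         subject = subjectIds[si], condition = conds[ci],
                         tr = tr)
      manifest <- rbind(manifest,
                        data.frame(subject = subjectIds[si],
                                   condition = conds[ci], index = k,
                                   stringsAsFactors = FALSE))
    }
  }
  if (nClipped > 0L)
    warning(nClipped, " coupling matrices were not positive semi-definite ",
            "after planted effects; repaired by eigenvalue clipping")
  gt <- unclass(truth)
  gt$effects <- lapply(truth$effects, unclass)
  gt$negativePairs <- negPairs
  gt$masterSeed <- as.integer(seed)
  new("StudyDataset", atlas = atlas, panels = panels, manifest = manifest,
      groundTruth = gt)
}
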