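## orthonormal within-subject contrast basis (k-1 columns orthogonal to 1)
.orthoContrasts <- function(k) {
  ch <- stats::contr.helmert(k)
  sweep(ch, 2L, sqrt(colSums(ch^2)), "/")
}

#' Sphericity diagnostics of a within-subject effect
#'
#' Given the covariance matrix of orthonormalized contrast scores (one score
#' vector per subject), computes Mauchly's W with its chi-square
#' approximation, the Greenhouse-Geisser epsilon
#' `(sum lambda)^2 / ((k-1) sum lambda^2)` over the eigenvalues, and the
#' Huynh-Feldt epsilon
#' `min(1, (n (k-1) e_GG - 2) / ((k-1) (n - 1 - (k-1) e_GG)))`.
#' With k = 2 sphericity holds trivially (epsilons 1, test skipped); when
#' the covariance is singular (too few subjects for the contrast dimension)
#' the Mauchly test is undefined and reported as NA.
#'
#' @param contrastCov (k-1) x (k-1) covariance of orthonormal contrast
#'   scores.
#' @param n number of subjects.
#' @return list with `W`, `chi2`, `df`, `p`, `ggEpsilon`, `hfEpsilon`.
#' @export
sphericityEpsilons <- function(contrastCov, n) {
  p <- nrow(contrastCov)
  if (p < 2L)
    return(list(W = NA_real_, chi2 = NA_real_, df = NA_real_, p = NA_real_,
                ggEpsilon = 1, hfEpsilon = 1))
  ev <- eigen(contrastCov, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (sum(ev) == 0)     # zero contrast variance: sphericity is moot
    return(list(W = NA_real_, chi2 = NA_real_, df = NA_real_, p = NA_real_,
                ggEpsilon = 1, hfEpsilon = 1))
  gg <- sum(ev)^2 / (p * sum(ev^2))
  hf <- min(1, (n * p * gg - 2) / (p * (n - 1 - p * gg)))
  hf <- max(hf, gg)
  if (min(ev) <= 1e-12 * max(ev) || n - 1L < p) {
    ## singular covariance: Mauchly undefined
    return(list(W = NA_real_, chi2 = NA_real_, df = NA_real_, p = NA_real_,
                ggEpsilon = gg, hfEpsilon = hf))
  }
  W <- prod(ev) / (mean(ev))^p
  f <- 1 - (2 * p^2 + p + 2) / (6 * p * (n - 1))
  chi2 <- -(n - 1) * f * log(W)
  df <- p * (p + 1) / 2 - 1
  list(W = W, chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       ggEpsilon = gg, hfEpsilon = hf)
}

#' Partial omega-squared effect size
#'
#' `w2p = df (F - 1) / (df (F - 1) + N)`, clipped at 0; a low-bias estimate
#' of the population variance accounted for by an ANOVA effect, robust to
#' small samples.
#'
#' @param F F statistic.
#' @param dfEffect effect degrees of freedom.
#' @param nObservations total number of observations in the analyzed table.
#' @return scalar effect size in [0, 1).
#' @export
partialOmegaSquared <- function(F, dfEffect, nObservations) {
  if (!is.finite(F)) return(1)
  max(0, dfEffect * (F - 1) / (dfEffect * (F - 1) + nObservations))
}

#' Sidak-adjusted pairwise comparisons
#'
#' Paired t-tests on subject-level marginal means for every level pair;
#' adjusted p = 1 - (1 - p)^m over the m comparisons.
#'
#' @param scores n x k matrix of subject-by-level marginal means.
#' @param levels level labels (defaults to column names).
#' @return data.frame with `levelA`, `levelB`, `meanDiff`, `t`, `p`,
#'   `pSidak`.
#' @export
sidakPairwise <- function(scores, levels = colnames(scores)) {
  k <- ncol(scores)
  if (is.null(levels)) levels <- paste0("L", seq_len(k))
  pairs <- utils::combn(k, 2L)
  m <- ncol(pairs)
  out <- data.frame(levelA = levels[pairs[1L, ]], levelB = levels[pairs[2L, ]],
                    meanDiff = NA_real_, t = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (c in seq_len(m)) {
    d <- scores[, pairs[1L, c]] - scores[, pairs[2L, c]]
    out$meanDiff[c] <- mean(d)
    if (stats::sd(d) == 0) {       # degenerate: no within-pair variability
      out$t[c] <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
      out$p[c] <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- stats::t.test(d)
      out$t[c] <- unname(tt$statistic)
      out$p[c] <- tt$p.value
    }
  }
  out$pSidak <- 1 - (1 - out$p)^m
  out
}

## cell-mean helper: value averaged over the levels of the dropped factors
.marginalScores <- function(data, dv, subject, factor) {
  agg <- stats::aggregate(data[[dv]],
                          list(s = data[[subject]], f = data[[factor]]), mean)
  levs <- if (is.factor(data[[factor]])) levels(data[[factor]]) else
    unique(agg$f)
  subs <- unique(agg$s)
  m <- matrix(NA_real_, length(subs), length(levs),
              dimnames = list(subs, as.character(levs)))
  m[cbind(match(agg$s, subs), match(agg$f, levs))] <- agg$x
  m
}

#' Repeated-measures ANOVA (one or two within-subject factors)
#'
#' Classical within-subject sums-of-squares decomposition on a complete
#' balanced table: each effect is tested against its effect-by-subject
#' interaction (F_A = MS_A / MS_AxS, and analogously for the second factor
#' and the interaction). Mauchly's test is run per effect; when sphericity
#' is violated (or untestable), degrees of freedom are multiplied by the
#' Huynh-Feldt epsilon for moderate violations (GG epsilon >= 0.75) and by
#' the Greenhouse-Geisser epsilon otherwise. Partial omega-squared is
#' reported per effect, and Sidak-adjusted pairwise contrasts on the first
#' factor's marginal means.
#'
#' @param data long data.frame with one row per observation.
#' @param dv name of the value column.
#' @param subject name of the subject column.
#' @param within character vector of one or two within-factor column names.
#' @param epsilonCutoff GG-epsilon cutoff separating HF from GG correction
#'   (default 0.75).
#' @return list of class `AnovaResult`: `effects` data.frame (effect, df1,
#'   df2, F, p, epsilonType, epsilon, mauchlyW, mauchlyP, omegaSq; df are
#'   epsilon-corrected where applied), `pairwise` data.frame for the first
#'   factor, `nSubjects`.
#' @export
rmAnova <- function(data, dv = "value", subject = "subject",
                    within = c("condition", "threshold"),
                    epsilonCutoff = 0.75) {
  .assert(length(within) %in% 1:2, "one or two within factors supported")
  for (col in c(dv, subject, within))
    .assert(col %in% names(data), "missing column: ", col)
  f1 <- factor(data[[within[1L]]],
               levels = if (is.factor(data[[within[1L]]]))
                 levels(data[[within[1L]]]) else unique(data[[within[1L]]]))
  subj <- factor(data[[subject]])
  y <- data[[dv]]
  n <- nlevels(subj)
  a <- nlevels(f1)
  twoWay <- length(within) == 2L
  if (twoWay) {
    f2 <- factor(data[[within[2L]]],
                 levels = if (is.factor(data[[within[2L]]]))
                   levels(data[[within[2L]]]) else unique(data[[within[2L]]]))
    b <- nlevels(f2)
    cnt <- table(subj, f1, f2)
  } else {
    b <- 1L
    cnt <- table(subj, f1)
  }
  .assert(all(cnt == 1L), "complete balanced table required (one value per cell)")

  gm <- mean(y)
  mA <- tapply(y, f1, mean)
  mS <- tapply(y, subj, mean)
  ssA <- n * b * sum((mA - gm)^2)
  mAS <- tapply(y, list(subj, f1), mean)
  ssAS <- b * sum((mAS - outer(mS, rep(1, a)) -
                     outer(rep(1, n), mA) + gm)^2)

  effects <- list()
  addEffect <- function(name, ss, dfe, ssErr, dfErr, scoreMat, contrastDim) {
    msE <- ss / dfe
    msR <- ssErr / dfErr
    F <- if (msR > 0) msE / msR else if (msE > 0) Inf else 0
    ## sphericity on the orthonormalized contrast scores
    sph <- if (contrastDim >= 2L) {
      cc <- .orthoContrasts(contrastDim + 1L)
      if (!is.null(scoreMat)) {
        sc <- scoreMat %*% cc
        sphericityEpsilons(stats::cov(sc), n)
      } else NULL
    } else NULL
    epsType <- "none"
    eps <- 1
    if (!is.null(sph)) {
      violated <- is.na(sph$p) || sph$p < 0.05
      if (violated) {
        if (sph$ggEpsilon >= epsilonCutoff) {
          epsType <- "HF"; eps <- sph$hfEpsilon
        } else {
          epsType <- "GG"; eps <- sph$ggEpsilon
        }
      }
    }
    p <- if (is.finite(F)) stats::pf(F, dfe * eps, dfErr * eps,
                                     lower.tail = FALSE)
         else if (is.infinite(F)) 0 else 1
    data.frame(effect = name, df1 = dfe * eps, df2 = dfErr * eps, F = F,
               p = p, epsilonType = epsType, epsilon = eps,
               mauchlyW = if (is.null(sph)) NA_real_ else sph$W,
               mauchlyP = if (is.null(sph)) NA_real_ else sph$p,
               omegaSq = partialOmegaSquared(F, dfe, length(y)),
               degenerate = !is.finite(F),
               stringsAsFactors = FALSE)
  }

  ## per-subject score matrices for the sphericity machinery
  scoreA <- .marginalScores(data.frame(s = subj, f = f1, v = y), "v", "s", "f")
  res <- addEffect(within[1L], ssA, a - 1L, ssAS, (a - 1L) * (n - 1L),
                   scoreA, a - 1L)
  if (twoWay) {
    mB <- tapply(y, f2, mean)
    ssB <- n * a * sum((mB - gm)^2)
    mBS <- tapply(y, list(subj, f2), mean)
    ssBS <- a * sum((mBS - outer(mS, rep(1, b)) -
                       outer(rep(1, n), mB) + gm)^2)
    mAB <- tapply(y, list(f1, f2), mean)
    ssAB <- n * sum((mAB - outer(mA, rep(1, b)) -
                       outer(rep(1, a), mB) + gm)^2)
    ssTot <- sum((y - gm)^2)
    ssS <- a * b * sum((mS - gm)^2)
    ssABS <- ssTot - ssA - ssB - ssAB - ssS - ssAS - ssBS
    scoreB <- .marginalScores(data.frame(s = subj, f = f2, v = y), "v", "s", "f")
    ## interaction contrast scores: per-subject cell matrix times kron basis
    cells <- tapply(y, list(subj, f1, f2), mean)
    cellMat <- matrix(cells, nrow = n)            # n x (a*b), A varying fastest
    kronC <- kronecker(.orthoContrasts(b), .orthoContrasts(a))
    scAB <- cellMat %*% kronC
    res <- rbind(res,
                 addEffect(within[2L], ssB, b - 1L, ssBS,
                           (b - 1L) * (n - 1L), scoreB, b - 1L),
                 {
                   dfAB <- (a - 1L) * (b - 1L)
                   msE <- ssAB / dfAB
                   msR <- ssABS / (dfAB * (n - 1L))
                   F <- if (msR > 0) msE / msR else if (msE > 0) Inf else 0
                   sph <- sphericityEpsilons(stats::cov(scAB), n)
                   epsType <- "none"; eps <- 1
                   if (is.na(sph$p) || sph$p < 0.05) {
                     if (sph$ggEpsilon >= epsilonCutoff) {
                       epsType <- "HF"; eps <- sph$hfEpsilon
                     } else { epsType <- "GG"; eps <- sph$ggEpsilon }
                   }
                   p <- if (is.finite(F))
                     stats::pf(F, dfAB * eps, dfAB * (n - 1L) * eps,
                               lower.tail = FALSE)
                   else if (is.infinite(F)) 0 else 1
                   data.frame(effect = paste(within, collapse = ":"),
                              df1 = dfAB * eps, df2 = dfAB * (n - 1L) * eps,
                              F = F, p = p, epsilonType = epsType,
                              epsilon = eps, mauchlyW = sph$W,
                              mauchlyP = sph$p,
                              omegaSq = partialOmegaSquared(F, dfAB, length(y)),
                              degenerate = !is.finite(F),
                              stringsAsFactors = FALSE)
                 })
  }
  pairwise <- sidakPairwise(scoreA)
  structure(list(effects = res, pairwise = pairwise, nSubjects = n),
            class = "AnovaResult")
}

#' @export
print.AnovaResult <- function(x, ...) {
  cat("Repeated-measures ANOVA (", x$nSubjects, "subjects )\n")
  print(transform(x$effects, F = signif(F, 5), p = signif(p, 4),
                  omegaSq = signif(omegaSq, 3)), row.names = FALSE)
  invisible(x)
}

#' Per-threshold one-way follow-up ANOVAs
#'
#' One 1-way repeated-measures ANOVA (condition factor) per density
#' threshold, with the same sphericity machinery and Sidak pairwise
#' contrasts.
#'
#' @param data long data.frame with subject, condition, threshold, value
#'   columns.
#' @inheritParams rmAnova
#' @param threshold name of the threshold column.
#' @return named list of `AnovaResult`, one per threshold level.
#' @export
perThresholdAnovas <- function(data, dv = "value", subject = "subject",
                               condition = "condition",
                               threshold = "threshold",
                               epsilonCutoff = 0.75) {
  levs <- unique(data[[threshold]])
  out <- lapply(levs, function(th) {
    rmAnova(data[data[[threshold]] == th, , drop = FALSE], dv = dv,
            subject = subject, within = condition,
            epsilonCutoff = epsilonCutoff)
  })
  names(out) <- as.character(levs)
  out
}

#' Node-wise FDR control (Benjamini-Yekutieli)
#'
#' Step-up procedure valid under arbitrary dependence, with constant
#' c(m) = sum_{i=1..m} 1/i.
#'
#' @param p vector of per-node p-values.
#' @param q FDR level (default 0.05).
#' @return list with logical `rejected`, numeric `adjustedP` and `q`.
#' @export
nodewiseFdr <- function(p, q = 0.05) {
  adj <- stats::p.adjust(p, method = "BY")
  list(rejected = adj <= q, adjustedP = adj, q = q)
}

#' Repeated-measures ANCOVA of correlation strength on distance
#'
#' Operates on per-subject per-condition binned mean correlations (from
#' [binByDistance()]), with the bin-centre distance as a continuous
#' covariate: condition effect (tested within subjects), distance effect and
#' condition-by-distance interaction. Empty bins are dropped with a warning.
#' Follow-up: one 1-way repeated-measures ANOVA per retained bin with Sidak
#' pairwise contrasts.
#'
#' @param binTable long data.frame with columns subject, condition, bin,
#'   center, meanR (one row per subject x condition x bin).
#' @return list with `ancova` (data.frame of effects), `perBin` (named list
#'   of `AnovaResult`), and `binsUsed`.
#' @export
rmAncovaDistance <- function(binTable) {
  need <- c("subject", "condition", "bin", "center", "meanR")
  .assert(all(need %in% names(binTable)), "binTable lacks required columns")
  empty <- unique(binTable$bin[is.na(binTable$meanR)])
  if (length(empty)) {
    warning("dropping empty distance bin(s): ", paste(empty, collapse = ", "))
    binTable <- binTable[!binTable$bin %in% empty, , drop = FALSE]
  }
  binTable$subject <- factor(binTable$subject)
  binTable$condition <- factor(binTable$condition,
                               levels = intersect(conditionLevels(),
                                                  unique(binTable$condition)))
  fit <- stats::aov(meanR ~ condition * center +
                      Error(subject / condition), data = binTable)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1L]]
    rn <- trimws(rownames(tab))
    k <- match(term, rn)
    if (is.na(k)) return(NULL)
    data.frame(effect = term, df1 = tab[k, "Df"],
               df2 = tab[nrow(tab), "Df"], F = tab[k, "F value"],
               p = tab[k, "Pr(>F)"], stringsAsFactors = FALSE)
  }
  eff <- rbind(pull("Error: subject:condition", "condition"),
               pull("Error: Within", "center"),
               pull("Error: Within", "condition:center"))
  perBin <- perThresholdAnovas(
    data.frame(subject = binTable$subject, condition = binTable$condition,
               threshold = binTable$bin, value = binTable$meanR),
    dv = "value", subject = "subject", condition = "condition",
    threshold = "threshold")
  list(ancova = eff, perBin = perBin, binsUsed = sort(unique(binTable$bin)))
}
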