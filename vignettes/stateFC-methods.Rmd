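---
title: "Models and methods behind stateFC"
author: "stateFC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stateFC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

stateFC analyses state-dependent reconfiguration of functional brain
networks from region-of-interest (ROI) time series, in the setting of a
four-condition repeated-measures design: wakefulness (W), sedation (S),
loss of consciousness (LOC) and recovery (R), with every subject scanned in
all four conditions. The pipeline runs from temporal cleaning of ROI time
series through Pearson connectivity, proportional density thresholding,
weighted graph metrics normalized against rewired null networks, linear SVM
classification of connectomes, to a sphericity-corrected repeated-measures
statistical framework. Because real data of this kind are rarely shareable,
the package includes a fully specified synthetic-study generator with
planted ground truth; every downstream stage is validated against that
ground truth and against independent oracles.

# Connectivity construction

Cleaning operates purely in the temporal domain, in the order trim →
polynomial detrend → nuisance regression → band-pass:

* the first `trim` volumes (default 4) are discarded;
* linear and quadratic trends are removed per ROI by least squares;
* optional nuisance regressors (motion parameters, white-matter and CSF
  signals) are partialled out by linear regression; the polynomial basis is
  kept in the design so trends inside nuisance signals cannot re-enter.
  The global signal is deliberately not removed, as global-signal
  regression is known to manufacture artificial anticorrelations;
* a zero-phase (forward–backward) Butterworth band-pass, default
  0.01–0.1 Hz, the standard resting-state band at TR = 2.46 s. Both edges
  and the trim count are exposed in the configuration.

Connectivity is the Pearson correlation between all ROI pairs; matrices are
symmetric with unit diagonal, and a constant ROI column is an error naming
the offending region rather than a silent NaN.

Descriptive analyses summarize the upper triangle of condition-mean
matrices (median, negative fraction, tail fractions, histogram), compare
correlation distributions between conditions with the two-sample
Kolmogorov–Smirnov test, and resolve correlation strength into fifteen 9-mm
Euclidean-distance bins (half-open bins, the last bin absorbing the
remainder) for the distance ANCOVA.

# Graphs and weighted metrics

Proportional thresholding ranks the upper triangle by signed correlation
and keeps the strongest `round(density * M)` edges (`M = N(N-1)/2`,
rounding half away from zero) with their original weights; all other
entries, including every negative correlation, become zero. Ties at the
cutoff break by row-major index order, which makes retained edge sets
nested across densities. Negative correlations are excluded from graphs
only; classification and the descriptive analyses use the unthresholded
matrices.

Stronger correlations are functionally closer, so each retained edge has
length 1/w (the standard convention of weighted connectivity toolboxes; a
log-based mapping would be the main alternative and the mapping is isolated
in one place). On that length structure the package computes:

* characteristic path length `L`: mean shortest path over ordered reachable
  pairs, with the unreachable fraction reported;
* global efficiency `E`: mean inverse shortest path, with 1/Inf = 0;
* Onnela weighted clustering `C_i`: geometric-mean triangle intensity with
  weights rescaled by the network maximum; the degree `k_i` in the
  denominator is the binary neighbour count — with strength in the
  denominator the coefficient would not be bounded by 1;
* weighted local efficiency: the same triple structure with the inner term
  replaced by shortest paths restricted to the neighbourhood of the node;
* nodal strength `s_i = sum_j w_ij`;
* Newman weighted modularity `Q`, maximized by Louvain (igraph) on a random
  vertex permutation, refined by a deterministic fine-tuning pass (single
  node moves while `Q` strictly increases) and a probabilistic tuning pass
  that reassigns a fraction `pTune = 0.45` of nodes and re-fine-tunes,
  keeping the better partition. Because the optimization is stochastic and
  degenerate, the mean `Q` and mean module count over 50 restarts (10 for
  null networks) are the reported statistics, all reproducible from one
  seed.

Raw metric values are not interpretable in absolute terms, so each graph is
compared with degree-preserving rewired null networks: repeated double edge
swaps with weights travelling on their original edges, preserving the exact
degree sequence and weight multiset (10 successful swaps per edge by
default; rejected proposals — self-loops or multi-edges — count against a
10x attempt budget and a shortfall is reported). Normalized metrics are
`nX = X / mean(X over 100 nulls)` and small-worldness is
`sigma = nC / nL`. Null metrics use exactly the same engines, settings and
modularity seed as the real graph, so a 0-swap ensemble gives ratios of
exactly 1 — a useful self-test.

The analysis density range follows two constraints: the lowest density must
keep the mean degree at or above `2 ln(N)` (network estimability; with
proportional thresholding the mean degree is the closed form
`2 round(dM)/N`, so this bound needs no simulation), and the highest
density must keep mean small-worldness at or above 1 in every condition.
On the default study this yields 11–31%, sampled in 5% steps.

# Classification

Classification uses the unthresholded correlation matrices, vectorized as
the row-major upper triangle. The classifier is a linear soft-margin SVM
(e1071, cost 1 — the single trade-off parameter of the linear kernel), with
leave-one-subject-out cross-validation: both of a subject's samples are
held out per fold, so the paired design never leaks a subject between
training and test. Accuracy is the percent of correct held-out predictions;
sensitivity and specificity are the per-class percents.

Because only inner products matter to a linear kernel, the feature matrix
is first reduced by a thin SVD (`Z = U D`, with the Gram matrix unchanged);
the SVM sees an n-dimensional problem and the hyperplane maps back exactly
as `w = V w_z`. This makes the permutation test affordable at full feature
dimension: each permutation flips each subject's pair of labels with
probability 1/2 (the exchangeable operations under the paired null), reruns
the complete LOOCV, and the p-value is the +1-smoothed tail proportion
`(1 + #{perm >= observed}) / (nPerm + 1)`, with a Bonferroni-adjusted
version for the family of comparisons.

Importance maps split the hyperplane weight matrix into the edges
contributing to each class. An edge goes to class A when
`w (meanA + meanB) >= 0`; with both class means positive — the common case —
this is a plain split by the sign of `w`, and an edge driven by
anticorrelation is credited to the class in which it is negative, which is
the phenomenon the maps are meant to display. Each sparse matrix (absolute
weights) is multiplied elementwise by the mean unthresholded matrix over
that class's correctly classified samples, so the entry's sign is the sign
of the contributing correlation. The top 1% of edges by absolute weight are
assigned to fifteen anatomical kinds ({cortex, thalamus, basal ganglia,
cerebellum, brainstem} unordered pairs, the four cortical lobes collapsing
to "cortex") crossed with correlation sign, and two kind distributions are
compared with a plain Pearson chi-square on the 2 x k table after dropping
empty kinds.

# Repeated-measures statistics

The ANOVA engine is a classical within-subject sums-of-squares
decomposition (one or two within factors), each effect tested against its
effect-by-subject interaction. Sphericity is assessed per effect with
Mauchly's test on orthonormalized contrast scores; on violation (or when
the contrast covariance is singular, as for the condition-by-threshold
interaction with 12 subjects, where the test is undefined and correction is
applied defensively) degrees of freedom are scaled by the Huynh–Feldt
epsilon for moderate violations (Greenhouse–Geisser epsilon at or above
0.75, the conventional cutoff) and by the Greenhouse–Geisser epsilon
otherwise. Partial omega-squared,
`df(F-1) / (df(F-1) + N)` clipped at zero, is reported as a
small-sample-resistant effect size. Pairwise condition contrasts are paired
t-tests on marginal means with the Sidak adjustment `1 - (1-p)^m`. The
two-way model (condition x threshold) is followed by one 1-way
repeated-measures ANOVA per threshold. Node-wise tests control FDR with
Benjamini–Yekutieli, valid under arbitrary dependence, at q = 0.05
(configurable).

The distance ANCOVA operates on per-subject, per-condition binned mean
correlations with the bin-centre distance as a continuous covariate
(condition, distance and their interaction), fitted with `aov` error
strata. Binned subject-level means are the observational unit deliberately:
edge-level observations would pseudo-replicate 18,721 correlated values
into a subject-level design and invalidate the degrees of freedom; the
follow-up tests are per-bin 1-way repeated-measures ANOVAs, matching the
binned reading.

# The synthetic study generator

The generator emulates a 12-subject, four-condition study on a 194-ROI
atlas (196 timepoints at TR 2.46 s). ROIs are apportioned to eight
anatomical subdivisions (largest-remainder rounding) and placed in
subdivision-specific boxes of a brain-sized volume.

Baseline signal couplings come from a latent-factor model in which every
component is positive semi-definite by construction, so no spectral repair
is needed at baseline: a global factor (`baseCoupling` 0.25), one factor
per module (`moduleCoupling` 0.35, 6 modules, assigned at random so module
structure and distance carry separately identifiable signal), a spatial
field with exponential kernel `exp(-d/lambda)` (`distCoupling` 0.5,
`lambda` 60 mm), and five unstructured factors with random loadings
(`factorCoupling` 0.4) providing pair-level coupling heterogeneity; the sum
is normalized to a correlation matrix. Time series mix smooth Gaussian
processes (Gaussian kernel, SD 1.2 TR) through the Cholesky factor, scaled
to signal variance 3, plus unit-variance white noise, so observed
correlations are the signal correlations shrunk by 3/4. These constants
were calibrated once against the descriptive statistics the study design
implies — wakefulness median r near 0.2, about 80–90% of correlations in
[0, 0.4], a few percent negative — and then frozen.

Condition effects perturb the coupling matrix:

* **S** keeps the global level of wakefulness and adds thalamo-cortical
  (+0.25) and mild cortico-cortical (+0.03) hyperconnectivity; a small
  within-module factor (1.03) offsets the segregation dilution those extra
  inter-block edges would otherwise cause, consistent with sedation and
  wakefulness being indistinguishable on normalized clustering.
* **LOC** halves all couplings (global gain 0.5), boosts within-module
  coupling by 1.75 (raising clustering and path length together), and
  plants negative cortico-cortical couplings: a randomly ordered set of
  cortical nodes has its global-factor loading negated (amplified 2.5x) and
  the set grows until the expected negative-edge fraction reaches the 14%
  target. Independent random sign flips cannot do this — isolated negative
  entries of magnitude ~0.25 inside an otherwise positive correlation
  structure have no positive semi-definite completion, and any spectral
  repair erases them — whereas an anti-phase node set is exactly how
  anticorrelated networks appear in real data: structured, long-range,
  strongest between distant cortical regions.
* **R** returns to the wakefulness level and applies a triangle-closure
  boost (1.3): couplings are strengthened in proportion to their
  normalized two-path support. This raises weighted clustering with little
  effect on shortest paths, which is precisely the recovery phenotype —
  elevated normalized clustering with normalized path length back at
  baseline — and is deliberately a different mechanism from the
  within-module boost, whose clustering gains always drag path length
  along.

Between-subject variability is a multiplicative log-normal perturbation of
couplings (SD 0.1) shared across a subject's four scans, keeping the paired
design honest. Within-subject (scan-level) variability has two parts: an
edge-wise log-normal jitter (SD 0.06) and a common log-normal fluctuation
of the within-module coupling level (SD 0.07). The second part matters: a
purely edge-wise jitter averages out of any global graph metric, leaving
repeated-measures error terms unrealistically tiny and every minuscule
condition difference "significant". A common segregation-state fluctuation
is what gives graph-level contrasts a realistic within-subject error.
Where condition effects or subject perturbations break positive
semi-definiteness, the coupling matrix is repaired by eigenvalue clipping
with a warning; at the default settings the repairs are small.

What the generator does not emulate: haemodynamics, scanner artefacts and
motion, spatial smoothness of noise, non-Gaussian BOLD marginals, and any
genuine neurophysiology of anaesthesia. Passing the recovery suite
therefore shows that the pipeline detects effects of the planted kinds at
realistic noise levels — not that the biological claims would replicate.

# Numerical choices and degenerate inputs

Rounding of edge counts is half-away-from-zero; R's own `round` is
banker's rounding and would make edge counts depend on parity. Thresholding
refuses densities that demand more edges than there are positive
correlations, reporting the maximum achievable density. Path-length
routines represent disconnection (`+Inf`, fraction reported) rather than
failing; `charPathLength` errors only when every pair is unreachable.
Modularity on an edgeless graph is an error. Sphericity on k = 2 levels is
trivially 1; a zero or singular contrast covariance yields an undefined
Mauchly test (reported as NA) with epsilons handled conservatively.
Degenerate ANOVA cells (zero residual variance) are flagged rather than
reported as spuriously huge F values. All simulation, null-ensemble,
modularity and permutation randomness derives from explicit integer seeds;
a fixed master seed makes the entire pipeline byte-identical across runs.

# Problem sizes used by the validation suite

The test suite exercises metric oracles on hundreds of random 8–12 node
graphs, closed-form modularity on planted cliques, rewiring invariants,
small-world sanity on ring lattices with 100-null normalization, classifier
calibration on 50 no-effect replicates of the full-size study (194 ROIs,
12 subjects) with permutation tests, ground-truth recovery of the planted
anatomy, and the full pipeline on five replicates of the default study at
five densities with 20-null normalization — sizes chosen so the whole suite
completes in well under half an hour on a single core while still operating
at the study's native dimensionality where it matters.

# Known limitations

* The atlas-to-subdivision assignment of any real parcellation must be
  supplied by the user; the package treats the atlas as input.
* The null model randomizes topology with weights attached to edges;
  reshuffling weights over a fixed topology is a different null with
  different nC/nL behaviour (the rewiring intensity is configurable, the
  alternative null is not built in).
* Permutation tests explore the 2^12 paired relabelings by sampling, so
  the smallest attainable p is bounded by the permutation count.
* The ANCOVA's binned-means design trades edge-level resolution for valid
  subject-level inference; an edge-level variant would need an explicit
  dependence model.
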