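---
title: "Dynamic functional connectivity state analysis: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectivity state analysis: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
model behind each stage, the tunable parameters and why their defaults are
what they are, what the synthetic cohort generator does and does not emulate,
and the numerical and design choices made where the method leaves room.

## The model

The pipeline treats a subject's regional fMRI signal as a `T x R` matrix
(`T` timepoints at repetition time TR, `R` regions of interest) and asks
three questions in sequence: how does inter-regional coupling change over the
scan, does it revisit a small set of recurring whole-brain patterns
("states"), and do the statistics of those visits differ between groups and
track clinical severity?

### Windowed connectivity

Connectivity is estimated inside a tapered sliding window. The taper is a
unit rectangle of `length_tr` samples convolved with a zero-mean Gaussian of
width `sigma_tr`, truncated to the rectangle's support and normalised to sum
one. It is symmetric, strictly positive and peaked at the window centre, so
timepoints near the window edges contribute less and window-to-window
estimates change smoothly as the window slides. Defaults `length_tr = 22`,
`sigma_tr = 3`, `step_tr = 1` follow the common tapered-window setup for
TR = 2 s data, where a ~44 s window balances estimator quality against
temporal resolution; at `T = 230` this yields 209 windows.

Within a window the taper-weighted covariance (weighted mean removed) is
computed. With `l1_lambda = 0` it is rescaled to weighted Pearson
correlations. With `l1_lambda > 0` — the default, 0.1 — the covariance is
first rescaled to a correlation matrix and an L1-penalised precision matrix
is estimated from it by a block coordinate-descent graphical lasso
(implemented in compiled code; the diagonal is penalised, `W_ii = S_ii +
lambda`); off-diagonal precision entries are converted to partial
correlations `-P_ij / sqrt(P_ii P_jj)`. The penalty regularises the
rank-deficient within-window problem (22 weighted samples, often many more
regions) and suppresses indirect coupling. `lambda` is held constant across
subjects and windows: per-window cross-validation would multiply the cost of
the pipeline's dominant stage by orders of magnitude for little gain, and a
shared penalty keeps windows comparable, which is what the clustering
consumes. The value is exposed in `window_params()`.

Connectivity values are Fisher-z transformed by default (`use_fisher_z`),
with magnitudes clipped to `1 - 1e-7` first so perfectly correlated pairs
stay finite. The transform is monotone, so it never reorders pair values; its
purpose is variance stabilisation, which benefits the Euclidean geometry
k-means operates in. Whether the original analyses z-transformed before
clustering is not stated in the tradition this follows; the flag makes either
choice available and the default is on.

Pair ordering is fixed and documented: the row-major upper triangle (1,2),
(1,3), ..., (1,R), (2,3), ..., so centroids and per-subject matrices are
comparable across runs and implementations.

### State identification

Clustering all `subjects x windows` vectors directly is wasteful because
consecutive windows are nearly identical. Each subject therefore contributes
only *exemplar* windows — strict interior local maxima of the across-pair
connectivity variance series (population variance, dividing by the number of
pairs). If a subject's series has no strict interior maximum (monotone or
plateaued), the single global argmax is used, taking the first of tied
positions. Endpoints are never exemplars: a boundary maximum cannot be
distinguished from truncation.

The pooled exemplars are clustered by k-means under the correlation distance
`1 - cor(x, y)`, which is sensitive to the *pattern* of connectivity and
blind to its overall magnitude. Rows are standardised to zero mean and unit
norm, where the correlation distance is exactly half the squared Euclidean
distance, so Lloyd iterations remain valid; centroids are re-standardised
after each update. Fifty random restarts (`n_init`) guard against bad
initialisations at the exemplar stage. An emptied cluster is re-seeded from
the point farthest from its centroid, each emptied cluster from a distinct
point. The best run by total within-cluster distance wins; everything is
deterministic given the seed.

The number of states `k` is chosen by the elbow criterion on the ratio of
mean within-cluster distance to mean between-centroid distance, evaluated
over `k_range` (default 2–8). The pick is the interior candidate maximising
the discrete second difference of the ratio curve — the sharpest bend — with
ties toward smaller `k`. Two boundary rules complete the definition: if the
curve's minimum sits at the smallest candidate there is no bend to its right
and that candidate is returned directly (a two-cluster dataset scanned from
`k = 2` must be able to select 2, which an interior-only rule cannot do), and
a monotonically increasing curve returns the smallest candidate with a
warning, since no elbow exists.

Stage two runs a single k-means pass over *all* windows of all subjects,
initialised at the exemplar centroids — the exemplars decide what the states
are; the full pass decides when each subject is in each of them. States are
then relabelled in descending order of total occupancy, so "state 1" is
always the most frequent. This canonicalisation makes reports reproducible
across runs; it also means fitted labels need not coincide with any
generator's state indices, which is why `match_states()` exists for
synthetic-data work.

### State metrics and statistics

Per subject, the package computes reoccurrence times (windows per state,
summing to `W`), undirected transition frequencies (a change between
successive windows increments the counter of the unordered state pair; moves
`i -> j` and `j -> i` are the same event, self-transitions are not events),
and the number of distinct states visited. A directed variant exists behind a
flag but the standard pipeline never uses it. Runs of equal states count once
per boundary crossing, with no run-length weighting.

Group comparisons use pooled-variance (Student) t tests — the two-sample
default when no unequal-variance concern is raised; Welch is available by
argument. Bonferroni families follow the natural structure: `k` reoccurrence
tests, `k(k-1)/2` transition tests, and for clinical correlations the full
`(k + k(k-1)/2) x n_clinical` family — 20 tests at `k = 4` with two clinical
variables, giving the adjusted threshold 0.05/20 = 0.0025. The Mann-Whitney
U is computed from midranks (ties count one half) with a tie-corrected
normal-approximation p; chi-square tests are Pearson's without continuity
correction. Metrics that are constant across subjects (a never-used
transition pair — zero counts are common in short scans) yield `NA`
correlations rather than aborting the table. Subjects missing a clinical
score are excluded from that correlation only, never from clustering or
metrics: windows are pooled across everyone.

### Classification

Features per subject are the distinct-state count, the `k` reoccurrence
times and the `k(k-1)/2` transition counts — 11 features at `k = 4`. The
classifier is a Lagrangian SVM: the L2-regularised linear SVM with penalised
bias, trained by the fixed-point iteration
`u <- Q^{-1}(e + ((Qu - e) - alpha*u)_+)` with `Q = I/nu + H H'`,
`H = D[A, -e]` and `alpha = 1.9/nu` (convergence requires `alpha < 2/nu`;
1.9 is the customary margin). `Q^{-1}` is applied through the
Sherman-Morrison-Woodbury identity, so each iteration inverts only a
`(d+1) x (d+1)` matrix. The iteration is linearly convergent and its iterate
change is monotone after the first step, which the tests assert.

Evaluation is nested stratified 10-fold cross-validation. Within each outer
training set, inner folds choose how many top-ranked features to keep
(ranking by absolute pooled t statistic on inner-training rows only; ties in
inner accuracy break toward fewer features), the model is refit on the outer
training set, and outer-test predictions are pooled into a single confusion
matrix for accuracy, sensitivity (patients positive), specificity, and
rank-based AUC (ties count one half). Standardisation, ranking and feature
selection never see held-out rows. The permutation test reruns the full
nested procedure on label permutations and reports
`p = (1 + #{null >= observed}) / (n_permutations + 1)`; 1000 permutations by
default, so p < 0.001 is reachable.

One caution the implementation surfaced: with unbalanced groups (36 vs 23),
"chance" for accuracy is not 50% — a classifier that merely learns the
majority-class prior scores up to 61% on permuted labels. The permutation
null, which is computed by the same procedure on the same class ratio,
accounts for this automatically; fixed binomial bands around 50% do not, and
are only meaningful for balanced cohorts.

## The synthetic cohort generator

No patient cohort ships with the package, so validation uses a generator
whose structure mirrors the assumptions the analysis makes: each subject
carries a latent state sequence from a per-group Markov chain, each timepoint
is drawn from the current state's zero-mean Gaussian, and clinical scores are
linear in realised state occupancy plus noise.

- **States.** `make_state_covariances()` builds `k` correlation-scale SPD
  matrices over `2k` contiguous region blocks; each state activates a
  distinct disjoint pair of blocks (within-block r = 0.6, between active
  blocks r = 0.15 by default), so the vectorised state patterns are nearly
  orthogonal — comfortably inside the separation regime the clustering
  recovery claims require.
- **Dynamics.** Transition matrices take the sticky form
  `P = s*I + (1-s) 1 pi'`, whose stationary distribution is exactly `pi` and
  whose mean dwell in state i is `1/((1-s)(1-pi_i))`. The default
  `stay = 0.98` gives dwells of 50+ TRs, at least twice the window length, so
  windowed estimates can resolve state visits. Chains start at their
  stationary distribution.
- **Group structure.** Default stationary occupancies mirror a
  baseline-dominant control profile, `(0.55, 0.12, 0.20, 0.13)`, against a
  patient profile shifted toward the third, "enriched" state,
  `(0.38, 0.13, 0.30, 0.19)` — the direction and rough magnitude of the
  group differences the analysis is meant to detect.
- **Clinical coupling.** Pseudo-CIPE and pseudo-IELT are
  `intercept + slopes . occupancy + noise`, with a positive slope on the
  baseline state and a negative slope on the enriched state, so worse scores
  accompany more time in the enriched state. Noise standard deviations
  (14 for CIPE, 4.7 for IELT) were calibrated once so the planted
  correlations land around |r| = 0.3–0.45 at n = 59 — the moderate regime
  typical of clinical correlates — and are not revisited. With realised
  occupancy this noisy (dwells are long relative to the scan, so occupancy
  fractions vary widely across subjects), the scores' numeric ranges are
  wider than the real instruments'; the generator models the coupling
  *statistics*, not the instruments' bounded scales.

What the generator does **not** emulate: hemodynamic convolution, 1/f and
physiological noise spectra, head motion, scanner drift, spatial structure
within regions, and any non-Markovian state dynamics. Passing tests therefore
demonstrate that the pipeline recovers the structure it assumes when that
structure is present — they say nothing about whether real resting-state data
contain such structure.

## Problem sizes and numerical choices

Test and validation runs use `R = 60` regions (264 is supported; the
per-window penalised-precision estimate is the dominant cost and scales
roughly cubically in `R`), `T = 230`, and 59 subjects — the default cohort
geometry. The end-to-end recovery check runs the elbow selection and the full
two-stage fit once at `n_init = 10`; the 20-seed sign-recovery suite fixes
`k = 4` and `n_init = 5` and uses plain tapered correlations
(`l1_lambda = 0`), while the sparse path is exercised end-to-end separately —
the sign pattern of occupancy differences does not depend on the penalised
estimator, and this split keeps repeated validation runs proportionate. The
permutation calibration uses 99 permutations at 5x5 folds on a balanced null
cohort, for the chance-level reason given above.

Other numerical decisions: the graphical lasso iterates block coordinate
descent to a relative off-diagonal tolerance of 1e-4 (inner lasso tolerance
1e-7) with warm starts across sweeps; Fisher-z clips at `|r| = 1 - 1e-7`;
k-means ties in nearest-centroid assignment take the first centroid;
zero-variance feature columns standardise to zero with unit scale; a
zero-variance region column in input is an error naming the column (a dead
ROI upstream should fail loudly, not silently). All randomness flows from one
master seed through a fixed documented derivation (`stage_seed()`), so any
stage can be re-run in isolation and whole runs are byte-reproducible.

## Known limitations

- Sliding-window correlation cannot resolve dynamics faster than the window,
  and the choice of `k` inherits the elbow criterion's bluntness; both are
  properties of the method, not the implementation.
- The graphical-lasso penalty is shared across windows; windows with very
  different signal-to-noise would ideally get adaptive penalties.
- Nested CV with 59 subjects has high variance; pooled confusion-matrix
  metrics are reported without fold-level dispersion.
- The generator's Gaussian, Markovian world is a best case for the pipeline;
  conclusions about real data require real data.
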