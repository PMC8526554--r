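---
title: "Dynamic functional-connectivity brain states: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional-connectivity brain states: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis in one paragraph

`dynstates` takes a cohort of resting-state ROI (or independent-component)
time series plus a phenotype table and asks whether time-resolved network
topology carries information about a clinical response variable that
whole-scan ("static") connectivity does not. Functional connectivity (FC)
is estimated in short sliding windows, the windowed matrices are pooled
across subjects and clustered into recurring *brain states*, graph-theory
metrics are computed on proportionally thresholded binary graphs of each
state's median matrix, summarised across thresholds by the area under the
curve (AUC), and finally correlated with the response under covariate
control. The motivating application is percent UPDRS-III improvement under
subthalamic deep brain stimulation in Parkinson's disease, where network
assortativity of a hypoconnected state is the headline marker; the package
itself is agnostic about what the response represents.

## Pipeline stages and their parameters

### Static connectivity

Static FC is the product-moment correlation of every region pair over the
whole scan. Cohort covariates (age, gender, preoperative UPDRS-III ON
score, mean framewise displacement) are removed by *edge-wise
residualisation*: each edge's cross-subject vector is regressed on the
covariate design (with intercept) and replaced by residual + cohort mean.
This is a deliberate, transparent simplification of the multivariate
covariance-modelling toolbox step used in the source workflow: with
covariates used purely for adjustment the two approaches serve the same
end, and the edge-wise version is directly unit-testable against a
normal-equations oracle. Zero-variance covariates (e.g. a single-gender
small cohort) are dropped with a logged note.

Each subject's *overall FC* — the mean of the strictly positive edges of
the subject's own static matrix — is retained as a control covariate for
all graph-metric and edge associations, because proportional thresholding
leaves metric differences exposed to gross connectivity-level differences
between subjects.

The `(p < 0.05)` aside in the source description of edge formation is read
as reporting rather than as an edge-deletion mask; masking would create
subject-specific missing edges whose handling is never described. The
alternative reading is available via `run_config(edge_significance_mask =
TRUE)` but is off by default.

### Windowed connectivity

Windows are `window_length_tr = 22` TRs long (59.4 s at TR = 2.7 s),
advanced by `step_tr = 1`, and weighted by a taper built by convolving a
rectangle of length 22 with a unit-mass Gaussian of `taper_sigma_tr = 3`
TRs (support ±⌈3σ⌉), keeping the central 22 samples and renormalising.
The window count convention is `floor((T − W)/step)`: for a 253-volume
scan this yields exactly 231 windows. The alternative `(T − W)/step + 1`
convention would give 232; the chosen convention (dropping the final,
partially tapered position) is the only one consistent with the
231-window design the pipeline reproduces, and it is asserted in the test
suite.

With 22 samples and 25 regions the window covariance is rank-deficient,
so the window precision matrix is estimated by graphical lasso (L1
penalty on off-diagonal precision entries, block coordinate descent,
compiled). The penalised precision is inverted and standardised, so
windowed FC is reported on the correlation scale like static FC. At
`lambda = 0` the estimate reduces exactly to the tapered correlation; at
very large `lambda` the off-diagonals vanish. The per-subject penalty is
chosen from `lambda_grid = {0.01, 0.03, 0.1, 0.3, 0.5}` by
`lambda_reps = 10` random half-splits of the subject's windows, fitting
on the pooled training covariance and scoring the Gaussian held-out
log-likelihood `log det Θ − tr(S_test Θ)`; the criterion used by the
source toolbox is not stated, and held-out likelihood (that toolbox
lineage's convention) is adopted. The penalty is applied with the
diagonal unpenalised, the convention of the widely used reference
implementations, against one of which the solver is frozen-value tested.

### Brain states

All subjects' windowed matrices are pooled (states must be cohort-common
to be comparable across subjects), embedded as Fisher-z upper-triangle
vectors, and clustered by k-means with squared-Euclidean distance,
`kmeans_reps = 100` random restarts per candidate k (initial centres are
random distinct feature rows; the restart with the lowest within-cluster
dispersion wins), for k in `2..10`. k is selected by maximal mean
silhouette; a spherical-Gaussian BIC,

  BIC = n·d·ln(WSS/(n·d)) + k·(d+1)·ln(n),

is reported per k as validation (the source names BIC without a formula;
this variant is fixed and unit-tested). Silhouette follows the standard
definition with singleton clusters contributing 0; it is computed from
one pre-computed distance matrix reused across k, which bounds the
pooled-window count at roughly 10⁴ on desktop memory.

States are relabelled so that state 1 has the highest centroid mean
connectivity — state 1 is always the hyperconnected state, making output
deterministic across runs and seeds. Per subject and state the
element-wise *median* of the windows assigned to the state forms the
state matrix; states a subject never visits are missing and that subject
is excluded pairwise from the state's downstream tests, with the count
logged. Temporal statistics per subject: fraction of windows per state,
mean dwell time (mean maximal-run length × step × TR / 60, in minutes)
and the number of transitions.

### Graph metrics

Connectivity matrices are binarised by *proportional thresholding*:
keeping the top `round(p/100 · R(R−1)/2)` upper-triangle edges by signed
weight, for p from 10% to 34% in 1% steps — 25 binary graphs per matrix.
Signed (not absolute) ranking is the default, matching the toolbox
lineage the workflow descends from; `rank_by_absolute = TRUE` is
available. Rounding is half-up and ties in weight break by the fixed
column-major pair order, making the edge set deterministic; nestedness of
edge sets along the sweep is a tested invariant.

On each binary graph the package computes global efficiency (mean inverse
shortest-path length, disconnected pairs contributing 0), degree
assortativity (Newman's end-point degree correlation; undefined on
regular graphs and then treated as missing, never 0-imputed, since
imputation would bias toward the null), per-node clustering coefficients
(0 for degree < 2) and normalised betweenness centrality, plus
small-worldness σ = (C/C_null)/(L/L_null) against degree-preserving
rewired nulls (default `n_null_graphs = 100`, 10 double-edge swaps per
edge) to verify that the threshold range straddles the small-world
optimum. Characteristic path length and degree distribution are not
reported as stand-alone metrics (they overlap global efficiency and
assortativity); L is used only inside σ. The path-based metrics and the
rewiring null are evaluated through igraph; assortativity uses a direct
vectorised Newman sum-formulation (it sits in the simulation hot loop).
All four metrics are verified against independent brute-force
implementations (BFS distance enumeration, triangle counting,
exhaustive shortest-path enumeration, endpoint-degree correlation) on
random graphs to 1e-9 in the test suite, and assortativity additionally
against igraph.

Each metric's threshold profile is summarised by the trapezoidal AUC over
the grid expressed as fractions (0.10–0.34); missing values are excluded
together with their sub-intervals and flagged.

### Associations

The response is `100 · (ON-OFF − ON-ON) / ON-OFF`, the percent UPDRS-III
improvement from stimulation with both assessments on medication. Pearson
partial correlations relate each target to the response: graph-metric
AUCs and FC edges control for overall FC; temporal statistics use no
additional covariate (the source leaves this unstated; none is applied,
and the choice is configurable in code). Age, gender, UPDRS-III ON and
motion are *not* re-entered here because they were consumed by the
static-stage residualisation. p-values use the t distribution with
n − 2 − |Z| degrees of freedom and Fisher-z confidence intervals with
variance 1/(n − 3 − |Z|). Benjamini–Hochberg FDR is applied within each
local-metric family (one family per metric per state, across nodes) and
each edge family (one per state); global metrics and temporal statistics
are reported uncorrected, mirroring the source analysis. Two-sided tests
throughout.

## The synthetic cohort generator

No imaging data accompany the emulated study, so the generator is a
first-class module: every downstream stage is exercised against known
ground truth.

* **Regions.** 25 regions in 8 networks (Sa 1, DMN 7, FPN 7, SM 4, Ce 2,
  Vi 2, Au 1, La 1), 253 time points at TR = 2.7 s.
* **States.** Two correlation templates: a hyperconnected state
  (within-network 0.60, between 0.30) and a hypoconnected state in which
  coupling survives mainly inside the SM, DMN and Vi blocks (0.45 there,
  0.15 other within, 0.05 between), both projected to valid correlation
  matrices. The hypoconnected block structure follows the qualitative
  description of the emulated result, not quantitative values.
* **Dwell structure.** A two-state Markov chain per subject. By default
  each subject's target hypoconnected occupancy u_i is drawn from
  Beta(0.98, 0.48) (mean ≈ 2/3, sd ≈ 0.30, clipped to [0.05, 0.95]) and
  the leave rates set to `switch_rate · (u_i, 1 − u_i)` with
  `switch_rate = 0.06`, fixing expected occupancy at u_i while keeping
  the expected transition count near 4 per scan and the hypoconnected
  dwell time at a few minutes — the temporal statistics of the emulated
  cohort (occupancy 67 ± 33%, ~4 transitions, dwell ≈ 4.6 vs 1.0 min).
  These are emulation targets of the generator, not test assertions.
* **Signal.** At each TR a zero-mean Gaussian draw from the active
  state's covariance, then variance-preserving AR(1) smoothing
  (`ar_coef = 0.3`) and column restandardisation. This switches
  covariance pointwise instead of convolving with a hemodynamic
  response — a simulation simplification that is sufficient to stress
  windowed estimation but does not emulate hemodynamic blurring,
  scanner noise spectra, or head motion.
* **Planted association.** Each subject has a latent *resilience* that
  moves edge weight between hub–hub and hub–leaf pairs of the
  hypoconnected template (hubs = SM/DMN/Vi regions), then re-projects to
  a correlation matrix; higher resilience yields higher assortativity of
  the thresholded graphs (monotonicity is unit-tested). Because
  assortativity cannot be set in closed form, each subject's true
  state-2 assortativity AUC is computed directly from its generated
  matrix, and the response is `53.5 + 16.7 · (ρ·z(A) + √(1−ρ²)·ε)`
  clipped to [0, 100] — mean, spread and range of the emulated cohort's
  response — giving a population correlation of ρ
  (`planted_r`, default −0.7) between true assortativity and response.
  The phenotype file carries the response through the ON-OFF/ON-ON score
  pair so that `dbs_response()` reconstructs it.

What passing tests on this generator do **not** show: robustness to
hemodynamics, physiological noise, motion artefacts, atlas/IC
misalignment, or real between-subject anatomical variability. They show
that the estimation chain is internally correct and recovers planted
structure of realistic size at realistic sample sizes.

## Numerical choices and degenerate inputs

* Graphical lasso: outer tolerance 1e-6 (relative to the mean absolute
  off-diagonal), inner coordinate-descent tolerance a tenth of that;
  non-convergence is an error naming the window.
* Fisher z features clip |r| at 1 − 1e-7 before `atanh`.
* k-means restarts that lose a cluster (possible under Lloyd) are
  resampled; identical pooled windows are rejected as unclusterable.
* Assortativity on regular graphs, rewiring-degenerate small-world
  nulls, empty states, all-negative matrices in `overall_fc()` — each is
  either a missing value with a logged warning or an error, as the
  respective function documents; missing values never silently become
  numbers.
* All randomness flows from one run seed, fanned out per stage through a
  fixed hash (`stage_seed`), so reruns are byte-identical and one
  stage's draws cannot perturb another's.

## Experiment sizes used by the packaged validation

The packaged validation experiments (test suite and
`scripts/acceptance.R`) choose desk-scale problem sizes:

* *State recovery*: 20 generator seeds × 18 subjects × 253 volumes;
  windows at `lambda = 0` (the unpenalised tapered correlation), k-range
  2–5 with 8 restarts. The full k = 2..10 × 100-restart selection is the
  analysis default; the reduced grid is used for the repeated experiment
  and makes the same decision on these well-separated cohorts.
* *Association recovery*: 100 cohorts of 60 subjects for the planted
  ρ = −0.7 effect, 200 null cohorts for type-I calibration. These
  operate on the generator's true state matrices — the planted quantity
  itself — rather than re-running windowing and clustering per cohort.
* *Full pipeline*: one 18-subject cohort at analysis-like settings
  (λ grid {0.03, 0.1, 0.3}, k 2–5, 10 restarts, 20 small-world nulls).

## Known limitations

* The generator's two states are stylised block models; real dynamic FC
  has richer geometry and the silhouette landscape of real data is far
  flatter than the planted one.
* Between-subject variance of static FC in the generator is dominated by
  occupancy mixing plus windowed-estimation noise; it reproduces the
  *ordering* (state medians vary less than static FC) but not the
  magnitude of the emulated study's variance figures, which reflect real
  anatomical heterogeneity the generator does not model.
* Assortativity estimated from regularised 22-TR windows is a noisy,
  attenuated version of the underlying state topology: in single
  18-subject runs the planted state-2 association keeps its sign but
  shrinks well below its planted size and need not reach significance.
  The validation experiments therefore separate statistical recovery
  (on the generator's true state matrices) from end-to-end estimation,
  which is reported descriptively.
* Edge-wise covariate residualisation is a linear, univariate stand-in
  for full multivariate covariance modelling.
* The pooled distance matrix bounds cohorts to roughly 10⁴ windows;
  larger cohorts would need a streaming silhouette.
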