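# dynstates

Dynamic functional-connectivity brain states and graph-theory markers of
treatment response, for resting-state ROI/IC time series.

## The problem

Whole-scan ("static") functional connectivity assumes one brain state
spans the acquisition. When connectivity is instead estimated in short
sliding windows and the windowed matrices are clustered across subjects,
recurring *brain states* emerge — typically a hyperconnected and a
hypoconnected regime with very different network topology. A clinical
marker can live in one state and be invisible in the whole-scan average.
The motivating application is predicting motor response to subthalamic
deep brain stimulation (STN-DBS) in Parkinson's disease from
preoperative resting-state fMRI, where degree assortativity (a
resilience-like property: do hubs attach to hubs?) of the hypoconnected
state correlates negatively with the percent UPDRS-III improvement,
while no static measure does.

`dynstates` implements that full analysis chain for anyone with
per-subject region time courses and a phenotype table — no imaging
preprocessing, which is assumed done:

1. **Static FC** — pairwise Pearson correlation over the scan; edge-wise
   residualisation against cohort covariates (age, gender, UPDRS-III ON,
   head motion); per-subject *overall FC* (mean positive edge) kept as a
   later control covariate.
2. **Windowed FC** — 22-TR windows (59.4 s at TR = 2.7 s), Gaussian
   taper (σ = 3 TR), step 1 TR (253 volumes → 231 windows); sparse
   inverse covariance per window by graphical lasso, penalty chosen per
   subject by held-out likelihood over 10 random window splits.
3. **Brain states** — k-means on Fisher-z edge vectors pooled across
   subjects (100 restarts, k = 2…10 by silhouette, BIC as validation);
   per-subject per-state median matrices; fraction time, dwell time,
   transition counts.
4. **Graph metrics** — proportional thresholding at 10–34 % in 1 % steps
   (25 binary graphs per matrix); global efficiency, assortativity,
   clustering coefficients, betweenness centrality, small-worldness
   versus degree-preserving rewired nulls; trapezoidal AUC across the
   threshold sweep.
5. **Associations** — Pearson partial correlations of metric AUCs, FC
   edges and temporal statistics with the response
   `100·(ON-OFF − ON-ON)/ON-OFF`, controlling overall FC for
   metric/edge tests; Benjamini–Hochberg FDR within each local-metric
   and edge family.

Because the cohort it emulates has no public data, the package ships a
**synthetic cohort generator** (`generate_cohort()`): 25 regions in 8
networks, two planted connectivity states with per-subject Markov dwell
structure (occupancy ≈ 67 ± 30 %, a handful of transitions per scan),
and a planted correlation between true hypoconnected-state assortativity
and response, so the whole chain is testable against ground truth.

## Worked example

```r
library(dynstates)

ch  <- generate_cohort(n_subjects = 18, t_points = 253, seed = 42)
cfg <- run_config(k_min = 2L, k_max = 5L, kmeans_reps = 10L,
                  lambda_grid = c(0.03, 0.1, 0.3), lambda_reps = 5L,
                  n_null_graphs = 20L, rng_seed = 42L)
study <- dfc_study(ch, cfg)
summary(study)
plot(study)   # assortativity AUC vs response, one panel per condition
```

```
Brain-state decomposition of 18 subjects: k = 2
  silhouette by k: 2:0.215  3:0.105  4:0.053  5:0.049
  state 1: occupancy 32.80 +/- 27.97 %, mean dwell 1.35 min
  state 2: occupancy 67.20 +/- 27.97 %, mean dwell 4.20 min
  transitions: 4.39 +/- 3.88
  mean edge variance: static 0.0094; state1 0.0102, state2 0.0073
  global metric associations with response:
    global_efficiency  static  r = +0.283 [-0.229, +0.672], p = 0.2712 (n = 18)
    assortativity      static  r = +0.226 [-0.286, +0.637], p = 0.3836 (n = 18)
    global_efficiency  state1  r = -0.295 [-0.714, +0.280], p = 0.3063 (n = 15)
    assortativity      state1  r = +0.120 [-0.438, +0.612], p = 0.6817 (n = 15)
    global_efficiency  state2  r = +0.506 [+0.034, +0.794], p = 0.0381 (n = 18)
    assortativity      state2  r = -0.403 [-0.740, +0.096], p = 0.1088 (n = 18)
  notes:
    - state 1: 3 subject(s) never visit it (sim003, sim006, sim014); excluded pairwise
```

Reading the output: silhouette clearly picks k = 2 states; subjects
spend about two thirds of the scan in the hypoconnected state 2 (67 ±
28 %) with a dwell time of a few minutes and ~4 transitions per scan —
the temporal profile the generator emulates. The planted negative
association between state-2 assortativity and DBS response (population
value −0.7 on the *true* state matrices) shows up in the right state
with the right sign (r = −0.40) but attenuated: at n = 18, assortativity
estimated from 22-TR regularised windows carries substantial estimation
noise, and no static or state-1 metric shows a comparable pattern.
Statistical recovery of the planted effect at its full size — and the
type-I calibration of the machinery — are demonstrated on the
generator's true matrices by the validation experiments below. Subjects
who never visit a state are excluded pairwise from that state's tests,
as the notes record.

A command-line interface wrapping the same functions (subcommands
`simulate`, `static`, `dynamic`, `states`, `graph`, `associate`, `run`)
is installed at `inst/cli/dynstates`.

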