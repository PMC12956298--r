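---
title: "Edge-level mixed models for DMN small-world analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-level mixed models for DMN small-world analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Cognitively normal brains balance *segregation* (dense local clustering
that supports specialized processing) against *integration* (short paths
that support distributed processing); networks showing both are called
small-world. Chronic HIV infection and regular marijuana (MJ) use have
each been associated with altered resting-state connectivity of the
default mode network (DMN), and their joint effect is poorly understood.
`netlmm` asks: do the four cells of an HIV × MJ design differ in how DMN
connection strength relates to nodal clustering and nodal efficiency, and
is that relationship moderated by global cognitive performance (GlobalT, a
demographically adjusted composite T-score)?

The statistical object is deliberately *not* a per-subject summary
statistic. Instead every retained edge of every subject becomes one
observation, and group differences appear as interactions between group
indicators, nodal network metrics, and a DMN edge-class indicator. This
keeps the DMN embedded in its whole-brain context and lets a single model
carry confounders, distance effects, and subject-level dependence.

## Pipeline

1. **Connectome construction** (`correlation_network`,
   `apply_edge_filters`): per-run column standardization, temporal
   concatenation, Pearson correlation; negative weights are set to zero
   (observed zeros), and pairs of regions with centroids strictly closer
   than 20 mm are *structurally missing* — they never enter metrics or the
   edge table, which is distinct from an observed zero. Filtering is
   idempotent. Subjects with relative mean displacement (RMD) of 0.3 mm or
   more are excluded (`qc_filter_subjects`); both thresholds are strict
   inequalities.
2. **Graph metrics** (`weighted_clustering`, `weighted_shortest_paths`,
   `nodal_global_efficiency`): Onnela weighted clustering with matrix-wide
   max normalization, and nodal global efficiency with connection lengths
   `1/w` and unreachable pairs contributing zero (the `(n-1)` denominator
   is not reduced). The Onnela geometric-mean form and the `1/w` length
   map are the standard weighted-undirected conventions of the brain
   connectivity toolboxes; `-log w` lengths were rejected as harder to
   interpret on correlation weights. Structurally missing pairs behave
   exactly like absent edges, since metrics are computed after edge
   exclusion.
3. **Edge design** (`build_edge_table`, `assemble_design_matrix`): one row
   per subject × retained edge (strictly positive, non-missing). The
   edge-level metric covariate is the arithmetic mean of the two endpoint
   nodal values; edges are classed within-DMN / between / outside, with
   outside as the reference level and between never contrasted. Distance
   is squared *before* centering (squaring after would change the model).
   All continuous covariates — network metrics included — are centered by
   their grand mean over rows; binary indicators stay 0/1; interaction
   columns are products of the already-centered parents. The primary model
   has exactly 43 fixed-effect columns, the GlobalT model 79.
4. **Mixed model and inference** (`fit_lmm`, `group_contrast_vector`,
   `wald_test`, `adaptive_fdr`): subject-random-intercept LMM estimated by
   REML; contrasts of the interaction coefficients give each group's
   within- or outside-DMN slope difference from the control; Wald z with a
   normal reference (row counts are in the 10^5 range, so df corrections
   are negligible); the twelve contrasts of a model's table are adjusted
   together by a two-stage adaptive step-up.
5. **Reporting** (`slope_lines`, `slope_surfaces`,
   `representative_network`, `group_density_comparison`): the quantitative
   content of the standard figures. Slope lines share their algebra with
   the contrast code path, so figure slopes and table estimates agree to
   machine precision; surfaces are affine in GlobalT by construction, and
   the representative network retains the top fraction (default 15%) of
   edges by fixed-effect predicted strength at cohort-mean covariates.

## The mixed-model solver

For the subject-random-intercept structure the marginal covariance is
block diagonal, `V_k = σ_e² (I + θ J_k)` with `θ = σ_b²/σ_e²`, so REML
profiles down to a one-dimensional optimization in `θ`. `fit_lmm`
precomputes `X'X`, `X'y` and per-subject column sums once and evaluates
each candidate `θ` with Sherman–Morrison identities in `O(K p² + p³)` —
exact, and fast enough that hundreds of replicate fits (the null
calibration suite) cost minutes. Numerical choices:

* columns are equilibrated to unit root-mean-square internally (squared
  distances and three-way products differ by six orders of magnitude) and
  estimates unscaled on exit;
* the profiled criterion is minimized over `log θ ∈ [−20, 10]` with
  `optimize()` at tolerance `1e-8`, and the `θ = 0` boundary is always
  evaluated and kept if no interior point beats it;
* rank deficiency is detected on the equilibrated cross-product
  (`qr`, tolerance `1e-12`) and reported with the dependent column names;
* the `converged` flag is honest: any non-finite profile evaluation marks
  the fit unconverged, and the estimates are still returned with a
  warning.

ML (`reml = FALSE`) exists for likelihood-ratio cross-checks; the test
suite verifies the fitter against `lme4` on matched designs and against
exact least squares in the `σ_b = 0` limit.

## Contrast coding

With the HIV / MJ / HIVMJ (= HIV·MJ) indicator coding, a group's slope
difference versus the HIV−MJ− control is a *sum* of coefficients, not a
single dummy: HIV+MJ− uses the hiv terms, HIV−MJ+ the mj terms, and
HIV+MJ+ the sum of hiv, mj and hivmj terms. `outside` contrasts use the
group × metric products; `within` adds the group × metric × within-DMN
products; GlobalT moderation applies the identical pattern to the
GlobalT-product terms. A zero (self) contrast cannot be constructed
through this interface, and `wald_test` rejects an all-zero vector.

## Adaptive FDR

The two-stage step-up: stage 1 runs Benjamini–Hochberg at `q/(1+q)` and
estimates the number of true nulls as `m₀ = m − r₁`; if `r₁ = 0` nothing
is rejected, if `m₀ = 0` everything is; otherwise stage 2 reruns BH at
`q·m/m₀`. Adjusted p-values are defined operationally as the smallest `q`
at which a hypothesis is rejected and found by bisection (60 iterations,
capped at 1); the tests assert monotonicity in `q` and step-up coherence.
Note the stage-2 level here is `q·m/m₀`; a common variant uses
`q/(1+q)·m/m₀`, which is uniformly slightly more conservative — the
package pins the former and documents it, since the choice is otherwise
invisible to users.

## The synthetic cohort and what it does (not) show

No public dataset accompanies this design, so validation rests on
simulation with recoverable ground truth. `simulate_oracle_cohort`
separates two roles that are entangled in real data:

* a **reference network** per subject supplies the *metric covariates*,
  which are frozen;
* the **strengths** are then drawn from the model's own linear predictor
  `Xβ + b + ε` with known `β`, clipped to `[0, 1]`.

Because the covariates are frozen (not recomputed from the simulated
strengths), refitting recovers `β` exactly in expectation — the estimator
is evaluated under its own assumptions. Endogenous analysis, where metrics
are recomputed from the simulated matrices as with real data, is available
by running the returned matrices back through `compute_nodal_metrics` and
`build_edge_table`; it has no closed-form truth, which is why recovery
testing uses oracle mode.

The reference networks are built from five node regimes re-drawn per
subject (`reference_regimes`): a strongly interconnected hub core, spokes
hanging off it (high clustering, mid efficiency), bridges tying
non-adjacent spokes (near-zero clustering, mid efficiency), small detached
cliques (high clustering, low efficiency), and near-isolates (low both).
Background edges get a mild distance attenuation
(`0.9 + 0.1·exp(−d/60 mm)`), and simulated strengths additionally carry
linear and quadratic distance terms in `β`, so distance-dependent
connectivity is present at both levels. This mixture was chosen — once,
by design — to give the nodal metrics broad support over `[0, 1]` with a
weak clustering–efficiency correlation, because the precision of the
interaction contrasts is proportional to the *within-subject, pair-level*
spread of the metric covariates (the subject random intercept discounts
between-subject spread by roughly `1/(1 + θ n_k)`, which is ~1/500 at
these row counts). Two consequences deserve emphasis:

* **Real connectomes are far more homogeneous.** Correlation networks
  with only negatives removed have narrow metric distributions and a
  strong clustering–efficiency correlation; at this package's desk scale
  (60 subjects, 80 nodes) such homogeneity would make the interaction
  standard errors an order of magnitude larger than the published-scale
  effect sizes. Passing recovery tests therefore demonstrates the
  *correctness of the estimator and contrast algebra*, not that a
  60-subject study of real brains would be adequately powered.
* **There is a hard ceiling on efficiency spread.** Because efficiency is
  a mean inverse shortest-path length, any strong edge to a node floors
  that node's efficiency through two-hop paths; the maximal standard
  deviation of nodal efficiency over `[0, 1]`-weighted graphs is about
  0.25–0.3 and is achieved only by degenerate core/isolate structures
  that simultaneously destroy clustering spread. The calibrated defaults
  sit close to the joint optimum: within-DMN contrast SEs of ~0.006
  (clustering) and ~0.010 (efficiency) at the reference scale. One
  consequence is that the smallest published-scale efficiency effect
  (0.012) is recovered within noise but its SE cannot be pushed below
  half the effect size at this scale; the recovery tests document this
  rather than silently enlarging the cohort.

Other generator defaults: group-wise GlobalT, age, education means/SDs and
sex/race proportions follow the demographic structure of a 237-participant
HIV × MJ cohort (e.g., GlobalT 50.45 ± 5.91 in controls vs 47.27 ± 5.21 in
HIV+MJ+); RMD is truncated to (0, 0.3) mm so generated subjects pass QC;
`σ_e = 0.05`, `σ_b = 0.02`; the baseline `β` puts mean strength near 0.4
with mild distance decay, which keeps the clipping fraction at zero in
practice (the contract is < 5%, checked in tests). The edge-strength
distribution (clipped Gaussian around the linear predictor) is a modeling
decision; nothing in the design constrains the real-world marginal.

## Problem sizes in the test suite

The suite validates at three scales, chosen as the package's reference
conditions: exhaustive graph-metric checks against brute-force oracles on
all 4-node graphs with weights in {0, 0.25, 0.5, 1} (4096 graphs) plus
seeded 5–6-node samples; unit and integration tests on 24–40-node cohorts
with 3–8 subjects per group; and two full recovery experiments (80 nodes,
20 DMN, 15 subjects per group, ~190,000 edge rows, seeds 42/43) plus a
200-replicate null calibration at 40 nodes that checks p-value uniformity
(Kolmogorov–Smirnov) and the family-level false-rejection rate of the
adaptive FDR (observed ≤ 7%).

## Known limitations

* The random-effect structure is a subject intercept only; random metric
  slopes are plausible but unidentified in oracle mode and left to future
  work.
* The strength model conditions on strictly positive edges; the presence /
  absence process is not modeled (a two-part extension would add a
  logistic component).
* Edges within a subject are treated as exchangeable given the intercept;
  spatial autocorrelation between overlapping edges is not modeled.
* Representative networks use a top-fraction rule on fixed-effect
  predictions — a reproducible, monotone stand-in for publication-grade
  network rendering, not a calibrated thresholding procedure.
* The pipeline consumes region time series or correlation matrices; it
  does not touch image preprocessing, nuisance regression, or atlas
  construction.
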