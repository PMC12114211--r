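---
title: "Dietary networks: model, estimation and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary networks: model, estimation and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietnet)
```

## The statistical model

`dietnet` treats the `log10(1 + grams/day)` transforms of `p` food-group
intakes as approximately multivariate normal and estimates their
conditional-dependency graph. A zero entry `Θ_ij` of the precision matrix
`Θ = Σ⁻¹` means groups `i` and `j` are independent given every other group,
so the graph separates direct dietary associations from ones merely induced
by shared habits. Sparsity is imposed by the graphical lasso — the
L1-penalised Gaussian maximum-likelihood problem

$$\hat\Theta = \arg\max_{\Theta \succ 0} \; \log\det\Theta - \mathrm{tr}(S\Theta)
  - \lambda \sum_{i \neq j} |\Theta_{ij}|,$$

with the penalty on off-diagonal entries only. Edge weights are signed
partial correlations `ρ_ij = −Θ_ij/√(Θ_ii Θ_jj)`; positive and negative
conditional dependencies are both meaningful and both retained.

The model's assumptions, and where they bend on real FFQ data:

* **Post-transform normality.** The log10 transform removes most
  right-skew, but food groups that many participants never consume put a
  point mass at zero. The generator exposes this through its
  `zero_inflation` parameter; see *What passing tests show* below.
* **Linear hazard in the score.** The Cox stage enters the community score
  linearly; quintile contrasts are the model-free check on that shape.
* **Self-reported outcomes.** The outcome machinery models the wave
  structure of self-report (first "yes" defines the event, cases are not
  carried forward) but not its misclassification.

## Estimation pipeline and tunables

1. **Transform and scale.** `log_transform()` then `sample_covariance()`
   (divisor `n`). By default the model is fitted on the **correlation**
   matrix of the transformed intakes. This was a genuinely open design
   point: fitting on the covariance preserves the grams/day variance
   structure, but a single penalty then bears unevenly — food groups with
   small log-scale variance have their edges shrunk away first, and in
   planted-structure experiments this broke recovery (spurious isolated
   nodes, fragmented communities) while correlation-scale fitting recovered
   the planted partition exactly. `scale = "cov"` remains available for
   sensitivity analysis.
2. **Penalty selection** (`stars_select()`). StARS with the original
   recommendations: `N = 20` subsamples without replacement of size
   `b = ⌊10√n⌋` (capped at `n`), a 30-point log-spaced grid from
   `λ_max = max_{i≠j}|S_ij|` down to `0.1 λ_max`, instability threshold
   `β = 0.05`. Per-edge instability is `2f̂(1−f̂)` (maximal 0.5 when an edge
   appears in half the subsamples); the total instability is monotonised
   from the sparse end and the selected `λ` is the smallest grid value
   whose monotonised instability is at most `β`. If nothing qualifies the
   sparsest grid value is returned with a warning.
3. **Sparse precision** (`graphical_lasso()`). Blockwise coordinate
   descent, each column a lasso solved by cyclic coordinate descent
   (inner tolerance 1e-10). Stopping is certified by a duality gap: the
   working covariance `W` is projected onto the dual-feasible box
   `|W_d − S|_∞,off ≤ λ`, giving the bound
   `f* ≤ −log det W_d − p`; iteration stops when this bound exceeds the
   objective of the recovered sparse `Θ` by less than `tol = 1e-6`
   (at most 500 sweeps, non-convergence is an error carrying the gap).
   The certificate is computed this way because the recovered `Θ`
   satisfies the textbook gap identity *by construction* — evaluating the
   gap at `Θ` itself always returns ~0 and certifies nothing. `λ = 0` is
   solved exactly by Cholesky inversion.
4. **Edge calling** (`to_network()`): `|Θ_ij| > 1e-6`. Nodes left without
   edges are *isolated*: excluded from community detection, analysed
   one-by-one in the survival stage.
5. **Communities and centrality.** Louvain multilevel modularity
   optimisation (`igraph`) on the non-isolated subgraph with `|ρ|` edge
   weights — negative conditional dependencies count as connection
   strength, since planted and observed communities contain both signs; a
   binary mode exists for sensitivity. The node visit order is shuffled by
   a seed, making runs reproducible. Eigenvector centrality is computed by
   power iteration per connected component on the `|ρ|`-weighted adjacency
   (tolerance 1e-10, max 1e4 iterations), with each component's maximum
   scaled to 1 and isolated nodes at 0. Two numerical details: the
   iteration runs on `A + sI` (`s` = max row sum), which leaves the
   eigenvectors untouched but prevents the oscillation that plain power
   iteration exhibits on bipartite components (e.g. path graphs); and
   whole-graph rather than per-community centrality is the default, with a
   per-community alternative reachable by subsetting, because the
   centrality feeding the scores should not depend on where the partition
   happens to cut. Per-community central nodes break ties
   lexicographically, with a warning.
6. **Scores and quintiles** (`community_scores()`, `assign_quintiles()`).
   Scores multiply centrality by **raw** grams/day — the actual daily
   intake, not the transformed value — and sum within community. Quintiles
   are computed on the whole population (not within sex), so Q1–Q5 mean
   the same thing in every stratum; ties are resolved by stable participant
   order and a tie straddling a boundary warns. A column with more than
   80% identical scores refuses quintile assignment and points the user to
   the continuous score. The continuous score enters the Cox model in its
   raw units (hazard ratios sit near 1); `standardize = TRUE` rescales
   per SD.
7. **Cox models** (`fit_cox()`, `association_table()`). Partial likelihood
   with the Efron tie correction — person-years derived from wave dates are
   heavily tied, and Efron is the better-behaved default. Time origin is
   the baseline survey; years use 365.25 days. Model 1 adjusts age (+ sex
   in the total stratum); Model 2 adds the demographic/anthropometric
   block; Model 3 adds lifestyle and total energy. The sex interaction is
   a Wald test on the product terms, reported for Model 3 in the total
   stratum. Fewer than 2 events or a constant exposure is an error, not a
   fit; fewer than 10 events warns. No multiple-testing correction is
   applied across communities or outcomes (α = 0.05 throughout), and
   proportional-hazards diagnostics are left to the user — both deliberate
   mirrors of common practice in this literature, flagged here as
   limitations.

## Cohort construction rules

* Energy exclusion keeps males with 800–4000 kcal/day and females with
  500–3500; the bounds are *strict* exclusions ("fewer than" / "more
  than"), so boundary values are retained.
* A baseline "yes" to either outcome question excludes the participant; a
  missing baseline response is treated as "no" (counted in the exclusion
  log) — exclusion on missingness would silently drop non-prevalent
  participants.
* Across follow-up waves, the first wave with any "yes" fixes the event
  and its date; both-in-one-wave is its own status and counts as an event
  for stroke, MI, and the combined outcome. All-missing responders are
  excluded; mixed missing/"no" responders are non-cases censored at their
  last responded wave. In type-specific analyses a participant whose only
  event is the other type is censored at their last observed wave, because
  self-report stops after the first event.
* Covariates with under 5% missingness (evaluated on the post-exclusion
  cohort) are imputed with the sex-stratified median (numeric) or mode
  (categorical); at or above 5%, categoricals gain an explicit `unknown`
  category while numerics are median-imputed with a companion missingness
  indicator — the numeric analogue of an unknown category, since a numeric
  column cannot hold one.

## What the synthetic generator emulates

`cohort_spec()` bundles the study conditions: `n` participants × 45 food
groups; a planted precision matrix with 5 communities of sizes 8/6/6/5/11
and 9 isolated nodes; zero-inflated lognormal intakes on the log10 scale;
demographic and lifestyle covariates with injected missingness (income
above the 5% threshold, BMI and education below it); and multi-wave
self-reported outcomes from an exponential proportional-hazards model
(4 waves, 2 years apart, 5% missing responses, 2% baseline prevalence,
baseline hazard 0.006 events/person-year at mean covariates).

Design of the planted network, and why:

* Each community is a random spanning **cycle** plus independent extra
  edges (probability 0.2) — a connected "ring + random chords" block in
  which every member has degree ≥ 2, so no community node's membership
  hinges on a single edge.
* Planted partial correlations are drawn from |ρ| ∈ [0.15, 0.3] with 20%
  negative signs. The lower bound is a detectability floor: StARS judges
  edges on subsamples of size `⌊10√n⌋` (≈ 707 at n = 5000), where
  |ρ| = 0.1 sits near z ≈ 2.7 and is intrinsically unstable — a benchmark
  whose planted effects cannot be detected at the stated sample size
  would test nothing.
* Positive definiteness is guaranteed by seeded rejection on the minimum
  eigenvalue of `I − R` (floor 0.08) rather than row-sum diagonal
  dominance, which the requested magnitudes would violate in the 11-node
  block; the planted partial correlations are kept exactly as drawn.
  Specs that cannot reach positive definiteness (e.g. a dense block at
  |ρ| = 0.6) fail with an error naming the bound.
* Community log-hazards are per SD of the true score (defaults 0, −0.12,
  −0.2, +0.12, +0.08 for the five planted communities), because the raw
  score's scale is an arbitrary product of centralities and grams;
  numeric covariate effects are per unit above the cohort mean, making
  `baseline_hazard` interpretable as the rate at mean covariates.
* Intake location/scale parameters per group default to U(0.8, 2.0) and
  U(0.25, 0.45) on the log10 scale (median intakes roughly 5–100 g/day).
  No per-group intake distributions are available to emulate, so these
  are arbitrary and tunable.
* Missing wave responses are injected only into "no" responses: injecting
  them into the event wave would erase planted events and conflate
  missingness with under-ascertainment, which the generator does not
  attempt to model.

**What passing tests show, and what they do not.** The default generator
produces post-transform Gaussian data — the GGM's home turf — and under
those conditions the pipeline recovers the planted partition essentially
perfectly at n = 5000. Real FFQ data are not Gaussian: never-consumed
foods put mass at zero. Setting `zero_inflation` to 0.05–0.10 degrades
recovery visibly (at 10% zeros the partition agreement drops to ARI ≈
0.6), because each zero is an extreme low outlier on the log scale. Passing
tests therefore validate the estimator's correctness, not its robustness
to zero-inflation; on real data, groups with many non-consumers deserve
care (merging, presence adjustment, or nonparanormal extensions, which
this package deliberately does not implement).

## Problem sizes used by the test suite

Unit tests run on 8–12-node networks with cohorts of a few hundred;
validation experiments use the full 45-node conditions with n = 2000 for
penalty-selection stability and n = 5000 for structure recovery, 100
replicates for Cox null calibration, and 25 end-to-end replicates for
directional recovery of the planted protective community — sizes at which
each experiment's sampling noise is small relative to the property being
asserted, while the whole suite stays runnable on a laptop in about a
minute.

## Known limitations

* Single-estimator scope: no nodewise-regression or nonparanormal
  alternatives to the graphical lasso.
* Community labels are structural (`c1..cK` by node order), never
  nutritional; interpreting a community is the analyst's job.
* The interval-censored self-report design is reduced to right censoring
  at wave dates; no competing-risks handling.
* Quintile cut points come from the analysed population; external cohorts
  scored with `predict()` reuse the fitted centralities but get their own
  quintiles.
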