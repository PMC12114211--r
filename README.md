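# dietnet

Dietary patterns are usually extracted with PCA or factor analysis, which
force foods into components without a probabilistic model. `dietnet`
implements the network alternative for epidemiologists working with food
frequency questionnaire (FFQ) data: it models the conditional-dependency
structure of food-group intakes as a sparse Gaussian graphical model, reads
dietary "communities" off that network, scores each participant on every
community, and relates those scores to disease risk with Cox
proportional-hazards models. A synthetic-cohort generator with a planted
network and planted hazards makes every stage testable against ground truth,
which matters because cohort data of this kind (e.g. national biobank FFQs)
are usually access-restricted.

## The model

Intakes (grams/day) for `p` food groups are transformed to
`y = log10(1 + x)` and assumed approximately multivariate normal. The
precision matrix `Θ = Σ⁻¹` encodes conditional independence: `Θ_ij = 0` iff
groups `i` and `j` are independent given all other groups. `Θ` is estimated
by the graphical lasso,

```
Θ̂ = argmax_{Θ ≻ 0}  log det Θ − tr(SΘ) − λ Σ_{i≠j} |Θ_ij| ,
```

with `S` the sample correlation (default) or covariance of the transformed
intakes. The penalty `λ` is chosen by StARS: refit on subsamples of size
`⌊10√n⌋`, measure per-edge selection instability `2 f̂ (1 − f̂)`, and take
the least regularisation whose monotonised total instability stays below
`β = 0.05`. Edges carry the signed partial correlation
`ρ_ij = −Θ_ij / √(Θ_ii Θ_jj)`.

Communities are found by multilevel (Louvain) modularity optimisation on
the `|ρ|`-weighted subgraph of non-isolated nodes; nodes isolated by the
regularisation are analysed individually. Each node gets an eigenvector
centrality (power iteration per connected component, component maximum
scaled to 1), and each participant a community score

```
score(i, c) = Σ_{j ∈ community c} centrality(j) · intake_raw(i, j) .
```

Continuous scores and population quintiles (Q1 reference) enter Cox models
at three adjustment levels — Model 1: age (+ sex for the total population);
Model 2: + education, income, city, marital status, job, comorbidity
history, BMI, waist category; Model 3: + drinking, smoking, total energy,
exercise — fitted for the total population and within sex, with a
sex-by-score interaction at Model 3.

## Worked example

```r
library(dietnet)

# synthetic cohort at the default study conditions: 45 food groups,
# 5 planted communities (sizes 8/6/6/5/11), 9 isolated nodes
cohort <- simulate_cohort(cohort_spec(n = 5000, seed = 1))
built  <- build_cohort(cohort$intakes, cohort$covariates,
                       cohort$waves, cohort$baseline)

fit <- dietary_network(built$intakes, seed = 1)
print(fit)
#> Dietary network model
#>   45 food groups, 4833 participants
#>   lambda = 0.0865 (StARS), 53 edges, 9 isolated nodes
#>   5 communities (sizes 5/6/6/11/8), modularity Q = 0.742

scores <- predict(fit, built$intakes)      # per-person scores + quintiles
d <- survival_data(built, scores = scores)
fit_cox(d, "score_c1", outcome = "stroke_or_mi", model = 3,
        stratum = "total", interaction = TRUE)
#> Cox model 3, outcome stroke_or_mi, stratum total (4833 participants, 316 events)
#>      term    hr             ci     p
#>  score_c1 1.001 (1.000, 1.002) 0.181
#> sex-interaction p = 0.91
```

Reading the output: the StARS-selected penalty leaves 53 conditional
dependencies; the 9 isolated groups are exactly the planted ones, and the
five detected communities reproduce the planted partition. The hazard ratio
is per unit of the raw community score (centrality-weighted grams/day), so
values sit close to 1; community `c1` maps to a planted null community here
and its confidence interval covers 1, as it should.
`dietnet_pipeline(pipeline_config(spec = cohort_spec(n = 5000, seed = 1)))`
runs the same chain end to end and `report()` prints community membership,
central nodes, score medians and the full hazard-ratio tables.

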