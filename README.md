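# painnet

Partial-correlation network analysis of chronic-pain survey data.

Cross-sectional studies of chronic pain increasingly model the interplay of
pain outcomes (intensity, disability, quality of life) with psychological,
social and societal factors as a **Gaussian graphical model (GGM)**: nodes
are scored questionnaire variables and an edge between two nodes is their
partial correlation — their association after conditioning on every other
variable in the set. `painnet` packages the full workflow such a study
needs, from raw participant-by-item responses to a stability-checked
network, plus the simulation machinery used to decide whether a planned
sample size can support a network of a given size and density.

## What the package does

- **Synthetic data** (`generate_true_network`, `chronic_pain_network_spec`,
  `sample_gaussian`, `emulate_survey`): ground-truth sparse GGMs via the
  diagonal-dominance construction standard in the network-simulation
  literature, and Likert-style survey tables (items, skewed margins,
  missingness, careless responders) generated from them, so every
  downstream stage is testable without any external dataset.
- **Preprocessing** (`clean_sample`, `score_variables`, `cronbach_alpha`,
  `marginal_skewness`, `henze_zirkler`, `nonparanormal_transform`):
  participant-level exclusion rules (eligibility, duplicates, empty
  responses, speeders, attention checks, per-variable missingness),
  reverse coding and scale scoring (sums, CPGS mean×10, composites) with
  person-mean imputation, reliability and normality diagnostics, and the
  rank-based nonparanormal transformation.
- **Estimation** (`estimate_network`, `predictability`): nodewise LASSO
  regressions with 10-fold cross-validation (via glmnet), Loh–Wainwright
  style thresholding, AND-rule symmetrization with geometric-mean edge
  weights, and per-node predictability (R²).
- **Stability** (`bootstrap_network`): nonparametric bootstrap of the whole
  estimator; per-edge inclusion proportions and empirical 95% quantile
  intervals.
- **Sample-size simulation** (`run_simulation`): grid of sample sizes ×
  variable counts × densities; estimation error, sensitivity, specificity
  and weight correlation averaged over replicates.
- **Pipeline** (`run_pipeline`): clean → score → diagnose → transform →
  estimate → predictability → bootstrap for configured variable subsets
  (built-in `"replication"` and `"extended"` presets), with all outputs
  and a hashed run manifest written to disk. A thin command-line wrapper
  lives at `inst/cli/painnet.R`.

## The model in brief

For standardized variables `X_1 … X_p`, each node is regressed on all
others with an L1 penalty chosen by 10-fold cross-validated MSE on a
logarithmic grid. Coefficients below `τ_j = c_j · sqrt(log(p)/n)` are
zeroed (by default `c_j` is the L2 norm of node j's selected coefficient
vector). An edge i–j is kept only if both β_ij and β_ji survive with the
same sign (AND rule), with weight `sign(β_ij)·sqrt(β_ij·β_ji)`, which on
standardized data estimates the partial correlation. Node predictability
is the R² of each node's retained model. Edge stability is assessed by
re-estimating the network on bootstrap resamples.

## Worked example

```r
library(painnet)

cfg <- survey_config(n_participants = 262, n_careless = 7,
                     missing_rate = 0.02, seed = 5)
survey  <- emulate_survey(cfg)             # participant-by-item table
cleaned <- clean_sample(survey, cfg$map)
print(cleaned$report)
#> Cleaning report: 269 in, 258 out
#>   ...
#>   speeders                   -7
#>   excess_missing             -4

scores <- score_variables(cleaned$table, cfg$map)
vars   <- analysis_preset("extended")
m      <- scores[complete.cases(scores[, vars]), vars]
z      <- nonparanormal_transform(m)
henze_zirkler(z)   # statistic 1.00, p = 0.32: normality not rejected

net <- estimate_network(z, folds = 10, seed = 11)
print(net)
#> GGM network: 15 nodes, 15 of 105 possible edges
#>   mood_symptoms--stress: 0.325
#>   pain_worry--pain_acceptance: -0.226
#>   pain_intensity--pain_disability: 0.221
#>   ...
round(sort(predictability(z, net), decreasing = TRUE)[1:3], 2)
#> quality_of_life  stress  pain_worry
#>            0.23    0.20        0.18
```

The survey generator plants the 15-variable structure of
`chronic_pain_network_spec()` (strongest edge: mood symptoms–stress, partial
correlation .46); the estimate above recovers that edge as the strongest
in the network at .33 — attenuated, as expected, by Likert measurement
error in the simulated items.

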