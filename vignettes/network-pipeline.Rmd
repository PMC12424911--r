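---
title: "Estimating and stress-testing partial-correlation networks from survey data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and stress-testing partial-correlation networks from survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painnet)
```

## The model

`painnet` estimates Gaussian graphical models (GGMs) from questionnaire
data. Under multivariate normality, the (i, j) entry of the inverse
covariance (precision) matrix is, up to sign and scaling, the partial
correlation of variables i and j given all others:

$$\rho_{ij\cdot\text{rest}} = -\frac{\Omega_{ij}}{\sqrt{\Omega_{ii}\,\Omega_{jj}}}.$$

A zero partial correlation means conditional independence, so the sparsity
pattern of $\Omega$ *is* the network. Because survey samples are small
relative to the number of edges ($p(p-1)/2$), the estimator regularizes:
each variable is regressed on all others with an L1 (LASSO) penalty, the
penalty weight chosen per node by 10-fold cross-validated mean squared
error on glmnet's logarithmic grid. Ties in CV error resolve to the larger
penalty, i.e. the sparser model. Two post-processing steps control false
positives:

1. **Thresholding.** Coefficients below $\tau_j = c_j \sqrt{\log(p)/n}$
   are zeroed. The constant $c_j$ defaults to the L2 norm of node $j$'s
   selected coefficient vector — the convention of the nodewise-estimation
   software family this pipeline follows; `threshold_c = "penalty"`
   substitutes the CV-selected penalty weight, a markedly weaker threshold
   that retains more small edges. The boundary is strict: a coefficient
   exactly at $\tau_j$ survives.
2. **AND-rule symmetrization.** Edge i–j requires both $\beta_{ij}$ and
   $\beta_{ji}$ nonzero with equal sign; its weight is
   $\mathrm{sign}(\beta_{ij})\sqrt{\beta_{ij}\beta_{ji}}$, which on
   standardized data estimates the partial correlation. A sign conflict
   (possible since the two regressions are penalized independently) drops
   the edge and records a warning on the returned object rather than
   erroring: it is a legitimate, if rare, outcome of independent penalized
   fits.

Assumptions worth stating: continuous (or continuized) variables,
multivariate normality after marginal transformation, linear conditional
relations, complete rows (listwise deletion precedes estimation; the 50%
per-variable missingness filter upstream bounds what can be lost), and
i.i.d. participants.

## From raw responses to a variable matrix

Cleaning applies the exclusion rules in a fixed order — consent/
eligibility, no recent pain, pain duration under 3 months, duplicate ids,
no responses beyond demographics, completion under 5 minutes, two or more
failed attention checks (of five), more than 50% of any variable's items
missing. Counts are order-dependent (a speeding attention-check failer is
counted as a speeder), so the `cleaning_report` records the order
explicitly. All thresholds are configurable via `cleaning_thresholds()`;
the defaults are the conventional values just listed.

Scoring reverse-codes flagged items by reflection on the item scale
($x \mapsto \min + \max - x$), then aggregates: plain sums, the Chronic
Pain Grade Scale convention (item mean × 10, giving 0–100 intensity and
disability scores), or composite sums that pool short instruments (e.g. a
mood-symptoms composite of the PHQ-2 and GAD-2 totals, which are strongly
correlated and otherwise inflate the node count). A participant missing at
most half of a variable's items is scored by person-mean imputation across
that variable's available items — standard psychometric prorating, and the
natural complement of a 50% retention rule; with more than half missing
the score is NA.

Normality diagnostics are bias-adjusted marginal skewness (flagged when
$|g| > 0.5$) and the Henze–Zirkler test with its standard smoothing
parameter $\beta = ((2p+1)n/4)^{1/(p+4)}/\sqrt{2}$ and lognormal
p-value approximation. The **nonparanormal transformation** maps each
column's average-ranks to normal quantiles, $r \mapsto
\Phi^{-1}(r/(n+1))$, then standardizes. The $r/(n+1)$ convention keeps
extreme ranks finite without truncation constants and is well defined for
the heavy ties Likert scoring produces; being a rank function, the
transform is exactly invariant to monotone marginal distortions and
preserves Spearman correlations, which is precisely the copula assumption
the downstream Gaussian model needs.

## The synthetic-data generator

The generator exists so that every stage has a ground truth. A
`true_network_spec` is built by sampling an Erdős–Rényi adjacency at a
target density (rejection-sampled into a ±0.05 band around the target,
with at least one edge), drawing raw coupling weights uniformly from
±[0.5, 1], and enforcing positive definiteness by the diagonal-dominance
construction used throughout the psychological-network simulation
literature: set the precision diagonal to 1.5× each row's absolute
off-diagonal sum, normalize rows, symmetrize by averaging. Partial
correlations are then recomputed from the resulting precision, so the spec
is exactly self-consistent (a round-trip property the tests verify to
1e-10).

A consequence of this construction — and the scientific point of the
simulation study — is that realized partial correlations shrink as nodes
gain neighbors: at p = 15 the typical edge magnitude falls from roughly
.14–.67 at density 0.1 to .04–.24 at density 0.5. Dense networks are
therefore intrinsically harder to recover at a fixed n, which reproduces
the characteristic degradation pattern (near-perfect recovery for sparse
networks at n = 250, sensitivity below one half for dense ones). The
low/medium/high density labels map to edge probabilities 0.1/0.3/0.5 —
values spanning the sparse-to-dense range used in comparable simulation
work; both the mapping and the weight distribution are configurable.

Specs can also be built from an explicit partial-correlation matrix
(`true_network_from_partial`, `chronic_pain_network_spec`). There the requested
weights are authoritative, so positive definiteness is instead enforced by
minimal diagonal inflation of the unit-diagonal candidate $I - P$: the
closed form $\delta = (m - \lambda_{\min})/(1 - m)$ (target smallest
eigenvalue m = 0.05) shrinks all weights by the common factor
$1/(1+\delta)$, is deterministic and idempotent, and reports the largest
induced deviation. The built-in 15-variable structure needs no repair at
all ($\delta = 0$), so its printed edge weights are realized exactly.

`emulate_survey()` turns a spec into a study-shaped table: latent variable
scores are sampled from the spec; each item is the latent score times a
loading (default 0.8, chosen to put Cronbach's α near 0.8–0.9 for typical
item counts) plus independent noise; a monotone transform
$g_a(z) = (e^{az}-1)/a$, with $a$ fitted by root finding, sets each item's
sample skewness to its variable's target exactly; items are then
discretized to their Likert scales; missingness is injected completely at
random; and careless-responder rows (sub-5-minute durations, some with
failed attention checks) are appended. The default skew targets (±0.5 on
five variables) mirror the margins a community pain survey shows. What the
generator does **not** emulate: non-monotone measurement distortions,
differential item functioning across languages, missingness that depends
on the data, or careless responders who pass speed and attention screens.
Passing tests on this generator therefore certify the pipeline's
statistical machinery, not robustness to every failure mode of real survey
data.

## Stability, predictability, simulation

`bootstrap_network()` re-runs the entire estimator on B resamples
(default 5000, the conventional choice; tests and examples use B in the
low hundreds). Per edge it reports the inclusion proportion and empirical
(inverse-ECDF, type 1) 2.5%/97.5% quantiles — empirical rather than
bias-corrected because no distributional assumption is wanted and the
quantity summarized is simply "where the edge estimates fell". Replicate
seeds derive from the master seed by counter, so results are independent
of execution order and reproducible; replicates whose resample breaks
estimation (e.g. a constant column) are redrawn and counted.

Node predictability is $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ of each
node's thresholded nodewise model on the standardized data, clipped at
zero. One design choice deserves a note: predictors are restricted to
neighbors that survived symmetrization, so a node with no incident edges
has exactly $R^2 = 0$ even if a one-directional coefficient survived
thresholding. This keeps predictability consistent with the network that
is actually reported.

`run_simulation()` crosses sample sizes × variable counts × densities;
each replicate generates a fresh truth, samples n rows, estimates, and
scores recovery: mean absolute weight error, sensitivity (share of true
edges found), specificity (share of true non-edges kept empty), and the
Pearson correlation between true and estimated upper-triangle weight
vectors. Conventions for degenerate cases: a constant weight vector
(e.g. an empty estimate) makes the correlation undefined — it is recorded
as 0 with a flag and excluded from the cell's correlation mean, with flag
counts reported; a zero-edge truth would make sensitivity undefined, which
the generator's at-least-one-edge guarantee prevents.

## Numerical choices

- glmnet is run with `thresh = 1e-12` so fits are invariant to predictor
  ordering; per-node fold seeds are derived from the node *label*, making
  estimation exactly permutation-equivariant (verified to 1e-6).
- CV ties resolve to the larger penalty (glmnet's `lambda.min`
  convention): sparser and reproducible.
- All randomness flows from integer seeds through a single deterministic
  derivation; identical inputs and seed give bit-identical networks, and
  bootstrap/simulation replicates can be recomputed in isolation.
- The adjacency rejection band (±0.05 realized density, 200 attempts) and
  the PD floor (smallest eigenvalue 0.05) are fixed constants recorded
  here; neither is data-dependent.

## Known limitations

- **No exact support recovery.** The CV-selected penalty is
  prediction-optimal, not model-selection-consistent: small
  sign-consistent spurious edges (absolute weight below ~0.01) survive at
  any sample size, because spurious coefficient magnitudes and the
  threshold $\tau$ both scale as $\sqrt{\log(p)/n}$. Weight estimates
  converge (max error < 0.01 at n = 100000 in the tests), but specificity
  plateaus below 1 — as it does in the simulation tables this pipeline
  reproduces.
- **Bootstrap inclusion under a null.** On data whose true network is
  empty, the fixed sample still carries correlation fluctuations of order
  $1/\sqrt{n}$; the estimator retains some of them, and the bootstrap —
  which resamples that same sample — correctly reports those edges as
  stable features *of the sample*, with inclusion proportions that can
  exceed one half. Inclusion proportions quantify stability, not
  population truth; interpreting them requires the effect-size context of
  the edge estimates themselves.
- **Likert attenuation.** Scored item composites attenuate latent
  correlations (roughly by the squared loading), so networks estimated
  from emulated surveys recover the planted structure with shrunken
  weights. The estimator consistency checks therefore run on continuous
  Gaussian samples, where the target weights are exact.
- Mixed-type (categorical/count) nodes, bias-corrected bootstrap
  intervals, case-dropping centrality stability, and layout/visualization
  beyond simple metric curves are out of scope.

## Problem sizes used by the test suite

The suite exercises the full estimator at n up to 100000 (consistency),
the simulation at 100 replicates per density cell (n = 250, p = 15), and
bootstraps at B = 200 on 4–5-node networks; property checks (coverage,
monotonicity in n, density calibration) run at reduced scale (B = 40–80,
6–20 seeds per condition), sizes chosen to keep the default run within a
desk-scale budget while leaving each check statistically decisive.
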