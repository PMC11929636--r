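---
title: "Estimating psychosocial support networks from mixed-type survey data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating psychosocial support networks from mixed-type survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supportnet)
```

## The scientific problem

Among Black women living with HIV, social support (from family, friends,
and a "special person"), depressive symptoms, post-traumatic stress
symptoms, and gendered coping through self-silencing are thought to relate
to the risk of viral non-suppression not as isolated bivariate
associations, but as a *system* of mutually adjusted relationships.
`supportnet` estimates that system as a Gaussian graphical model (GGM): an
undirected network whose nodes are the psychosocial variables and whose
edges are **partial correlations** — the association between two variables
after conditioning on every other variable in the network. An absent edge
means conditional independence (under multivariate normality of the latent
scores); a present edge is a candidate direct relationship.

The estimation pipeline has four stages, each exposed as ordinary
functions:

1. **Scoring** (`score_scale()`, `score_composite_risk()`,
   `build_node_table()`): items from the MSPSS (perceived support, three
   4-item subscales on a 1–7 metric, aggregated by mean), the CES-D
   (20 depressive-symptom items, 0–3, summed), the Davidson Trauma Scale
   frequency ratings (17 PTSD-symptom items, 0–4, summed), and the
   Silencing the Self Scale (31 items, 1–5, summed; four subscales) are
   aggregated into node variables, together with a composite risk count in
   0–3 (low antiretroviral adherence strictly below 80%, detectable viral
   load in the past year, a missed HIV-care visit in the past year).
2. **Mixed-type correlation** (`mixed_correlation_matrix()`): Pearson
   correlations for continuous pairs, polychoric for ordinal pairs,
   polyserial for mixed pairs, each on that pair's complete cases
   (pairwise deletion), with positive-definite repair when needed.
3. **Regularized GGM** (`ggm_select()`): graphical lasso along a penalty
   path with extended-BIC model selection at `gamma = 0.5`.
4. **Centrality** (`centrality_table()`): strength, expected influence,
   closeness and betweenness, raw and z-standardized.

The package additionally ships the two published reference networks it
replicates (`load_fixture()`, `replicate_report()`) and a seeded synthetic
survey generator (`sample_survey()`, `recovery_experiment()`) so that the
whole pipeline is testable against a known truth: the raw study data were
never deposited, and all empirical claims the package makes are claims
about what its own code computes.

## Measurement model and the mixed correlation matrix

Scale scores built from handfuls of Likert items are treated as continuous;
the composite risk count, with four integer levels, is not. Feeding a
Pearson matrix of such a mix into a GGM attenuates every edge touching the
ordinal variable. The package therefore estimates each pairwise
correlation under a latent bivariate-normal model:

* An ordinal variable is modelled as a discretized standard normal with
  thresholds `tau_k = qnorm(empirical cumulative proportion)`
  (`estimate_thresholds()`).
* **Polychoric** (ordinal–ordinal): with thresholds fixed at their
  univariate estimates, `rho` maximizes the contingency-table
  log-likelihood whose cell probabilities are bivariate-normal rectangle
  masses. This is the classical two-step estimator — full maximum
  likelihood over thresholds and `rho` jointly buys little at these sample
  sizes and costs stability.
* **Polyserial** (continuous–ordinal): the continuous variable is
  standardized and `rho` maximizes the conditional likelihood of the
  observed categories given the continuous score.
* Both estimators use bounded scalar search on `[-0.999, 0.999]`; bivariate
  normal probabilities come from the angular-integral form (Drezner–
  Wesolowsky) with 64-point Gauss–Legendre quadrature (`pbvnorm()`),
  accurate to well below 1e-7 across the admissible range.

**Level detection.** A variable is auto-classified as ordinal when all its
non-missing values are integers with at most 7 distinct levels — the common
auto-detection convention — and as continuous otherwise. The rule is
deliberately overridable per variable (`variable_spec()`), because sums of
many 0–3 items are integers too and only the level count keeps them on the
continuous side.

**Pairwise deletion.** Each pair's correlation uses exactly the cases
complete for that pair, and each per-pair *n* is recorded. Pairwise
deletion makes the best use of sparse missingness but can produce a matrix
that is not positive definite; when the smallest eigenvalue falls below
1e-6 the matrix is repaired by eigenvalue clipping — eigenvalues floored at
1e-6, reconstruction, rescaling to unit diagonal, iterated until the
smallest eigenvalue reaches 1e-8 (a simplified Higham-style projection).
The repair event and the pre-repair eigenvalue are part of the result, not
silent. Because pairwise deletion leaves the "sample size" ambiguous, the
result carries both the listwise-complete count and the smallest per-pair
count; the EBIC uses the listwise count by default (`n_mode = "complete"`),
the conservative choice, with `"min_pairwise"` available behind the same
switch.

## The graphical lasso and EBIC selection

The precision matrix `K` is estimated by maximizing

```
log det K - trace(S K) - lambda * sum_{i != j} |K_ij|
```

with the diagonal unpenalized, by blockwise coordinate descent: each
column update solves a lasso regression subproblem by coordinate descent
with exact soft-thresholding, so absent edges are exact zeros rather than
small numbers. The penalty path holds `n_lambda = 100` values log-spaced
from `lambda_max` (the largest absolute off-diagonal correlation, above
which the network is empty) down to `lambda_max / 100`
(`lambda_min_ratio = 0.01`) — the defaults of the standard tooling for
psychometric networks. Fits are warm-started along the path.

Each fitted model is scored by the extended Bayesian information
criterion,

```
EBIC = -2 * loglik + |E| * log(n) + 4 * gamma * |E| * log(p)
```

with `|E|` the number of edges. `gamma = 0.5` is the default, the standard
setting for a parsimonious and sensitive psychometric network; `gamma = 0`
recovers ordinary BIC and can only select denser models, an invariant the
tests assert per run. Ties in EBIC are broken toward the larger penalty —
the sparser model — consistent with the parsimony rationale for `gamma =
0.5` in the first place. The selected precision matrix converts to partial
correlations by `r_ij = -K_ij / sqrt(K_ii K_jj)`; magnitudes below 1e-8
are reported as structural zeros.

Numerical choices: the outer loop stops when no entry of the working
covariance estimate moves by more than `convergence_tol` (default 1e-4, on
the correlation scale where all entries are O(1)); the inner lasso loop
uses a tenth of that. For oracle comparisons at `lambda = 0` a tolerance
of 1e-9 is used so that the fit agrees with direct matrix inversion to
1e-6 elementwise. A correlation matrix with no off-diagonal signal
degenerates the path to a single nominal penalty of 1e-3; any value gives
the same diagonal model there.

## Centrality on weighted signed networks

Distances follow the psychometric-network standard: traversing an edge of
weight `w` costs `1/|w|`, so strong conditional associations are short.

* **Strength** `sum_j |w_ij|` and **expected influence** `sum_j w_ij`; the
  latter lets negative edges cancel, so strength always dominates its
  absolute value, with equality exactly when all incident edges share a
  sign.
* **Betweenness**: the fraction of shortest paths between other node
  pairs passing through the node, with fractional credit when several
  paths tie (Brandes' algorithm via igraph). The verbal "frequency"
  definition in the source literature is ambiguous about ties; fractional
  credit is the standard resolution.
* **Closeness**: the inverse of the node's total distance to the nodes it
  can reach. On disconnected networks the sum runs within the node's
  component and the component size is attached to the result, because an
  unreachable node contributes an infinite distance under the literal
  definition; a harmonic variant (`harmonic = TRUE`), which averages
  reciprocal distances and remains comparable across components, is
  exposed as an option. Isolated nodes score 0.

Raw and z-standardized values are always reported side by side: published
centrality figures in this literature mix the two scales, and having both
makes concordance checks unambiguous.

Correctness is anchored by an independent oracle: on every test graph with
at most 8 nodes, betweenness and closeness are compared against exhaustive
enumeration of all simple paths.

## The bundled reference networks and what replicates

`load_fixture("main")` returns the published 7-node partial-correlation
network (depressive symptoms, PTSD symptoms, self-silencing total,
composite risk, and the three support sources); `"posthoc"` returns the
10-node variant with the self-silencing total replaced by its four
subscales. Printed absent edges are structural zeros. Where the source's
running text and its tables disagree on an edge weight (four such
conflicts, e.g. a family–risk weight printed as −.013 in text but −0.132
in the table), the tables are taken as authoritative.

`replicate_report("main")` recomputes all four centrality indices on the
fixture and compares them with the in-text claims. Two reproduce exactly:
the depressive node's raw strength (1.02) and expected influence (0.78) at
two decimals. The remaining printed values — betweenness of 4/5/5/1,
closeness of 0.22/0.18, and the composite-risk strength 0.31 — do not
follow from the printed matrix under any standard convention we
implemented (raw or z-scaled, 1/|w| distances, fractional tie credit,
within-component closeness), and the printed "highest strength" for the
depressive node conflicts with the friend node's recomputed strength of
1.088. The report flags these as *documented discrepancies*: the package
reproduces what is reproducible and refuses to tune conventions until the
rest matches.

## The synthetic generator: what it emulates, and what it does not

`sample_survey()` draws latent node scores from `N(0, Sigma)` where
`Sigma` is implied by a known sparse partial-correlation truth
(`true_network()` builds `K = I - P`, shrinking `P` toward zero by a
factor just below 1 in the rare case that `K` is not positive definite —
the bundled main network needs no shrinkage, its smallest eigenvalue being
0.161). Each scale node is expanded into its items by a one-factor
congeneric model (`item latent = 0.7 x node score + unique noise`) and
discretized at equally spaced normal quantiles; the loading of 0.7 gives
internal consistencies in the high-0.8s/low-0.9s for the longer scales,
the realistic range for these instruments, and is configurable. The
composite-risk node becomes three binary indicators (each loading 0.7 on
the risk latent) with marginal prevalences of 0.22 apiece, chosen so the
composite's distribution is concentrated at 0–1 with a thin tail at 3,
mimicking the scale of the published count distribution (57/40/12/3 across
scores 0–3 in a sample of 112); the first indicator is emitted as a
continuous adherence proportion calibrated so that `adherence < 0.80`
coincides with the indicator. Defaults `n = 119` respondents and, for
missingness experiments, a completely-at-random cell rate (with an
optional depression-dependent mode to stress pairwise deletion) emulate
the study scale, where row-level missingness reduced 119 respondents to
about 104 analyzable ones.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: item-level structure beyond a single
factor per scale (no correlated residuals, no reverse-keyed wording
effects), informative missingness beyond the simple MAR option, floor and
ceiling effects from skewed symptom distributions, and sampling from an
actual finite population. Recovery results on synthetic data are evidence
that the *estimator* works under its own assumptions, not that any
particular substantive network is true.

Benchmarks run by the test suite and `scripts/acceptance.R` (problem sizes
chosen to make Monte Carlo noise small relative to the tolerances while
keeping a full run in tens of seconds): under an empty 7-node truth at
`n = 1000` over 20 replicates the per-edge false-positive rate stays below
0.05 (EBIC at `gamma = 0.5` is strongly conservative, typically below
0.01); with the bundled main network as truth and `n = 2000` continuous
observations over 20 replicates, the mean absolute error on true-edge
weights stays below 0.07 and every true edge with `|r| >= 0.25` is
detected in at least 90% of replicates; polychoric and polyserial recover
latent correlations of 0.5 and 0.4 within 0.05 at `n = 5000`.

## Design decisions that were genuinely open

* **Proration.** The published observed self-silencing range (12–137)
  falls below the instrument's theoretical minimum of 31, implying some
  partial scoring whose exact rule is unstated. The package prorates:
  sum-aggregated scores are (mean of answered items) x (item count),
  issued only when at least `min_prop_answered = 0.75` of the items are
  answered. The threshold applies to mean-aggregated scales too — a score
  built from one answered item out of four is not credible under either
  aggregation — and is configurable per scale.
* **Missing risk criteria** contribute 0 to the composite and are flagged,
  rather than dropping the respondent; only a respondent missing all three
  criteria is unscorable. This mirrors the published accounting, where
  7 respondents lack the composite but partial criteria still count.
* **Adherence cutoff** is strictly below 80%: exactly 80% scores 0 on that
  criterion, as printed.
* **Two-step, not full-ML**, polychoric/polyserial estimation (see above).
* **Effective n for the EBIC** under pairwise deletion defaults to the
  listwise-complete count — penalizing as if the information were the
  smaller sample is the conservative direction — with the minimum per-pair
  count behind a switch, and both reported.
* **No reverse-coded items** are assumed for any instrument, and continuous
  node variables enter the correlation stage untransformed.

## Known limitations

* The latent-Gaussian route covers ordinal and continuous variables; there
  is no nonparanormal transform and no mixed graphical model for genuinely
  categorical (unordered) variables.
* No bootstrap edge-stability or centrality-stability intervals: the
  package replicates and validates point estimation, and the study design
  it mirrors performed no stability analysis.
* Network layout and visualization are out of scope; exports (adjacency
  CSV, edge list, JSON fit report) are designed to feed standard graph
  tooling instead.
* At the study's scale (about 100 complete cases, 7 nodes), EBIC at
  `gamma = 0.5` is conservative: weak true edges (|partial| below roughly
  0.1) are routinely shrunk to zero. That is the intended operating point
  of the published analysis, not a defect, but users should not read
  absent weak edges as evidence of conditional independence.
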