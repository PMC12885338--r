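---
title: "Models and methods behind panelnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind panelnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(panelnet)
```

panelnet estimates symptom networks from multi-wave panel data: undirected
partial-correlation networks within waves, a directed cross-lagged network
between waves, and the resampling diagnostics that qualify both. This
vignette explains the models, the tunable constants and their defaults,
the numerical conventions, and what the synthetic-data validation does and
does not establish.

## Cross-sectional model

Within a wave, the nine domain totals of the complete cases are
mean-centred and summarized by their Pearson correlation matrix $S$ and
sample size $n$. The Gaussian graphical model assumes the scores are
multivariate normal; conditional-independence structure lives in the
precision matrix $K$, estimated by the graphical lasso

$$\hat K(\lambda) = \arg\max_K \; \log\det K - \mathrm{tr}(SK)
  - \lambda \sum_{i \ne j} |K_{ij}|,$$

with no penalty on the diagonal. Edges are partial correlations
$w_{ij} = -K_{ij}/\sqrt{K_{ii}K_{jj}}$. The penalty is chosen by the
extended Bayesian information criterion,

$$\mathrm{EBIC}(\lambda) = -2L + E\log n + 4\gamma E \log P,$$

where $L = (n/2)(\log\det K - \mathrm{tr}(SK))$ is the penalized-fit
log-likelihood, $E$ the number of nonzero upper-triangle edges, $P = 9$
the node count. Defaults: $\gamma = 0.5$ (the conservative standard for
this estimator), a 100-point logarithmic grid from
$\lambda_{\max} = \max_{i<j}|S_{ij}|$ down to $0.01\,\lambda_{\max}$. Ties
in the EBIC go to the larger penalty, i.e. the sparser model.

Pearson correlations (not covariances, not polychorics) are the input
moments: domain totals are quasi-continuous sums of many items, and the
correlation scale makes $\lambda$ comparable across waves. Estimation is
complete-case per wave; missingness is handled separately by the
sensitivity stage.

### Solver

The solver is block coordinate descent over columns (each column update is
a lasso sub-problem solved by cyclic coordinate descent), implemented in
compiled code because the permutation and bootstrap stages call it tens of
thousands of times. Convergence is declared when the mean absolute change
of the working covariance per sweep falls below `tol` (default `1e-4`)
relative to the mean absolute off-diagonal of $S$, within `max_iter = 200`
sweeps; non-convergence is an error carrying the final change. At
$\lambda = 0$ the algorithm reproduces the matrix inverse of $S$, which is
the oracle used in the tests (agreement to `1e-6` with `tol = 1e-9`).

Two boundary conventions matter. The top of the penalty grid is pinned to
$\lambda_{\max}$ *exactly* (not through `exp(log(·))`, which lands one ulp
below), so the empty network is always among the candidate fits.
Coefficients whose magnitude is at rounding scale (below $10^{-10}$
relative to the diagonal) are floored to zero for $\lambda > 0$: the soft
threshold only produces such values through floating-point noise at grid
boundaries, never as genuine support. Without the floor, a ghost edge of
magnitude $10^{-17}$ can displace the empty model and the selector loses
exact sparsistency under independent data.

The solution path's edge count is non-increasing in $\lambda$ for edges of
meaningful magnitude; support flips of coefficients at the solver's
tolerance scale (~$10^{-5}$) can occur deep in the path, which is why the
monotonicity test counts edges above a small floor.

## Centrality

Strength $s_i = \sum_j |w_{ij}|$ and expected influence
$ei_i = \sum_j w_{ij}$, so $s_i \ge |ei_i|$ with equality when all
incident edges share a sign. Closeness and betweenness use shortest paths
over edge lengths $1/|w_{ij}|$ (absent edges are non-adjacent): closeness
is $1/\sum_{j\ne i} d(i,j)$ and betweenness sums $\sigma_{st}(i)/
\sigma_{st}$ over unordered pairs, with exact path counting.

Conventions the literature leaves open, fixed here and tested:

* Closeness uses the un-normalized form $1/\Sigma d$ rather than
  $(N-1)/\Sigma d$ — rankings and z-scores, which are what gets reported,
  are identical under either scaling.
* A node with any unreachable partner has closeness 0; pairs with no
  connecting path contribute 0 to betweenness.
* Shortest-path ties are detected at relative tolerance $10^{-10}$ so
  that path counts are deterministic under floating point.
* Negative edges enter distances by absolute value, consistent with the
  distance definition above.

z-scores use the $N-1$ denominator; a constant index maps to all-zero
z-scores rather than `NaN`.

## Invariance tests between waves

Two permutation statistics compare waves A and B: the maximum absolute
edge difference $M = \max_{ij}|w^A_{ij} - w^B_{ij}|$ and the global
strength difference $\mathcal S = |\,\Sigma|w^A| - \Sigma|w^B|\,|$ over
the upper triangle. Rows are pooled and reassigned to groups of the
original sizes; both networks are re-estimated per permutation with the
same EBIC settings; p-values use the add-one estimator
$(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$, so $p = 0$ is
impossible and the resolution is $1/(B+1)$. Defaults: 1,000 permutations
in production. The three pairwise wave comparisons are Bonferroni-adjusted
with family size 3.

The permutation scheme treats the waves as independent groups even though
panel waves share participants. A paired scheme would require complete
cases across both waves and a different null; the independent-group form
is the standard usage of this test, and every result object carries an
explicit caveat flag.

## Cross-lagged panel network

For each outcome symptom $Y$ at wave $t$, a linear LASSO regression on all
nine symptoms at $t-1$ plus the four covariates. Implementation choices:

* **Covariates are penalty-free** (zero penalty factor), so adjustment is
  unconditional — "controlling for" covariates, not selecting them.
* **Predictors are standardized internally** for the penalty and
  coefficients are returned on the centred-score scale.
* **Penalty selection**: ten-fold cross-validation of the Gaussian
  deviance; $\lambda_{1se}$, the largest grid value within one standard
  error of the CV minimum, favouring parsimony. By construction
  $\lambda_{1se} \ge \lambda_{\min}$, and forcing $\lambda_{\min}$ never
  yields fewer nonzero coefficients — both are asserted in tests.
* **Common sample**: complete cases over the wave pair, shared by all nine
  regressions, so a single $n$ describes each interval.
* **Reproducibility**: per-outcome fold seeds derive from the master seed
  by outcome index, and fold assignment keys to sorted participant IDs, so
  the fitted matrix is invariant to input row order.
* **No significance filter**: the network is the selected coefficient
  matrix itself; bootstrap intervals qualify edges afterwards.

The coordinate-descent LASSO and CV machinery come from glmnet, the
standard solver for this regression family; the package contributes the
design construction, seeding discipline, and network assembly around it.

In- and out-expected influence are column and row sums of the coefficient
matrix excluding the autoregressive diagonal, z-scored across the nine
nodes within the network.

## Bootstrap diagnostics

Edge accuracy uses an n-out-of-n case bootstrap (default $B = 1000$;
replicates that fail estimation are dropped, counted, and flagged above a
5% failure rate) with percentile intervals — simpler than BCa and exactly
reproducible from the stored replicates. Difference tests declare a pair
distinct when the percentile interval of the bootstrap difference
distribution excludes zero.

Centrality stability uses the case-dropping subset bootstrap: for each
drop proportion $p$ in a grid (default 0.05–0.75 in steps of 0.05, 100
subsamples per level), subsamples of size $(1-p)n$ are re-estimated and
their centrality correlated (Pearson, across the nine nodes) with the
full-sample values. The CS coefficient is the largest *tested* proportion
at which at least 95% of subsamples correlate ≥ 0.70 — reported on the
grid, never interpolated, because the procedure has no finer resolution.
Bands: > 0.50 excellent, 0.25–0.50 moderate, < 0.25 insufficient.

Two degenerate conventions: an estimation failure marks the subsample
infeasible (a level where most subsamples fail is excluded from the CS
search), while an *undefined* correlation — a constant centrality vector,
e.g. from an empty subsample network against a non-constant full-sample
vector — counts against the 0.70 criterion. Identical vectors count as
correlation 1 even when constant, so a perfectly stable degenerate
estimator attains the grid ceiling rather than `NaN`.

## Multiple-imputation sensitivity

Missing symptom cells are imputed by chained equations in a wide layout
(all waves' symptom columns jointly plus covariates, preserving the
cross-wave dependence the CLPN needs), with predictive mean matching
(donor pool 5, 10 iterations, default $m = 20$ streams from derived
seeds). PMM keeps imputed values inside the observed range, which suits
bounded questionnaire totals. Observed cells are never altered — asserted
bit-exactly — and a column more than 80% missing is refused.

Pooling across the $m$ completed analyses offers two modes:

* `estimates` (default): entrywise mean of the edge and coefficient
  matrices — the point-estimate part of Rubin's rules.
* `moments`: mean of the per-dataset correlation matrices, followed by a
  single EBIC-selected fit on the pooled moments.

The modes answer slightly different questions. Estimate pooling is the
conventional MI point estimate, but the pooled matrix is dense: an edge
selected in any one dataset contributes, so exact zeros survive only if
absent in all $m$ fits. That breaks rank comparisons against sparse
single-dataset fits, where the tied block of exact zeros dominates a
Spearman correlation. When the pooled network is to be *compared* with a
complete-case fit — the package's mask-and-recover validation, and the
agreement reporting itself — the `moments` mode produces a comparable
sparse object and is the mode the validation uses. Agreement is reported
as Spearman rank correlations over nodes (each centrality index), the 36
upper-triangle edges, and the 81 directed coefficients, with mid-ranked
ties and `NA` for constant vectors.

## The synthetic-data generator

`make_ground_truth()` parameterizes a data-generating process whose
estimands are known exactly: a contemporaneous precision matrix built by
placing each requested partial correlation $\rho$ as $-\rho$ in a
unit-diagonal matrix (plus the minimal ridge lifting the smallest
eigenvalue to 0.05 — the implied partials are recomputed and stored, and
equal the request exactly whenever no ridge is needed), a VAR(1)
transition matrix (spectral radius checked < 1), covariate effects, and
logistic dropout whose log-odds are linear in the baseline depression
score.

`default_ground_truth()` encodes the study conditions the package is
validated under: strongest contemporaneous pairs between the two
suicidality domains, the two anxiety domains and the two sleepiness
domains plus a web of moderate edges (partials 0.15–0.40); dominant
cross-lagged paths from active sleepiness to somatic symptoms (0.40) and
depression (0.35) and between the suicidality domains (0.40/0.20);
autoregression 0.3; and dropout intercepts (−0.95, −0.45) with slope 0.30
on baseline depression, calibrated so a 650-participant baseline retains
roughly 460 and 280 participants at the follow-ups with completers less
severe than dropouts. Covariates are drawn as age ~ U(15, 24), gender ~
Bernoulli(0.5), education uniform on {1..4}, illness duration ~
exponential with mean 2.2 years, with zero effects unless configured.
`hub_ground_truth()` is a strongly structured variant (pronounced hubs,
wide strength range) used for stability benchmarking, where heterogeneity
across nodes is what a correlation-stability analysis measures.

One property of the dropout mechanism deserves note: with the logit
linear in a zero-mean score, raising the severity slope increases the
*expected* dropout rate only where the logistic is convex (per-wave
dropout well below one half). Near a 50% rate the slope redistributes
dropout across severity without changing its level. The monotonicity
property test therefore exercises the convex regime (intercept −2), which
is also the empirically relevant one.

Scores are continuous and zero-mean — the analysis mean-centres totals
and treats them as continuous, so integer questionnaire totals, floor
effects, and item-level structure are deliberately not emulated. Missing
data from the generator are monotone (dropout), though the readers accept
arbitrary patterns. Passing the simulation suite therefore shows the
estimators recover the *kind* of structure these cohorts exhibit at these
sample sizes; it does not certify behaviour under ordinal floors,
non-monotone missingness, or measurement non-invariance across waves.

## Validation design and problem sizes

Every operation is tested against an independent oracle where one exists:
matrix inversion for the unpenalized graphical lasso, exhaustive
simple-path enumeration (networks of up to 7 nodes) for closeness,
betweenness and path counts, brute-force sums for the influence indices,
and rank-then-Pearson for the Spearman reporting. Statistical guarantees
are checked by simulation at sizes chosen to keep the full suite
comfortably within a desktop run: EBIC sparsistency at $n = 2000$ over 20
seeds; null calibration of the structure test with two groups of 150 over
200 replications of 100 permutations; cross-lagged path recovery at
$n = 500$ over 50 seeds; bootstrap interval coverage at $n = 650$,
$B = 200$, 20 replications; correlation-stability behaviour at $n = 600$
versus $n = 60$ with 50 subsamples per level over 10 seeds; and the
mask-and-recover imputation comparison at $n = 650$ with 20% follow-up
deletion over 10 replications. The imputation comparison simulates the
scenario sensitivity analysis exists for: deletion concentrated in the
high-severity tail (logit slope 10 on mean baseline severity) of a
high-stability cohort (autoregression 0.85, residual scale 0.28), where
complete-case analysis is genuinely biased and the imputation model has
the cross-wave signal it needs.

## Known limitations

* Gaussian, complete-case cross-sectional estimation: no polychoric
  moments, no FIML, no mixed graphical models.
* The invariance tests permute overlapping waves as independent groups
  (flagged in every result).
* The CLPN is a two-wave lag-1 model per interval: no random effects, no
  latent change, no measurement model.
* CS coefficients are grid-valued; a reported 0.35 means "0.35 was the
  largest tested proportion that met the rule", not a continuous
  estimate.
* Rubin's-rules variance pooling is out of scope; the sensitivity stage
  compares point estimates only.
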