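# panelnet

Longitudinal symptom-network analysis for multi-wave clinical panels:
cross-sectional Gaussian graphical models, cross-lagged panel networks, and
the stability toolkit around them.

## The problem

Psychopathology research increasingly models disorders as *networks* of
interacting symptoms rather than expressions of a single latent severity.
For a cohort measured on a set of symptom domains at several waves (for
example, depressed adolescents assessed at admission and at one- and
three-month follow-ups on nine domains spanning depression, somatic and
subjective anxiety, insomnia, hypersomnolence and suicidality), two
complementary questions arise:

1. **Structure** — which symptoms are conditionally associated *within* a
   wave, and which are most central to the network?
2. **Dynamics** — which symptoms *predict* which others across waves, over
   and above every symptom's own continuity?

panelnet implements the complete analysis pipeline for both questions,
together with the diagnostics that decide whether the answers can be
trusted, and a synthetic-panel generator with known ground truth so that
every stage can be validated by simulation.

## Methods at a glance

**Cross-sectional networks.** Within each wave, domain totals are
mean-centred and the Gaussian graphical model is estimated by the
graphical lasso: the precision matrix K maximizes

    log det K − tr(S K) − λ Σᵢ≠ⱼ |Kᵢⱼ|

over a descending λ grid, and λ is selected by the extended Bayesian
information criterion, EBIC = −2L + E log n + 4γ E log P, with E the edge
count and γ = 0.5 by default. Edges are partial correlations
wᵢⱼ = −Kᵢⱼ/√(Kᵢᵢ Kⱼⱼ).

**Centrality.** Four weighted node indices, reported raw and z-scored:
strength Σⱼ|wᵢⱼ|; expected influence Σⱼ wᵢⱼ; closeness 1/Σⱼ d(i,j) with
shortest-path distances over edge lengths 1/|wᵢⱼ|; and betweenness
Σ σₛₜ(i)/σₛₜ with exact shortest-path counting.

**Invariance between waves.** Permutation tests of the maximum edge
difference (network structure) and of total absolute connectivity (global
strength), with Bonferroni adjustment over the wave pairs.

**Cross-lagged panel network (CLPN).** For each symptom at wave t, a LASSO
regression on all nine symptoms at wave t−1 plus covariates (age, gender,
education, illness duration; unpenalized), with the penalty chosen by
ten-fold cross-validation under the one-standard-error rule (λ.1se). The
nine regressions assemble a directed 9×9 coefficient matrix —
autoregressive effects on the diagonal, cross-lagged effects off it — from
which in- and out-expected influence are computed.

**Robustness.** Nonparametric bootstrap (case resampling) for edge
confidence intervals and difference tests; case-dropping subset bootstrap
for the correlation-stability (CS) coefficient — the largest proportion of
participants that can be dropped while subsample centrality still
correlates ≥ 0.70 with the full sample in ≥ 95% of subsamples (> 0.50
"excellent", 0.25–0.50 "moderate"); and a multiple-imputation sensitivity
harness (chained equations with predictive mean matching) that re-runs the
entire pipeline on m completed datasets and reports Spearman agreement
with the complete-case results.

## Worked example

```r
library(panelnet)

truth <- default_ground_truth(seed = 2026)        # known 9-node structure
panel <- simulate_panel(truth, n0 = 650, waves = 3, seed = 2026)
panel
#> panel_data: 650 participants, 3 waves (T0, T1, T2), 9 symptom domains
#>   T0: 650 complete cases of 650 rows
#>   T1: 464 complete cases of 650 rows
#>   T2: 273 complete cases of 650 rows

fit_wave_ggm(panel, "T0")
#> ggm_fit: 9 nodes, 15/36 edges (41.7%), lambda = 0.03593 (gamma = 0.5, n = 650)
#>   SOM--ANX: 0.389
#>   SuI--SuT: 0.350
#>   Pas--AcS: 0.338

fit_clpn(panel, "T0", "T1", seed = 2026)
#> clpn_fit T0 -> T1: n = 464, 5/72 nonzero cross-lagged paths
#>   SuI -> SuT: B = 0.243
#>   AcS -> DEP: B = 0.163
#>   AcS -> SOM: B = 0.149

s <- center_within_wave(panel, "T0")$scores
case_dropping_cs(s, ggm_boot_estimator(), n_subsamples = 50, seed = 2026)
#> case-dropping stability (50 subsamples/level, pearson correlation)
#>   CS(betweenness) = 0.20 [insufficient]
#>   CS(closeness) = 0.45 [moderate]
#>   CS(expected_influence) = 0.45 [moderate]
#>   CS(strength) = 0.35 [moderate]
```

The simulated cohort retains 650/464/273 participants across waves, with
dropout probability increasing in baseline depression, so completers are
systematically less severe — the attrition pattern the multiple-imputation
stage is designed to probe. The baseline network recovers the generating
structure (strongest edges between the suicidality pair, the anxiety pair
and the sleepiness pair), and the cross-lagged fit isolates the generating
paths (active sleepiness driving later somatic symptoms and depression;
suicidal ideation driving later suicide tendency) among the 72 candidate
directed edges. Betweenness is the least droppable index — its CS
coefficient falls below the 0.25 band — which is the expected behaviour for
path-count-based indices at this sample size.

`run_full_pipeline(analysis_config(...), panel)` chains every stage
(per-wave networks and centralities, pairwise invariance tests, CLPNs,
bootstrap CIs, CS reports, and the imputation sensitivity stage when
missing cells are present) and writes JSON/CSV artifacts with a manifest
carrying the configuration hash and master seed. A thin command-line
wrapper lives at `inst/cli/panelnet.R` (`simulate` and `run-all`
subcommands).

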