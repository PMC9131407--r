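# vptbias

Analysis and simulation toolkit for **spontaneous visual perspective-taking
experiments** built on the rotated-character (mental rotation) paradigm.

In this paradigm a participant reports, as fast as possible, whether an
alphanumeric character shown at one of eight orientations θ ∈ {0°, 45°, …,
315°} is canonical or mirror-inverted, while another person is sometimes
seated to the left (azimuth 90°) or right (azimuth 270°) of the character,
and the participant's movement is either free or restricted by a chinrest.
Recognition time grows linearly with the character's angular disparity to a
viewpoint, so the working model is

```
E[RT] = γ + β_self · d(θ, 0) + β_other · d(θ, φ) · 1[person present]
          + δ_move · 1[restricted]
```

with `d(θ, φ)` the minimal rotation (0–180°) between the character and a
viewpoint's upright, and the two disparity predictors exactly orthogonal
over the 16 person-present design cells. The package implements, as tested
and reusable components:

* **design geometry** — the 4 × 144 factorial session, angular disparities,
  viewpoint azimuths (`enumerate_design()`, `angular_disparity()`);
* **synthetic cohorts** — trial-level RT/accuracy simulation with an
  ex-Gaussian noise model, lapse participants, and questionnaire scores
  generated through a Gaussian copula tied to the true perspective-taking
  propensity (`cohort_config()`, `simulate_cohort()`);
* **preprocessing** — the trial trimming (correct, 150–2000 ms) and
  participant exclusion (error > 20%) rules (`filter_trials()`,
  `exclude_participants()`);
* **bias statistics** — the towards/away (−cos) and left/right (−sin)
  vector projections of per-orientation RT or error profiles and the
  perspective-taking score `lr(left) − lr(right)`
  (`bias_summaries()`, `perspective_scores()`);
* **rotation regressions** — per-participant dual-viewpoint OLS on the 16
  cell means and its group summary (`fit_dual_viewpoint()`,
  `summarise_fits()`);
* **inference** — repeated-measures ANOVA with Greenhouse–Geisser
  correction, JZS and Jeffreys Bayes factors by quadrature, power
  inversions on the noncentral t (`rm_anova()`, `jzs_bf_ttest()`,
  `min_detectable_d()`);
* **individual differences** — AQ/IRI/STQ-STA scoring, trait correlations
  and hierarchical regression (`score_aq()`, `trait_correlations()`,
  `hierarchical_regression()`);
* **pipeline** — `run_simulate()` and `run_analyze()` orchestrate
  everything and write CSV/JSON bundles; `scripts/pipeline.R` is a thin
  command-line wrapper.

## Worked example

```r
library(vptbias)

config <- cohort_config(seed = 2026)   # reference study conditions
sim <- simulate_cohort(config)          # 79 participants x 576 trials
results <- run_analyze(sim$trials, sim$questionnaires)

results$mental_rotation$overall_towards_away
#>       n  mean    sd statistic    df        p     d    bf10
#>      61  55.8  21.8      20.0    60 3.61e-28  2.55 8.80e24

results$rotation$summary[, c("scope","term","n","mean","sd","statistic","p")]
#>   scope      term           n  mean    sd statistic        p
#> 1 all        beta_other    61 0.400 0.386      8.10 3.28e-11
#> 2 all        beta_self     61 1.46  0.578     19.8  6.02e-28
#> 3 free       beta_other    61 0.381 0.405      7.35 6.30e-10
#> 4 free       beta_self     61 1.47  0.581     19.7  6.62e-28
#> 5 restricted beta_other    61 0.420 0.399      8.24 1.93e-11
#> 6 restricted beta_self     61 1.46  0.597     19.1  3.51e-27

results$perspective$tests
#>   movement       n  mean    sd statistic    df        p     d      bf10
#> 1 all           61  30.6  29.4      8.14    60 2.82e-11 1.04  3.34e+08
#> 2 free          61  29.1  30.9      7.35    60 6.35e-10 0.941 1.69e+07
#> 3 restricted    61  32.2  30.3      8.30    60 1.54e-11 1.06  5.98e+08
```

Reading this: 18 of the 79 recruited synthetic participants exceed the 20%
error threshold, leaving 61. Their mean towards/away bias (55.8 ms here) is
the mental rotation effect as a cosine projection; its generative
expectation is `projection_constant() * 1.39 = 53.4` ms. The dual-viewpoint
regression recovers both generating slopes (1.39 and 0.38 ms/deg) in every
movement scope, and the perspective-taking score — how much the left/right
recognition advantage follows the seated person — is positive and of
similar size whether or not movement is restricted. The
individual-differences table shows the copula-encoded structure: a positive
age correlation, a negative schizotypy correlation, and null AQ/IRI
correlations.

A command-line session of the same thing:

```sh
Rscript scripts/pipeline.R simulate --seed 2026 --out sim/
Rscript scripts/pipeline.R analyze --trials sim/trials.csv \
  --questionnaires sim/questionnaires.csv --out results/
```

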