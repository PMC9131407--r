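---
title: "Modelling and analysing spontaneous visual perspective taking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing spontaneous visual perspective taking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vptbias)
library(dplyr)
```

## The paradigm and its measurement model

In the rotated-character paradigm, a participant judges as quickly as
possible whether an alphanumeric character ("4", "P" or "R") shown on a
table is in its canonical or mirror-inverted form. The character appears at
one of eight orientations $\theta \in \{0°, 45°, \dots, 315°\}$, where $0°$
is upright for the participant and angles grow counter-clockwise. On
two-thirds of trials another person sits at the table, to the left or right
of the character, viewing it from an azimuth of $90°$ or $270°$. Half of the
four 144-trial blocks are completed with the participant's head fixed in a
chinrest (movement restricted), in an alternating ABAB/BABA order.

Recognition time (RT) grows with the smallest rotation needed to bring the
character upright — the classic mental rotation effect — and, when a person
is present, also with the character's rotation away from *that person's*
upright. The package's generative and analysis model is therefore linear in
the two angular disparities:

$$
\mathrm{E}[RT] \;=\; \gamma \;+\; \beta_{\text{self}}\, d(\theta, 0°)
\;+\; \beta_{\text{other}}\, d(\theta, \phi)\,\mathbb{1}[\text{person}]
\;+\; \delta_{\text{move}}\,\mathbb{1}[\text{restricted}],
$$

where $d(\theta,\phi) = \min(|\theta-\phi| \bmod 360, 360 - |\theta-\phi|
\bmod 360) \in [0°, 180°]$ and $\phi$ is the seated person's azimuth.
Because the two seats are perpendicular to the participant's line of sight,
$d(\theta,0)$ and $d(\theta,\phi)$ are *exactly* orthogonal over the 16
design cells (8 orientations × 2 seats), so the two slopes are estimable
independently. All angles are kept in degrees, so slopes are in
ms/degree — the scale on which group means around 1.4 (self) and 0.4
(other) ms/deg are conventionally reported.

## The two projection statistics

Per participant and condition, the eight per-orientation mean RTs
$v(\theta)$ are summarised by two orthogonal projections:

* **towards/away bias** $= \frac{1}{8}\sum_\theta v(\theta)\,(-\cos\theta)$:
  positive when away-facing characters are recognised more slowly — the
  mental rotation effect as a single number;
* **left/right bias** $= -\frac{1}{8}\sum_\theta v(\theta)\,\sin\theta$:
  positive when left-facing characters (upright for a person seated on the
  left) are recognised faster.

For a profile exactly linear in a disparity with slope $b$, either
projection equals $b \times 38.40990$ ms (the projection constant
`projection_constant()`, i.e. $\frac{1}{8}\sum_\theta d(\theta,0)
(-\cos\theta)$). The **perspective-taking score** is the left/right bias
with the person on the left minus with the person on the right; under the
linear model its expectation is $2 \times 38.41 \times \beta_{\text{other}}$
(about 29.2 ms at $\beta_{\text{other}} = 0.38$).

Two sign conventions are possible for the sine projection, depending on
whether "positive" is tied to left-facing or right-facing characters; they
differ only by a global sign that cancels in the perspective-taking score.
This package fixes the sign so that a person seated on the *left* pushes
the bias *positive*, which keeps the score positive when perspective taking
occurs in the expected direction.

```{r constant}
projection_constant()
```

## Preprocessing rules

Two streams are derived from the raw trials. The RT stream keeps correct
responses with 150 ms ≤ RT ≤ 2000 ms (boundaries inclusive; trials strictly
shorter/longer are removed). The error stream keeps every responded trial.
Participants whose overall raw error rate strictly exceeds 20% are excluded
before either stream is built. Orientation-profile cells left empty by the
exclusions flag the profile incomplete; incomplete profiles are skipped and
logged, never imputed — the balanced design makes this rare. Pooled
("all"-movement) biases are the mean of the two movement-condition biases
rather than a recomputation from pooled trials, which keeps them balanced
when the conditions retain different trial counts.

## The synthetic cohort generator

The paradigm's raw data are not redistributable, so the package ships a
generator whose defaults encode the reference study conditions:

| parameter | default | rationale |
|---|---|---|
| recruited / lapse | 79 / 18 | the exclusion rule then retains about 61 |
| trials | 4 × 144 | full factorial, twice per movement condition |
| $\beta_{\text{self}}$ | mean 1.39, SD 0.566 ms/deg | SD = mean·√61/t from the group t of 19.181 |
| $\beta_{\text{other}}$ | mean 0.38, SD 0.412 ms/deg | SD from the group t of 7.209 |
| $\gamma$ | mean 750, SD 80 ms | a typical young-adult baseline; not constrained by the reference results |
| $\delta_{\text{move}}$ | mean 15, SD 10 ms | small nonzero shift so the movement factor is exercised |
| trial noise | ex-Gaussian, $\sigma$ = 60, $\tau$ = 100 ms | standard RT noise family; scales chosen so the towards/away-bias SD lands near the reference 22 ms |
| errors | Bernoulli(0.08), independent of RT | error biases are then null, as the reference error analyses are |
| lapse errors | uniform(0.21, 0.40) | strictly above the 20% exclusion threshold |
| response window | 150–3500 ms | truncation floor and response deadline |

Simulated RTs are the linear predictor plus ex-Gaussian noise, truncated
below at 150 ms and censored at the 3500 ms deadline. With the default
means the censoring probability is negligible, so slope recovery is
unbiased. Since a lapse participant's *empirical* error rate over 576
Bernoulli trials can occasionally dip below the threshold, the retained
count fluctuates slightly above 61 depending on the seed; the analysis
stages simply use whoever survives the rule.

Questionnaire scores are generated through a Gaussian copula anchored on
each participant's *true* $\beta_{\text{other}}$ — the generative
perspective-taking propensity. Latent normals with configured correlations
(age +.38, STQ-STA −.26, AQ and IRI 0) are mapped through monotone quantile
transforms to the marginals: age as a discretised young-skewed gamma on
18–35 (mean ≈ 20.5), AQ and IRI as rounded truncated normals (16.64 ± 6.29
and 68.45 ± 11.34), STQ-STA as a binomial over its 37 items. Each latent
correlation is divided by the map's attenuation factor (computed by
deterministic numerical integration), so the *linear* correlation between
the trait and the true propensity hits the target. Correlations with the
*estimated* perspective-taking score are still attenuated by estimation
noise — exactly as in real data — and that attenuation is measured by the
tests, not assumed away. Totals are decomposed into item-level responses
(a rounding allocation across the 50 AQ, 28 IRI and 37 STQ items) and then
re-scored with the package's scoring functions, so the scoring path is
exercised end to end. Three non-lapse participants lack questionnaires by
default, mirroring the reference analysis' 58 complete cases; age, a
demographic, is always recorded.

What the generator deliberately does **not** emulate: sequential and
fatigue effects, speed–accuracy coupling, actor-sex effects, RT
nonlinearity in disparity, and any movement × slope interaction (the
reference study found none). Passing recovery tests therefore shows the
pipeline is correct under the stated model, not that real data obey it —
in particular, real profiles are often slightly nonlinear near 180°, which
is why a simple self-rotation regression on real data can give a steeper
slope (≈1.5) than the dual-fit self slope (≈1.39) while the linear
generator cannot reproduce both at once.

## Inference machinery

* `one_sample_t()` wraps the standard t-test and adds Cohen's
  $d = \bar{x}/s$ and a JZS Bayes factor.
* `rm_anova()` computes the within-subject decomposition through a type-3
  multivariate linear model (`car::Anova`), reporting partial eta squared
  $SS_e/(SS_e + SS_{err})$ and, for factors with three or more levels, the
  Greenhouse–Geisser epsilon and corrected p alongside the uncorrected p
  (the convention in the reference results). ANOVA-level Bayes factors
  (g-prior model averaging) are out of scope and reported as `NA`.
* `jzs_bf_ttest()` integrates the Cauchy-prior (scale $\sqrt{2}/2$, the
  JASP default) alternative against the point null over the implied
  inverse-gamma mixture of g-priors, by quadrature at relative tolerance
  1e-8. `jeffreys_bf_correlation()` integrates the exact sampling density
  of $r$ (hypergeometric form, summed to 1e-13) against a stretched-beta
  prior ($\kappa = 1$, uniform on $(-1,1)$). Both are cross-checked in the
  test suite against Monte-Carlo integration over prior draws.
* `min_detectable_d()` inverts the noncentral-t power function by bisection
  to 1e-6. At $n = 61$, $\alpha = .05$, 80% power this gives $d = 0.32$
  one-tailed and $0.36$ two-tailed; the one-tailed variant is the one that
  reproduces the conventional planning value for this design.
  `min_detectable_r()` uses the Fisher-z closed form, which gives
  $r = 0.352$ two-tailed at $n = 61$ — substantially larger than the .25
  sometimes quoted for this sample size, which no standard method
  reproduces; the package documents its method and makes no attempt to
  match that figure.

## Numerical and design choices

* Degenerate inputs fail loudly: zero-variance t-tests and correlations
  are errors; rank-deficient or incomplete regression designs yield
  flagged `NA` fits with the cell count that caused them.
* `cospi()`/`sinpi()` are used for the projection weights so the right
  angles contribute exact zeros.
* The simple self-rotation regression uses cell-mean RTs (location ×
  orientation), consistent with the dual fit's 16 cell means; under the
  balanced design this is equivalent to trial-level regression but more
  robust after exclusions.
* Ties in bisection and quadrature tolerances are stated in the function
  documentation; all simulation tests fix their seeds and replicate counts
  (500 replicates for calibration checks, which keeps the full suite within
  a few minutes on one CPU — the type-I check simulates 500 null cohorts of
  61 participants × 576 trials).

## A worked run

```{r run}
config <- cohort_config(seed = 2026)
sim <- simulate_cohort(config)
results <- run_analyze(sim$trials, sim$questionnaires)

results$mental_rotation$overall_towards_away
results$rotation$summary |>
  select(scope, term, n, mean, sd, statistic, p, d, bf10)
results$perspective$tests
results$individual_differences$correlations
```

The towards/away bias mean lands near $38.41 \times 1.39 \approx 53$ ms
with an SD near 22 ms; both rotation slopes are recovered near their
generating means in every movement scope; the perspective-taking score is
positive in both movement conditions; and the age correlation is positive
while AQ/IRI hover near zero — the structure the generator encodes.

## Known limitations

* The generator's noise family and baseline are conventions, not estimates;
  only the slope structure, error rates and questionnaire marginals are
  anchored to reference values.
* `rm_anova()` handles fully crossed one- and two-factor within-subject
  designs — the shapes this paradigm needs — not mixed or unbalanced
  designs.
* Bayes factors are provided for t-tests and correlations only.
* The pipeline analyses characters collapsed (no per-character analyses)
  and ignores actor sex, as the reference analyses do.
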