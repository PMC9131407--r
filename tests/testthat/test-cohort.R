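test_that("cohort configuration is validated", {
  expect_error(cohort_config(), "seed")
  expect_error(cohort_config(seed = 1, n_lapse = 100), "n_lapse")
  expect_error(cohort_config(seed = 1, sigma = -1), "SDs")
  expect_error(cohort_config(seed = 1, p_error = 1.2), "p_error")
  expect_error(
    cohort_config(seed = 1, cor_age = 0.9, cor_stq = -0.9), "non-PSD"
  )
  expect_error(
    cohort_config(seed = 1, lapse_error_range = c(0.1, 0.3)), "above 0.20"
  )
  expect_s3_class(cohort_config(seed = 1), "cohort_config")
})

test_that("participant sampling honours the configured distributions", {
  cfg0 <- cohort_config(
    seed = 1, n_recruited = 10, n_lapse = 0, n_missing_questionnaire = 0,
    gamma_sd = 0, beta_self_sd = 0, beta_other_sd = 0, delta_move_sd = 0
  )
  set.seed(1)
  p0 <- sample_participants(cfg0)
  expect_true(all(p0$beta_self == cfg0$beta_self_mean))
  expect_true(all(p0$beta_other == cfg0$beta_other_mean))

  cfg <- cohort_config(seed = 1)
  set.seed(2)
  p <- sample_participants(cfg)
  expect_identical(sum(p$lapse), 18L)
  expect_true(all(p$p_error[p$lapse] > 0.20 & p$p_error[p$lapse] <= 0.40))
  expect_true(all(p$p_error[!p$lapse] == 0.08))

  # law of large numbers on the slope mean
  big <- cohort_config(seed = 1, n_recruited = 10000, n_lapse = 0)
  set.seed(3)
  pb <- sample_participants(big)
  se <- big$beta_self_sd / sqrt(10000)
  expect_lt(abs(mean(pb$beta_self) - big$beta_self_mean), 3 * se)
})

test_that("the linear predictor combines the two disparities and movement", {
  expect_equal(expected_rt(180, "none", "free", gamma = 700, beta_self = 1), 880)
  # theta = 270 seen from the left (azimuth 90): d_self = 90, d_other = 180
  expect_equal(
    expected_rt(270, "left", "free",
      gamma = 700, beta_self = 1, beta_other = 0.5
    ),
    700 + 90 + 90
  )
  # no other-slope: left and right locations are equivalent at every angle
  th <- orientation_angles()
  expect_equal(
    expected_rt(th, "left", "free", 700, 1.2, beta_other = 0),
    expected_rt(th, "right", "free", 700, 1.2, beta_other = 0)
  )
  expect_equal(
    expected_rt(0, "none", "restricted", 700, 1, delta_move = 25), 725
  )
})

test_that("trial simulation respects noise, error and window settings", {
  cfg <- noiseless_config()
  set.seed(4)
  design <- enumerate_design()
  p <- sample_participants(cfg)[1, ]
  sim <- simulate_trials(design, p, cfg)
  expect_true(all(sim$correct))
  expect_equal(
    sim$rt_ms,
    expected_rt(
      sim$orientation_deg, sim$person_location, sim$movement,
      p$gamma, p$beta_self, p$beta_other, p$delta_move
    )
  )
  expect_true(all(sim$response == sim$form))

  # ex-Gaussian residual spread: SD within 10% of sqrt(sigma^2 + tau^2)
  cfgn <- tiny_config(sigma = 60, tau = 100)
  set.seed(5)
  pn <- sample_participants(cfgn)[1, ]
  simn <- simulate_trials(dplyr::bind_rows(rep(list(design), 20)), pn, cfgn)
  mu <- expected_rt(
    simn$orientation_deg, simn$person_location, simn$movement,
    pn$gamma, pn$beta_self, pn$beta_other, pn$delta_move
  )
  resid <- simn$rt_ms - mu
  expect_lt(abs(stats::sd(resid) - sqrt(60^2 + 100^2)) / sqrt(60^2 + 100^2), 0.1)
  expect_true(all(simn$rt_ms >= cfgn$rt_floor & simn$rt_ms <= cfgn$rt_ceiling))
})

test_that("cohort simulation is reproducible and correctly sized", {
  cfg <- tiny_config(seed = 99, n = 3)
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim1$trials, sim2$trials)
  expect_identical(sim1$questionnaires, sim2$questionnaires)
  expect_identical(nrow(sim1$trials), 3L * 576L)
  expect_identical(
    as.vector(table(sim1$trials$participant_id)), rep(576L, 3)
  )
  # distinct seeds: same design multiset per participant, different order
  sim3 <- simulate_cohort(tiny_config(seed = 100, n = 3))
  cols <- c("movement", "person_location", "character", "form", "orientation_deg")
  first <- function(s) s$trials[s$trials$participant_id == "P001", cols]
  expect_false(identical(first(sim1), first(sim3)))
  expect_equal(
    dplyr::arrange(first(sim1), dplyr::across(dplyr::everything())),
    dplyr::arrange(first(sim3), dplyr::across(dplyr::everything()))
  )
})

test_that("questionnaire copula reproduces marginals, ranges and correlations", {
  cfg <- cohort_config(
    seed = 8, n_recruited = 10000, n_lapse = 0, n_missing_questionnaire = 0
  )
  set.seed(cfg$seed)
  parts <- sample_participants(cfg)
  q <- generate_questionnaires(parts, cfg)

  # hard ranges
  expect_true(all(q$aq_total >= 0 & q$aq_total <= 50))
  expect_true(all(q$iri_total >= 0 & q$iri_total <= 112))
  expect_true(all(q$stq_sta >= 0 & q$stq_sta <= 37))
  expect_true(all(q$age >= 18 & q$age <= 35))
  expect_equal(q$iri_total, q$iri_pt + q$iri_ec + q$iri_fs + q$iri_pd)

  # marginal means within 3 SE of the configured targets
  expect_lt(abs(mean(q$aq_total) - cfg$aq_mean), 3 * cfg$aq_sd / 100)
  expect_lt(abs(mean(q$iri_total) - cfg$iri_mean), 3 * cfg$iri_sd / 100)

  # copula correlations with the true perspective-taking propensity
  expect_lt(abs(stats::cor(parts$beta_other, q$age) - cfg$cor_age), 0.03)
  expect_lt(abs(stats::cor(parts$beta_other, q$stq_sta) - cfg$cor_stq), 0.03)
  expect_lt(abs(stats::cor(parts$beta_other, q$aq_total)), 0.03)
  expect_lt(abs(stats::cor(parts$beta_other, q$iri_total)), 0.03)

  # zero-target config: all traits independent of the propensity
  cfg0 <- cohort_config(
    seed = 9, n_recruited = 10000, n_lapse = 0, n_missing_questionnaire = 0,
    cor_age = 0, cor_stq = 0
  )
  set.seed(cfg0$seed)
  parts0 <- sample_participants(cfg0)
  q0 <- generate_questionnaires(parts0, cfg0)
  for (col in c("age", "aq_total", "iri_total", "stq_sta")) {
    expect_lt(abs(stats::cor(parts0$beta_other, q0[[col]])), 0.1)
  }
})

test_that("missing questionnaires hit only non-lapse participants", {
  cfg <- cohort_config(seed = 21)
  set.seed(cfg$seed)
  parts <- sample_participants(cfg)
  q <- generate_questionnaires(parts, cfg)
  missing <- q$participant_id[is.na(q$aq_total)]
  expect_identical(length(missing), 3L)
  expect_true(all(!parts$lapse[parts$participant_id %in% missing]))
  # age (a demographic) is always recorded
  expect_true(all(!is.na(q$age)))
})
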