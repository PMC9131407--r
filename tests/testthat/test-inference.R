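test_that("one-sample t-test reports the hand-computed statistics", {
  res <- one_sample_t(c(1, 2, 3, 4, 5), bf = FALSE)
  # mean 3, sd 1.5811: t = 4.2426, d = 1.897
  expect_equal(res$statistic, 4.242641, tolerance = 1e-6)
  expect_identical(res$df, 4)
  expect_equal(res$d, 1.897367, tolerance = 1e-6)
  # symmetric values about the null: t = 0, p = 1
  sym <- one_sample_t(c(-2, -1, 0, 1, 2), bf = FALSE)
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p, 1)
  # degenerate inputs
  expect_error(one_sample_t(c(3, 3, 3)), "zero standard deviation")
  expect_error(one_sample_t(5), "at least 2")
})

test_that("two-level repeated-measures effects equal squared paired t", {
  set.seed(61)
  n <- 24
  d <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:n), each = 2),
    cond = rep(c("a", "b"), n),
    y = stats::rnorm(2 * n, mean = rep(c(0, 0.4), n))
  )
  res <- rm_anova(d, "y", "cond")
  tt <- stats::t.test(
    d$y[d$cond == "a"], d$y[d$cond == "b"],
    paired = TRUE
  )
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_identical(res$df1, 1)
  expect_identical(res$df2, n - 1)
  # shifting every observation leaves all F unchanged
  d2 <- dplyr::mutate(d, y = y + 100)
  expect_equal(rm_anova(d2, "y", "cond")$statistic, res$statistic)
})

test_that("two-way rm-ANOVA decomposes effects with GG correction", {
  set.seed(62)
  n <- 20
  grid <- tidyr::expand_grid(
    participant_id = sprintf("P%02d", 1:n),
    movement = c("free", "restricted"),
    location = c("none", "left", "right")
  )
  grid$y <- stats::rnorm(nrow(grid)) +
    ifelse(grid$location == "left", 1.5, 0)
  res <- rm_anova(grid, "y", c("movement", "location"))
  expect_identical(
    res$effect, c("movement", "location", "movement:location")
  )
  expect_equal(res$df1, c(1, 2, 2))
  expect_equal(res$df2, c(n - 1, 2 * (n - 1), 2 * (n - 1)))
  # GG epsilon defined only for the 3-level effects
  expect_true(is.na(res$gg_epsilon[1]))
  expect_true(all(!is.na(res$gg_epsilon[2:3])))
  expect_true(all(res$gg_epsilon[2:3] <= 1 + 1e-12))
  # partial eta squared in range, large for the real effect
  expect_true(all(res$pes >= 0 & res$pes <= 1))
  expect_gt(res$pes[2], res$pes[1])
  # missing cell -> incomplete-design error
  expect_error(
    rm_anova(grid[-1, ], "y", c("movement", "location")),
    "incomplete design"
  )
})

test_that("JZS Bayes factor behaves like a default Bayes factor should", {
  # evidence for the null at t = 0
  expect_lt(jzs_bf_ttest(0, 61), 1)
  # strictly increasing in |t|
  bfs <- sapply(c(0, 0.5, 1, 2, 4, 8), jzs_bf_ttest, n = 61)
  expect_true(all(diff(bfs) > 0))
  # consistency: fixed standardized effect, growing n
  ladder <- sapply(c(10, 50, 200, 1000), function(n) {
    jzs_bf_ttest(0.5 * sqrt(n), n)
  })
  expect_true(all(diff(ladder) > 0))
  # quadrature against a Monte-Carlo prior-draw oracle
  set.seed(63)
  delta <- stats::rcauchy(2e5, 0, sqrt(2) / 2)
  for (n in c(10, 61)) {
    for (t in c(0, 2, 4)) {
      mc <- suppressWarnings(
        mean(stats::dt(t, n - 1, ncp = delta * sqrt(n))) / stats::dt(t, n - 1)
      )
      expect_equal(jzs_bf_ttest(t, n), mc, tolerance = 0.02)
    }
  }
})

test_that("Pearson correlation matches the closed form and handles edges", {
  res <- pearson_r(c(0, 1, 2), c(0, 1, 4), bf = FALSE)
  expect_equal(res$r, 0.9607689, tolerance = 1e-6)
  expect_equal(res$df, 1)
  perfect <- pearson_r(1:10, 2 * (1:10) + 1, bf = FALSE)
  expect_equal(perfect$r, 1)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("Jeffreys correlation Bayes factor is symmetric and consistent", {
  expect_equal(
    jeffreys_bf_correlation(0.3, 40),
    jeffreys_bf_correlation(-0.3, 40)
  )
  # r = 0: evidence for the null, growing with n
  bf_null <- sapply(c(10, 30, 100), jeffreys_bf_correlation, r = 0)
  expect_true(all(bf_null < 1))
  expect_true(all(diff(bf_null) < 0))
  # quadrature against a Monte-Carlo prior-draw oracle
  set.seed(64)
  rho <- 2 * stats::rbeta(2e4, 1, 1) - 1
  for (n in c(20, 61)) {
    for (r in c(0, 0.2, 0.38)) {
      mc <- mean(vptbias:::correlation_lr(rho, r, n))
      expect_equal(jeffreys_bf_correlation(r, n), mc, tolerance = 0.02)
    }
  }
})

test_that("p-values are uniform under the null", {
  set.seed(65)
  p_t <- replicate(500, one_sample_t(stats::rnorm(20), bf = FALSE)$p)
  expect_gt(stats::ks.test(p_t, "punif")$p.value, 0.01)
  p_r <- replicate(500, {
    pearson_r(stats::rnorm(20), stats::rnorm(20), bf = FALSE)$p
  })
  expect_gt(stats::ks.test(p_r, "punif")$p.value, 0.01)
})

test_that("power inversions match the reference design and round-trip", {
  # n = 61: one-tailed .32, two-tailed .36 (noncentral-t inversion)
  expect_equal(round(min_detectable_d(61, tails = 1), 2), 0.32)
  expect_equal(round(min_detectable_d(61, tails = 2), 2), 0.36)
  # base-R oracle for the same inversion
  oracle <- stats::power.t.test(
    n = 61, power = 0.8, sig.level = 0.05,
    type = "one.sample", alternative = "one.sided"
  )$delta
  expect_equal(min_detectable_d(61, tails = 1), oracle, tolerance = 1e-4)
  # round-trip: power at the minimal d reaches the target
  for (n in c(20, 61, 200)) {
    d <- min_detectable_d(n, tails = 2)
    pw <- power_one_sample_t(d, n, tails = 2)
    expect_gte(pw, 0.8)
    expect_lt(pw, 0.8 + 1e-4)
  }
  # monotone decreasing in n
  dd <- sapply(c(20, 40, 80, 160), min_detectable_d)
  expect_true(all(diff(dd) < 0))
})

test_that("minimal detectable correlation follows the Fisher-z form", {
  expect_equal(round(min_detectable_r(61, tails = 2), 3), 0.352)
  # power -> 0.5 limit: z_power term vanishes
  expect_equal(
    min_detectable_r(61, power = 0.5, tails = 1),
    tanh(stats::qnorm(0.95) / sqrt(58))
  )
  rr <- sapply(c(20, 40, 80, 160), min_detectable_r)
  expect_true(all(diff(rr) < 0))
  expect_error(min_detectable_r(3), "n > 3")
})
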