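#' One-sample t-test with effect size and default Bayes factor
#'
#' Two-tailed one-sample t-test of a vector against `mu0`, reporting
#' Cohen's d (`(mean - mu0) / sd`) and, optionally, the JZS Bayes factor.
#'
#' @param x Numeric vector (missing values dropped).
#' @param mu0 Null value.
#' @param bf Compute the JZS Bayes factor? (adds quadrature cost).
#' @param scale Cauchy prior scale for the Bayes factor.
#' @return One-row tibble: `n`, `mean`, `sd`, `statistic`, `df`, `p`, `d`,
#'   `bf10`.
#' @export
one_sample_t <- function(x, mu0 = 0, bf = TRUE, scale = sqrt(2) / 2) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) {
    stop("one_sample_t requires at least 2 observations", call. = FALSE)
  }
  s <- stats::sd(x)
  if (s == 0) {
    stop("degenerate input: zero standard deviation", call. = FALSE)
  }
  tt <- stats::t.test(x, mu = mu0)
  tstat <- unname(tt$statistic)
  tibble::tibble(
    n = n, mean = mean(x), sd = s,
    statistic = tstat, df = unname(tt$parameter), p = tt$p.value,
    d = (mean(x) - mu0) / s,
    bf10 = if (bf) jzs_bf_ttest(tstat, n, scale = scale) else NA_real_
  )
}

#' Repeated-measures ANOVA on a fully crossed within-subject design
#'
#' Two-way (or one-way) within-subject ANOVA decomposition, computed via a
#' type-3 multivariate linear model on the participant x cell matrix. For
#' every within-subject effect it reports F, degrees of freedom, p, partial
#' eta squared (`SS_effect / (SS_effect + SS_error)`), and -- for effects
#' with three or more levels -- the Greenhouse-Geisser epsilon and
#' corrected p.
#'
#' @param data Long-format data frame, one row per participant x cell.
#' @param dv Name of the value column.
#' @param within Character vector (length 1 or 2) of within-subject factor
#'   columns.
#' @param id Name of the participant identifier column.
#' @return Tibble with one row per effect: `effect`, `df1`, `df2`,
#'   `statistic`, `p`, `pes`, `gg_epsilon`, `p_gg`. ANOVA-level Bayes
#'   factors are not computed (column `bf10` is `NA`).
#' @export
rm_anova <- function(data, dv, within, id = "participant_id") {
  data <- as.data.frame(data)
  stopifnot(all(c(dv, within, id) %in% names(data)))
  levs <- lapply(data[within], function(x) sort(unique(as.character(x))))
  grid <- rev(expand.grid(rev(levs), stringsAsFactors = FALSE))
  names(grid) <- within
  keys <- do.call(paste, c(grid, sep = "\r"))
  data_key <- do.call(paste, c(data[within], sep = "\r"))
  ids <- unique(data[[id]])
  Y <- matrix(NA_real_, nrow = length(ids), ncol = length(keys))
  row_i <- match(data[[id]], ids)
  col_i <- match(data_key, keys)
  if (any(duplicated(cbind(row_i, col_i)))) {
    stop("rm_anova expects exactly one observation per participant and cell",
      call. = FALSE
    )
  }
  Y[cbind(row_i, col_i)] <- data[[dv]]
  if (anyNA(Y)) {
    stop("incomplete design: missing participant x cell combinations",
      call. = FALSE
    )
  }
  idata <- as.data.frame(lapply(grid, factor))
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  mlm <- stats::lm(Y ~ 1)
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  # Huynh-Feldt epsilons above 1 are routinely clipped; silence that notice
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  effects <- setdiff(rownames(ut), "(Intercept)")
  res <- tibble::tibble(
    effect = effects,
    df1 = unname(ut[effects, "num Df"]),
    df2 = unname(ut[effects, "den Df"]),
    statistic = unname(ut[effects, "F value"]),
    p = unname(ut[effects, "Pr(>F)"]),
    pes = unname(
      ut[effects, "Sum Sq"] / (ut[effects, "Sum Sq"] + ut[effects, "Error SS"])
    ),
    gg_epsilon = NA_real_,
    p_gg = NA_real_,
    bf10 = NA_real_ # model-averaged ANOVA Bayes factors are not provided
  )
  adj <- s$pval.adjustments
  if (!is.null(adj) && nrow(adj) > 0) {
    hit <- match(trimws(rownames(adj)), res$effect)
    # car emits NA epsilon (and a placeholder p) for 1-df effects, where no
    # sphericity correction applies; keep those NA
    ok <- !is.na(hit) & is.finite(adj[, "GG eps"])
    res$gg_epsilon[hit[ok]] <- adj[ok, "GG eps"]
    res$p_gg[hit[ok]] <- adj[ok, "Pr(>F[GG])"]
  }
  res
}

#' JZS Bayes factor for a one-sample t-test
#'
#' Default-prior Bayes factor comparing a Cauchy prior on the standardised
#' effect (scale `sqrt(2)/2` by default) against the point null, computed
#' by numerical quadrature over the implied inverse-gamma mixture of
#' g-priors (relative tolerance 1e-8).
#'
#' @param t Observed t statistic.
#' @param n Sample size.
#' @param scale Cauchy prior scale.
#' @return The Bayes factor BF10 (evidence for the alternative over the
#'   null).
#' @export
jzs_bf_ttest <- function(t, n, scale = sqrt(2) / 2) {
  stopifnot(is.finite(t), n >= 2)
  nu <- n - 1
  log_m0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    exp(
      -0.5 * log1p(n * g) -
        (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) -
        log_m0
    ) * scale / sqrt(2 * pi) * g^(-1.5) * exp(-scale^2 / (2 * g))
  }
  q <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-8, abs.tol = 0),
    error = function(e) {
      stop("JZS quadrature failed: ", conditionMessage(e), call. = FALSE)
    }
  )
  q$value
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors (pairwise complete observations used).
#' @param bf Compute the Jeffreys correlation Bayes factor?
#' @param kappa Stretched-beta prior width for the Bayes factor.
#' @return One-row tibble: `n`, `r`, `statistic`, `df`, `p`, `bf10`.
#' @export
pearson_r <- function(x, y, bf = TRUE, kappa = 1) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    stop("pearson_r requires at least 3 complete pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  r <- unname(ct$estimate)
  tibble::tibble(
    n = n, r = r,
    statistic = unname(ct$statistic), df = unname(ct$parameter),
    p = ct$p.value,
    bf10 = if (bf) jeffreys_bf_correlation(r, n, kappa = kappa) else NA_real_
  )
}

# Gauss hypergeometric 2F1 by series summation; converges for |x| < 1,
# which covers every value arising in the correlation likelihood.
hyp2f1 <- function(a, b, cc, x, tol = 1e-13, max_terms = 100000L) {
  vapply(x, function(xi) {
    term <- 1
    s <- 1
    k <- 0
    while (abs(term) > tol * abs(s)) {
      term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * xi
      s <- s + term
      k <- k + 1
      if (k >= max_terms) {
        stop("2F1 series failed to converge", call. = FALSE)
      }
    }
    s
  }, numeric(1))
}

# Likelihood ratio p(r | rho, n) / p(r | 0, n) of an observed sample
# correlation, using the exact sampling density of r (hypergeometric form).
correlation_lr <- function(rho, r, n) {
  (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^(-(n - 1.5)) *
    hyp2f1(0.5, 0.5, n - 0.5, (rho * r + 1) / 2) /
    hyp2f1(0.5, 0.5, n - 0.5, 0.5)
}

#' Jeffreys-type Bayes factor for a Pearson correlation
#'
#' Compares a stretched-beta prior on the population correlation (uniform
#' on (-1, 1) for `kappa = 1`) against the point null, by numerical
#' integration of the exact sampling density of r. Symmetric in the sign of
#' `r`.
#'
#' @param r Observed sample correlation, `|r| < 1`.
#' @param n Sample size (`>= 3`).
#' @param kappa Prior width: the prior on `(rho + 1) / 2` is
#'   `Beta(1/kappa, 1/kappa)`.
#' @return The Bayes factor BF10.
#' @export
jeffreys_bf_correlation <- function(r, n, kappa = 1) {
  stopifnot(abs(r) < 1, n >= 3)
  q <- tryCatch(
    stats::integrate(
      function(rho) {
        correlation_lr(rho, r, n) * stats::dbeta((rho + 1) / 2, 1 / kappa, 1 / kappa) / 2
      },
      -1, 1,
      rel.tol = 1e-8
    ),
    error = function(e) {
      stop("correlation BF quadrature failed: ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  q$value
}

#' Power of a one-sample t-test
#'
#' @param d Standardised effect size (Cohen's d).
#' @param n Sample size.
#' @param alpha Significance level.
#' @param tails 1 or 2.
#' @return Power, from the noncentral t distribution with noncentrality
#'   `d * sqrt(n)`.
#' @export
power_one_sample_t <- function(d, n, alpha = 0.05, tails = 2) {
  stopifnot(n >= 2, alpha > 0, alpha < 1, tails %in% c(1, 2))
  nu <- n - 1
  ncp <- d * sqrt(n)
  if (tails == 1) {
    1 - stats::pt(stats::qt(1 - alpha, nu), nu, ncp)
  } else {
    tc <- stats::qt(1 - alpha / 2, nu)
    (1 - stats::pt(tc, nu, ncp)) + stats::pt(-tc, nu, ncp)
  }
}

#' Minimal detectable effect size of a one-sample t-test
#'
#' Smallest Cohen's d at which the test reaches the target power, found by
#' bisection on the noncentral-t power function (tolerance 1e-6).
#'
#' @param n Sample size.
#' @param alpha Significance level.
#' @param power Target power.
#' @param tails 1 or 2.
#' @return Cohen's d.
#' @export
min_detectable_d <- function(n, alpha = 0.05, power = 0.80, tails = 2) {
  stopifnot(power > 0, power < 1)
  f <- function(d) power_one_sample_t(d, n, alpha, tails) - power
  if (f(10) < 0) {
    stop("target power unattainable for d <= 10", call. = FALSE)
  }
  lo <- 0
  hi <- 10
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  hi
}

#' Minimal detectable Pearson correlation (Fisher-z approximation)
#'
#' `r = tanh((z_{1 - alpha/tails} + z_power) / sqrt(n - 3))`.
#'
#' @param n Sample size (`> 3`).
#' @param alpha Significance level.
#' @param power Target power.
#' @param tails 1 or 2.
#' @return Correlation coefficient.
#' @export
min_detectable_r <- function(n, alpha = 0.05, power = 0.80, tails = 2) {
  if (n <= 3) {
    stop("min_detectable_r requires n > 3", call. = FALSE)
  }
  stopifnot(tails %in% c(1, 2), power > 0, power < 1)
  tanh((stats::qnorm(1 - alpha / tails) + stats::qnorm(power)) / sqrt(n - 3))
}
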