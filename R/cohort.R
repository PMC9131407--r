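#' Generative configuration for a synthetic cohort
#'
#' Collects every parameter of the synthetic-cohort generator. Defaults
#' describe the reference study conditions: 79 recruited participants of
#' whom 18 are "lapse" participants with elevated error probability
#' (so that the error > 20% exclusion rule leaves about 61), 576 trials per
#' participant, response times that increase linearly at about 1.4 ms/deg
#' with angular disparity to the participant and 0.38 ms/deg with disparity
#' to a person present in the scene, ex-Gaussian trial noise, an 8% baseline
#' error probability, and questionnaire marginals/correlations matched to
#' the reference cohort (AQ mean 16.64, SD 6.29; IRI mean 68.45, SD 11.34;
#' perspective-taking propensity correlated +.38 with age and -.26 with
#' schizotypy, 0 with AQ and IRI).
#'
#' The between-participant slope SDs default to `mean * sqrt(61) / t` with
#' the reference group t statistics (19.181 for the self slope, 7.209 for
#' the other slope), i.e. the spread implied by those group-level tests.
#'
#' @param seed Integer master seed (mandatory; all randomness derives from it).
#' @param n_recruited Number of recruited participants.
#' @param n_lapse Number of participants with lapse-level error rates.
#' @param n_missing_questionnaire Number of (non-lapse) participants whose
#'   questionnaires are missing.
#' @param gamma_mean,gamma_sd Baseline RT mean and between-participant SD (ms).
#' @param beta_self_mean,beta_self_sd Self-disparity slope mean and SD
#'   (ms/degree).
#' @param beta_other_mean,beta_other_sd Other-disparity slope mean and SD
#'   (ms/degree).
#' @param delta_move_mean,delta_move_sd Additive RT shift in
#'   movement-restricted blocks (ms).
#' @param sigma,tau Ex-Gaussian trial-noise parameters (normal SD and
#'   exponential mean, ms).
#' @param p_error Baseline error probability.
#' @param lapse_error_range Range of the uniform draw for lapse participants'
#'   error probability (must lie above the exclusion threshold).
#' @param rt_floor,rt_ceiling Truncation floor and response-window ceiling
#'   for simulated RTs (ms).
#' @param age_range Inclusive age range in years.
#' @param aq_mean,aq_sd,iri_mean,iri_sd Target questionnaire marginals.
#' @param stq_prob Success probability of the binomial-like STQ-STA marginal
#'   (37 items).
#' @param cor_age,cor_stq,cor_aq,cor_iri Target correlations between the
#'   latent perspective-taking propensity (the participant's true other
#'   slope) and each individual-differences measure.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(seed,
                          n_recruited = 79,
                          n_lapse = 18,
                          n_missing_questionnaire = 3,
                          gamma_mean = 750, gamma_sd = 80,
                          beta_self_mean = 1.39,
                          beta_self_sd = 1.39 * sqrt(61) / 19.181,
                          beta_other_mean = 0.38,
                          beta_other_sd = 0.38 * sqrt(61) / 7.209,
                          delta_move_mean = 15, delta_move_sd = 10,
                          sigma = 60, tau = 100,
                          p_error = 0.08,
                          lapse_error_range = c(0.21, 0.40),
                          rt_floor = 150, rt_ceiling = 3500,
                          age_range = c(18L, 35L),
                          aq_mean = 16.64, aq_sd = 6.29,
                          iri_mean = 68.45, iri_sd = 11.34,
                          stq_prob = 0.35,
                          cor_age = 0.38, cor_stq = -0.26,
                          cor_aq = 0, cor_iri = 0) {
  if (missing(seed)) {
    stop("`seed` is mandatory in a cohort configuration", call. = FALSE)
  }
  cfg <- list(
    seed = as.integer(seed),
    n_recruited = as.integer(n_recruited),
    n_lapse = as.integer(n_lapse),
    n_missing_questionnaire = as.integer(n_missing_questionnaire),
    gamma_mean = gamma_mean, gamma_sd = gamma_sd,
    beta_self_mean = beta_self_mean, beta_self_sd = beta_self_sd,
    beta_other_mean = beta_other_mean, beta_other_sd = beta_other_sd,
    delta_move_mean = delta_move_mean, delta_move_sd = delta_move_sd,
    sigma = sigma, tau = tau,
    p_error = p_error,
    lapse_error_range = lapse_error_range,
    rt_floor = rt_floor, rt_ceiling = rt_ceiling,
    age_range = as.integer(age_range),
    aq_mean = aq_mean, aq_sd = aq_sd,
    iri_mean = iri_mean, iri_sd = iri_sd,
    stq_prob = stq_prob,
    cor_age = cor_age, cor_stq = cor_stq,
    cor_aq = cor_aq, cor_iri = cor_iri
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' Validate a cohort configuration
#'
#' @param config A `cohort_config` object (or a bare list with the same
#'   fields, e.g. read back from JSON).
#' @return The validated `cohort_config`, invisibly classed.
#' @export
validate_cohort_config <- function(config) {
  cfg <- unclass(config)
  stopifnot(is.list(cfg))
  if (is.null(cfg$seed) || is.na(cfg$seed)) {
    stop("config error: `seed` is required", call. = FALSE)
  }
  if (cfg$n_lapse > cfg$n_recruited) {
    stop("config error: `n_lapse` cannot exceed `n_recruited`", call. = FALSE)
  }
  if (cfg$n_missing_questionnaire > cfg$n_recruited - cfg$n_lapse) {
    stop("config error: `n_missing_questionnaire` exceeds non-lapse count",
      call. = FALSE
    )
  }
  sds <- c(
    cfg$gamma_sd, cfg$beta_self_sd, cfg$beta_other_sd, cfg$delta_move_sd,
    cfg$sigma, cfg$tau, cfg$aq_sd, cfg$iri_sd
  )
  if (any(sds < 0)) {
    stop("config error: all SDs and noise scales must be >= 0", call. = FALSE)
  }
  if (cfg$p_error < 0 || cfg$p_error > 1) {
    stop("config error: `p_error` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$lapse_error_range[1] <= 0.20 || cfg$lapse_error_range[2] > 1 ||
    diff(cfg$lapse_error_range) < 0) {
    stop("config error: `lapse_error_range` must be an increasing range above 0.20",
      call. = FALSE
    )
  }
  # The copula correlates each trait with the same latent propensity, so the
  # implied trait/propensity correlation matrix is PSD iff the squared
  # targets sum to at most 1.
  rho <- c(cfg$cor_age, cfg$cor_stq, cfg$cor_aq, cfg$cor_iri)
  if (any(abs(rho) > 1) || sum(rho^2) > 1) {
    stop("config error: target correlations imply a non-PSD copula matrix",
      call. = FALSE
    )
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf(
    "  %d recruited (%d lapse), seed %d\n",
    x$n_recruited, x$n_lapse, x$seed
  ))
  cat(sprintf(
    "  slopes: self %.3f (SD %.3f), other %.3f (SD %.3f) ms/deg\n",
    x$beta_self_mean, x$beta_self_sd, x$beta_other_mean, x$beta_other_sd
  ))
  cat(sprintf(
    "  noise: ex-Gaussian sigma %.0f, tau %.0f ms; p_error %.2f\n",
    x$sigma, x$tau, x$p_error
  ))
  invisible(x)
}

#' Draw per-participant generative parameters
#'
#' Samples baseline RT, the two rotation slopes, the movement-restriction
#' shift and the error probability for every recruited participant. Exactly
#' `n_lapse` participants are flagged as lapse participants and receive an
#' error probability drawn uniformly from `lapse_error_range`; everyone
#' else responds at the baseline `p_error`. Block order (ABAB/BABA)
#' alternates across participants. Uses the current RNG state.
#'
#' @param config A `cohort_config`.
#' @return Tibble with one row per recruited participant.
#' @export
sample_participants <- function(config) {
  config <- validate_cohort_config(config)
  n <- config$n_recruited
  lapse <- rep(FALSE, n)
  lapse[sample.int(n, config$n_lapse)] <- TRUE
  p_error <- rep(config$p_error, n)
  p_error[lapse] <- stats::runif(
    config$n_lapse,
    config$lapse_error_range[1], config$lapse_error_range[2]
  )
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    gamma = pmax(stats::rnorm(n, config$gamma_mean, config$gamma_sd), 200),
    beta_self = stats::rnorm(n, config$beta_self_mean, config$beta_self_sd),
    beta_other = stats::rnorm(n, config$beta_other_mean, config$beta_other_sd),
    delta_move = stats::rnorm(n, config$delta_move_mean, config$delta_move_sd),
    p_error = p_error,
    lapse = lapse,
    block_order = rep(c("ABAB", "BABA"), length.out = n)
  )
}

#' Deterministic linear predictor of a trial's response time
#'
#' The generative RT model:
#' `gamma + beta_self * d_self + beta_other * d_other * [person present]
#'  + delta_move * [movement restricted]`,
#' where `d_self` is the item's angular disparity to the participant and
#' `d_other` its disparity to the seated person (left at 90 deg, right at
#' 270 deg). All arguments are vectorised and recycled.
#'
#' @param orientation_deg Item orientation in degrees.
#' @param person_location `"none"`, `"left"` or `"right"`.
#' @param movement `"free"` or `"restricted"`.
#' @param gamma Baseline RT (ms).
#' @param beta_self,beta_other Rotation slopes (ms/degree).
#' @param delta_move Restricted-movement shift (ms).
#' @return Numeric vector of expected RTs in ms.
#' @examples
#' expected_rt(180, "none", "free", gamma = 700, beta_self = 1) # 880
#' @export
expected_rt <- function(orientation_deg, person_location, movement,
                        gamma, beta_self, beta_other = 0, delta_move = 0) {
  d_self <- angular_disparity(orientation_deg, 0)
  az <- location_azimuth(person_location)
  person <- !is.na(az)
  d_other <- numeric(length(d_self))
  d_other[person] <- angular_disparity(
    rep(orientation_deg, length.out = length(az))[person], az[person]
  )
  gamma + beta_self * d_self + beta_other * d_other +
    delta_move * (movement == "restricted")
}

# Ex-Gaussian noise: normal(0, sigma) + exponential(mean tau).
# Zero scales degrade gracefully to exact zeros.
rexgauss <- function(n, sigma, tau) {
  norm <- if (sigma > 0) stats::rnorm(n, 0, sigma) else numeric(n)
  expo <- if (tau > 0) stats::rexp(n, rate = 1 / tau) else numeric(n)
  norm + expo
}

#' Simulate the behavioural outcomes of a set of trials
#'
#' Adds ex-Gaussian noise to the linear predictor, truncates below at the
#' RT floor and censors at the response-window ceiling, and draws
#' correctness as an independent Bernoulli with the participant's error
#' probability. Uses the current RNG state.
#'
#' @param design Trial tibble from [enumerate_design()].
#' @param params One-row tibble (or list) of participant parameters as
#'   produced by [sample_participants()].
#' @param config A `cohort_config` (supplies noise and window parameters).
#' @return `design` with `response`, `correct` and `rt_ms` columns added.
#' @export
simulate_trials <- function(design, params, config) {
  n <- nrow(design)
  mu <- expected_rt(
    design$orientation_deg, design$person_location, design$movement,
    params$gamma, params$beta_self, params$beta_other, params$delta_move
  )
  rt <- mu + rexgauss(n, config$sigma, config$tau)
  rt <- pmin(pmax(rt, config$rt_floor), config$rt_ceiling)
  correct <- stats::runif(n) >= params$p_error
  other_form <- ifelse(design$form == "canonical", "mirror", "canonical")
  design$response <- ifelse(correct, design$form, other_form)
  design$correct <- correct
  design$rt_ms <- rt
  design
}

#' Simulate a full synthetic cohort
#'
#' Generates, reproducibly from the master seed, the trial-level behavioural
#' table (one 576-trial session per recruited participant) and the
#' questionnaire table with the configured marginals and correlations to the
#' latent perspective-taking propensity.
#'
#' @param config A `cohort_config`.
#' @param questionnaires If `FALSE`, skip questionnaire generation (faster
#'   for purely behavioural simulations).
#' @return A list with elements `trials` (tibble), `questionnaires` (tibble
#'   or `NULL`), `participants` (the true generative parameters; useful as
#'   ground truth in recovery studies) and `config`.
#' @export
simulate_cohort <- function(config, questionnaires = TRUE) {
  config <- validate_cohort_config(config)
  set.seed(config$seed)
  participants <- sample_participants(config)
  trials <- purrr::map(seq_len(nrow(participants)), function(i) {
    p <- participants[i, ]
    design <- enumerate_design(p$block_order)
    sim <- simulate_trials(design, p, config)
    sim$participant_id <- p$participant_id
    sim
  })
  trials <- dplyr::bind_rows(trials)
  trials <- dplyr::relocate(trials, "participant_id")
  quest <- if (questionnaires) generate_questionnaires(participants, config) else NULL
  list(
    trials = trials, questionnaires = quest,
    participants = participants, config = config
  )
}
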