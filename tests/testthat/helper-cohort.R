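# Small configurations used across tests. The reference (default) settings
# stay untouched; these only shrink the cohort or switch noise off.

tiny_config <- function(seed = 1, n = 6, ...) {
  cohort_config(
    seed = seed, n_recruited = n, n_lapse = 0,
    n_missing_questionnaire = 0, ...
  )
}

noiseless_config <- function(seed = 1, n = 4, ...) {
  cohort_config(
    seed = seed, n_recruited = n, n_lapse = 0, n_missing_questionnaire = 0,
    gamma_sd = 0, beta_self_sd = 0, beta_other_sd = 0, delta_move_sd = 0,
    sigma = 0, tau = 0, p_error = 0, ...
  )
}

# Disparity of each orientation to a viewpoint, by direct enumeration --
# independent of angular_disparity()'s arithmetic.
brute_disparity <- function(theta, phi) {
  sapply(theta, function(th) {
    min(abs(th - phi) %% 360, (360 - abs(th - phi)) %% 360)
  })
}

# Retained-participant RT stream of a simulated cohort.
prepare_streams <- function(sim) {
  excl <- exclude_participants(sim$trials)
  filter_trials(sim$trials[sim$trials$participant_id %in% excl$retained, ])
}
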