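#' Projection constant linking linear rotation slopes to biases
#'
#' The mean over the eight orientations of the self-disparity multiplied by
#' the negative cosine of the orientation: for a profile that rises exactly
#' linearly in disparity with slope `b` ms/degree, the towards/away bias
#' equals `b` times this constant (38.40990...). The same constant links an
#' other-disparity slope to the left/right bias at either seating azimuth.
#'
#' @return A single number, `(1/8) * sum(d_self(theta) * -cos(theta))`.
#' @export
projection_constant <- function() {
  theta <- orientation_angles()
  mean(angular_disparity(theta, 0) * (-cospi(theta / 180)))
}

check_profile <- function(values, orientations) {
  ok <- length(values) == 8L &&
    length(orientations) == 8L &&
    setequal(orientations, orientation_angles()) &&
    !anyNA(values)
  ok
}

#' Towards/away bias of an orientation profile
#'
#' Cosine projection of a per-orientation profile: the mean of the eight
#' values multiplied by the negative cosine of their orientation. Positive
#' values mean slower responses the more the item faces away from the
#' participant (the mental rotation effect); orientations facing the
#' participant (315/0/45) contribute negatively, away-facing ones
#' (135/180/225) positively.
#'
#' @param values Numeric vector of 8 per-orientation means (RTs in ms or
#'   error rates).
#' @param orientations Orientation in degrees of each value (any order;
#'   must cover all eight angles).
#' @return The bias (same units as `values`), or `NA` if the profile is
#'   incomplete.
#' @export
towards_away_bias <- function(values, orientations = orientation_angles()) {
  if (!check_profile(values, orientations)) {
    return(NA_real_)
  }
  mean(values * (-cospi(orientations / 180)))
}

#' Left/right bias of an orientation profile
#'
#' Sine projection of a per-orientation profile, signed so that positive
#' values mean faster responses for left-facing orientations (45/90/135) --
#' the direction expected when a person seated on the left is granted the
#' upright view: `-(1/8) * sum(value * sin(theta))`.
#'
#' @inheritParams towards_away_bias
#' @return The bias, or `NA` if the profile is incomplete.
#' @export
left_right_bias <- function(values, orientations = orientation_angles()) {
  if (!check_profile(values, orientations)) {
    return(NA_real_)
  }
  -mean(values * sinpi(orientations / 180))
}

#' Bias summaries for every participant and condition
#'
#' Applies the two projections to each complete 8-orientation profile. The
#' biases for the free and restricted movement conditions are computed from
#' their own profiles; the pooled (`movement == "all"`) biases are the mean
#' of the two movement-condition biases rather than a recomputation from
#' pooled trials, which keeps the pooled summary balanced when the two
#' conditions retain different trial counts.
#'
#' @param profiles Output of [orientation_profiles()].
#' @return Tibble with `participant_id`, `movement` (free/restricted/all),
#'   `person_location`, `measure`, `ta_bias`, `lr_bias` and `complete`.
#'   Incomplete profiles yield `NA` biases and are flagged.
#' @export
bias_summaries <- function(profiles) {
  per_condition <- profiles |>
    dplyr::filter(.data$movement != "all") |>
    dplyr::group_by(
      .data$participant_id, .data$movement, .data$person_location,
      .data$measure
    ) |>
    dplyr::summarise(
      ta_bias = towards_away_bias(.data$value, .data$orientation_deg),
      lr_bias = left_right_bias(.data$value, .data$orientation_deg),
      complete = check_profile(.data$value, .data$orientation_deg),
      .groups = "drop"
    )
  pooled <- per_condition |>
    dplyr::group_by(.data$participant_id, .data$person_location, .data$measure) |>
    dplyr::summarise(
      ta_bias = mean(.data$ta_bias),
      lr_bias = mean(.data$lr_bias),
      complete = all(.data$complete) && dplyr::n() == 2L,
      .groups = "drop"
    ) |>
    dplyr::mutate(movement = "all")
  dplyr::bind_rows(per_condition, pooled) |>
    dplyr::relocate(
      "participant_id", "movement", "person_location", "measure"
    )
}

#' Perspective-taking score from a pair of left/right biases
#'
#' The spontaneous perspective-taking score is the left/right bias with the
#' person seated on the left minus the bias with the person seated on the
#' right; positive values index a shift of the recognition advantage
#' towards the orientation upright to the other person.
#'
#' @param lr_left,lr_right Left/right biases (ms) in the person-left and
#'   person-right conditions.
#' @return `lr_left - lr_right` (NA if either is missing).
#' @export
perspective_taking_score <- function(lr_left, lr_right) {
  lr_left - lr_right
}

#' Per-participant perspective-taking scores
#'
#' @param biases Output of [bias_summaries()] (RT measure).
#' @return Tibble with `participant_id`, `movement`, the two left/right
#'   biases and `pt_score`.
#' @export
perspective_scores <- function(biases) {
  biases |>
    dplyr::filter(
      .data$person_location %in% c("left", "right"),
      .data$measure == "rt_ms"
    ) |>
    dplyr::select(
      "participant_id", "movement", "person_location", "lr_bias"
    ) |>
    tidyr::pivot_wider(
      names_from = "person_location", values_from = "lr_bias"
    ) |>
    dplyr::mutate(
      pt_score = perspective_taking_score(.data$left, .data$right)
    )
}

#' Error-rate analogues of the bias statistics
#'
#' Convenience wrapper: computes the towards/away and left/right
#' projections of error-rate profiles (units are proportions).
#'
#' @param trials The error stream from [filter_trials()].
#' @return Tibble as from [bias_summaries()], `measure == "error_rate"`.
#' @export
error_rate_biases <- function(trials) {
  bias_summaries(orientation_profiles(trials, measure = "error_rate"))
}
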