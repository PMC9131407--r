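# R^2 without summary.lm (which warns on exact fits)
r_squared_of <- function(fit, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    return(NA_real_)
  }
  1 - sum(stats::residuals(fit)^2) / tss
}

scope_trials <- function(trials, scope) {
  if (scope == "all") {
    trials
  } else {
    trials[trials$movement == scope, ]
  }
}

#' Per-participant simple mental-rotation regression
#'
#' Ordinary least squares of cell-mean RT on the item's angular disparity
#' to the participant, for each participant separately. Cells are the
#' person-location x orientation means of the trials in scope (all
#' conditions, or one movement condition), so the fit uses up to 24 cell
#' means over the five distinct self-disparity values.
#'
#' @param trials RT-stream trial table (see [filter_trials()]).
#' @param scope `"all"`, `"free"` or `"restricted"`.
#' @return Tibble with one row per participant: `intercept`, `beta_self`
#'   (ms/degree), `r_squared`, `n_cells`. Participants whose cells span
#'   fewer than 3 distinct disparities get `NA` coefficients.
#' @export
fit_self_rotation <- function(trials, scope = c("all", "free", "restricted")) {
  scope <- match.arg(scope)
  trials <- scope_trials(validate_trial_table(trials), scope)
  cells <- trials |>
    dplyr::group_by(
      .data$participant_id, .data$person_location, .data$orientation_deg
    ) |>
    dplyr::summarise(rt = mean(.data$rt_ms), .groups = "drop") |>
    dplyr::mutate(d_self = angular_disparity(.data$orientation_deg, 0))
  cells |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      if (length(unique(df$d_self)) < 3L) {
        return(tibble::tibble(
          intercept = NA_real_, beta_self = NA_real_,
          r_squared = NA_real_, n_cells = nrow(df)
        ))
      }
      fit <- stats::lm(rt ~ d_self, data = df)
      tibble::tibble(
        intercept = unname(stats::coef(fit)[1]),
        beta_self = unname(stats::coef(fit)[2]),
        r_squared = r_squared_of(fit, df$rt),
        n_cells = nrow(df)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(scope = scope, .after = "participant_id")
}

#' Per-participant dual-viewpoint rotation regression
#'
#' For each participant, the 16 cell-mean RTs (8 orientations x person
#' left/right) are regressed on two predictors: the item's angular
#' disparity to the participant and its disparity to the seated person.
#' With the persons at 90 and 270 degrees the two predictors are exactly
#' orthogonal over the 16 design cells, so each coefficient equals its
#' simple-regression counterpart. Person-absent trials carry no
#' other-disparity and are excluded.
#'
#' @param trials RT-stream trial table.
#' @param scope `"all"`, `"free"` or `"restricted"`.
#' @return Tibble with one row per participant: `intercept`, `beta_self`,
#'   `beta_other` (ms/degree), `r_squared`, `n_cells`. Participants with
#'   incomplete 16-cell designs get `NA` coefficients and are flagged via
#'   `n_cells`.
#' @export
fit_dual_viewpoint <- function(trials, scope = c("all", "free", "restricted")) {
  scope <- match.arg(scope)
  trials <- scope_trials(validate_trial_table(trials), scope)
  cells <- trials |>
    dplyr::filter(.data$person_location %in% c("left", "right")) |>
    dplyr::group_by(
      .data$participant_id, .data$person_location, .data$orientation_deg
    ) |>
    dplyr::summarise(rt = mean(.data$rt_ms), .groups = "drop") |>
    dplyr::mutate(
      d_self = angular_disparity(.data$orientation_deg, 0),
      d_other = angular_disparity(
        .data$orientation_deg, location_azimuth(.data$person_location)
      )
    )
  cells |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 16L) {
        return(tibble::tibble(
          intercept = NA_real_, beta_self = NA_real_, beta_other = NA_real_,
          r_squared = NA_real_, n_cells = nrow(df)
        ))
      }
      fit <- stats::lm(rt ~ d_self + d_other, data = df)
      tibble::tibble(
        intercept = unname(stats::coef(fit)[1]),
        beta_self = unname(stats::coef(fit)[2]),
        beta_other = unname(stats::coef(fit)[3]),
        r_squared = r_squared_of(fit, df$rt),
        n_cells = nrow(df)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(scope = scope, .after = "participant_id")
}

#' Group-level summary of per-participant rotation fits
#'
#' For each coefficient, reports the across-participant mean and SD, a
#' one-sample t-test against zero with Cohen's d and the default-prior JZS
#' Bayes factor, and the count of positive slopes. Coefficient sets with
#' zero variance are flagged degenerate (`NA` statistics).
#'
#' @param fits Output of [fit_self_rotation()] or [fit_dual_viewpoint()].
#' @param coefficients Which coefficient columns to summarise.
#' @return Tibble with one row per scope x coefficient.
#' @export
summarise_fits <- function(fits,
                           coefficients = intersect(
                             c("beta_self", "beta_other"), names(fits)
                           )) {
  long <- fits |>
    dplyr::select(dplyr::all_of(c("participant_id", "scope", coefficients))) |>
    tidyr::pivot_longer(
      dplyr::all_of(coefficients),
      names_to = "term", values_to = "estimate"
    ) |>
    dplyr::filter(!is.na(.data$estimate))
  long |>
    dplyr::group_by(.data$scope, .data$term) |>
    dplyr::group_modify(function(df, key) {
      x <- df$estimate
      if (length(x) < 2L || stats::sd(x) == 0) {
        return(tibble::tibble(
          n = length(x), mean = mean(x), sd = stats::sd(x),
          statistic = NA_real_, df = NA_real_, p = NA_real_,
          d = NA_real_, bf10 = NA_real_, n_positive = sum(x > 0),
          degenerate = TRUE
        ))
      }
      tt <- one_sample_t(x)
      tibble::tibble(
        n = tt$n, mean = tt$mean, sd = tt$sd,
        statistic = tt$statistic, df = tt$df, p = tt$p, d = tt$d,
        bf10 = tt$bf10, n_positive = sum(x > 0), degenerate = FALSE
      )
    }) |>
    dplyr::ungroup()
}
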