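TRIAL_COLUMNS <- c(
  "participant_id", "block", "trial_index", "movement", "person_location",
  "actor_sex", "character", "form", "orientation_deg", "response",
  "correct", "rt_ms"
)

#' Validate a trial table against the expected schema
#'
#' @param trials A data frame of trial records.
#' @return The trials as a tibble, invisibly validated.
#' @export
validate_trial_table <- function(trials) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing) > 0) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  tibble::as_tibble(trials)
}

#' Apply trial-level exclusion rules
#'
#' Splits the trials into the two analysis streams. The RT stream keeps
#' correct, responded trials with RTs between `rt_min` and `rt_max`
#' (boundaries inclusive; the rules remove trials strictly shorter/longer
#' than the window). The error stream keeps every responded trial
#' regardless of correctness or RT. A removal log reconciles exactly with
#' the input: `nrow(trials) == nrow(rt_trials) + sum(log$n_removed)`.
#'
#' @param trials Trial table.
#' @param rt_min,rt_max Inclusive RT retention window in ms.
#' @return A list with `rt_trials`, `error_trials` and `log` (tibble of
#'   removal rule and count for the RT stream).
#' @export
filter_trials <- function(trials, rt_min = 150, rt_max = 2000) {
  trials <- validate_trial_table(trials)
  if (nrow(trials) == 0) {
    warning("filter_trials: empty input", call. = FALSE)
  }
  responded <- !is.na(trials$rt_ms) & !is.na(trials$response)
  incorrect <- responded & !trials$correct
  too_short <- responded & trials$correct & trials$rt_ms < rt_min
  too_long <- responded & trials$correct & trials$rt_ms > rt_max
  keep_rt <- responded & trials$correct & !too_short & !too_long
  log <- tibble::tibble(
    rule = c("no_response", "incorrect", "rt_too_short", "rt_too_long"),
    n_removed = c(sum(!responded), sum(incorrect), sum(too_short), sum(too_long))
  )
  list(
    rt_trials = trials[keep_rt, ],
    error_trials = trials[responded, ],
    log = log
  )
}

#' Apply the participant-level error-rate exclusion rule
#'
#' A participant is excluded iff their overall error proportion, computed on
#' the raw (untrimmed) trials, strictly exceeds the threshold. Unresponded
#' trials count as errors.
#'
#' @param trials Trial table (raw, before RT trimming).
#' @param threshold Exclusion threshold on the error proportion.
#' @return List with `retained` (character vector of participant ids) and
#'   `report` (per-participant tibble of trial counts, error rate and
#'   exclusion flag).
#' @export
exclude_participants <- function(trials, threshold = 0.20) {
  trials <- validate_trial_table(trials)
  report <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      error_rate = mean(!(.data$correct %in% TRUE)),
      .groups = "drop"
    ) |>
    dplyr::mutate(excluded = .data$error_rate > threshold)
  list(
    retained = report$participant_id[!report$excluded],
    report = report
  )
}

#' Per-orientation mean profiles
#'
#' Computes, for each participant, movement condition and person location,
#' the mean of the chosen measure at each of the eight orientations.
#' Movement level `"all"` pools the trials of both movement conditions.
#' Cells are computed from whatever stream is passed in: use the RT stream
#' from [filter_trials()] with `measure = "rt_ms"` and the error stream
#' with `measure = "error_rate"`.
#'
#' @param trials Trial table (already filtered to the appropriate stream).
#' @param measure `"rt_ms"` (mean RT of the cell) or `"error_rate"`
#'   (proportion incorrect).
#' @return Long tibble with columns `participant_id`, `movement`
#'   (free/restricted/all), `person_location`, `orientation_deg`, `value`,
#'   `n_trials` and `measure`. Empty cells are absent; completeness is
#'   checked by the bias statistics.
#' @export
orientation_profiles <- function(trials, measure = c("rt_ms", "error_rate")) {
  measure <- match.arg(measure)
  trials <- validate_trial_table(trials)
  summarise_cells <- function(data) {
    data |>
      dplyr::group_by(
        .data$participant_id, .data$movement, .data$person_location,
        .data$orientation_deg
      ) |>
      dplyr::summarise(
        value = if (measure == "rt_ms") mean(.data$rt_ms) else mean(!.data$correct),
        n_trials = dplyr::n(),
        .groups = "drop"
      )
  }
  by_movement <- summarise_cells(trials)
  pooled <- summarise_cells(dplyr::mutate(trials, movement = "all"))
  out <- dplyr::bind_rows(by_movement, pooled)
  out$measure <- measure
  out
}
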