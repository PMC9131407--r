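#' Read a cohort configuration from a JSON file
#'
#' The file holds a JSON object whose fields mirror the arguments of
#' [cohort_config()]; omitted fields take the defaults. `seed` is
#' mandatory.
#'
#' @param path Path to a JSON configuration file.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("config error: unknown fields: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(cohort_config, raw)
}

#' Read a trial table CSV
#'
#' @param path Path to a trial CSV in the package's dialect.
#' @return Validated trial tibble.
#' @export
read_trial_table <- function(path) {
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      movement = readr::col_character(),
      person_location = readr::col_character(),
      actor_sex = readr::col_character(),
      character = readr::col_character(),
      form = readr::col_character(),
      response = readr::col_character(),
      correct = readr::col_logical(),
      .default = readr::col_double()
    )
  )
  validate_trial_table(trials)
}

run_manifest <- function(config, stage_counts) {
  list(
    package = "vptbias",
    version = as.character(utils::packageVersion("vptbias")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    config = unclass(config),
    stages = stage_counts
  )
}

#' Simulate a cohort and write its tables to disk
#'
#' Runs the generator and writes `trials.csv`, `questionnaires.csv` and a
#' `manifest.json` recording the configuration, its hash and per-table row
#' counts. Outputs are deterministic given the config's seed.
#'
#' @param config A `cohort_config` or path to a JSON config file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the simulation list from [simulate_cohort()] with a
#'   `paths` element added.
#' @export
run_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_cohort_config(config)
  config <- validate_cohort_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config)
  paths <- list(
    trials = file.path(out_dir, "trials.csv"),
    questionnaires = file.path(out_dir, "questionnaires.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(sim$trials, paths$trials)
  readr::write_csv(sim$questionnaires, paths$questionnaires)
  manifest <- run_manifest(config, list(
    trials = nrow(sim$trials),
    questionnaires = nrow(sim$questionnaires)
  ))
  jsonlite::write_json(manifest, paths$manifest,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  sim$paths <- paths
  invisible(sim)
}

#' Run the full analysis pipeline on a trial table
#'
#' Applies the participant- and trial-level exclusion rules and then
#' reproduces the standard result set of the perspective-taking paradigm:
#' the overall mental-rotation summary (towards/away bias test and simple
#' rotation-slope summary), the movement x location ANOVA of towards/away
#' biases, the movement x location ANOVA of left/right biases with the
#' direct person-left vs person-right comparisons, the dual-viewpoint
#' regression summaries per movement scope with the movement x viewpoint
#' ANOVA of the coefficients, the error-rate bias table, and -- when a
#' questionnaire table is supplied -- the individual-differences
#' correlations and hierarchical regression. Participants lacking
#' questionnaires are analysed behaviourally and dropped (logged) from the
#' individual-differences stage.
#'
#' @param trials Trial table (tibble or path to CSV).
#' @param questionnaires Optional questionnaire table (tibble or path).
#' @param out_dir Optional directory; when given, result tables are written
#'   as CSV/JSON.
#' @param exclusion_threshold Participant error-rate exclusion threshold.
#' @return A list of result tables (see Details) plus `manifest`.
#' @export
run_analyze <- function(trials, questionnaires = NULL, out_dir = NULL,
                        exclusion_threshold = 0.20) {
  if (is.character(trials)) trials <- read_trial_table(trials)
  trials <- validate_trial_table(trials)
  if (is.character(questionnaires)) {
    questionnaires <- readr::read_csv(questionnaires, show_col_types = FALSE)
  }

  excl <- exclude_participants(trials, threshold = exclusion_threshold)
  retained_trials <- trials[trials$participant_id %in% excl$retained, ]
  streams <- filter_trials(retained_trials)

  rt_profiles <- orientation_profiles(streams$rt_trials, "rt_ms")
  rt_biases <- bias_summaries(rt_profiles)

  # mental rotation: overall towards/away bias (mean of the six
  # movement x location condition biases per participant) and per-condition
  # tests, plus the simple self-disparity slope summary
  overall_ta <- rt_biases |>
    dplyr::filter(.data$movement != "all", .data$complete) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(ta = mean(.data$ta_bias), n_cells = dplyr::n(), .groups = "drop")
  ta_test <- one_sample_t(overall_ta$ta[overall_ta$n_cells == 6L])
  ta_by_condition <- rt_biases |>
    dplyr::filter(.data$movement != "all") |>
    dplyr::group_by(.data$movement, .data$person_location) |>
    dplyr::group_modify(function(df, key) {
      one_sample_t(df$ta_bias[df$complete])
    }) |>
    dplyr::ungroup()
  self_fits <- fit_self_rotation(streams$rt_trials, "all")
  mental_rotation <- list(
    overall_towards_away = ta_test,
    by_condition = ta_by_condition,
    self_slope_summary = summarise_fits(self_fits, "beta_self")
  )

  # ANOVAs on the bias summaries
  ta_long <- rt_biases |>
    dplyr::filter(.data$movement != "all", .data$complete)
  anova_ta <- rm_anova(ta_long, "ta_bias", c("movement", "person_location"))
  lr_long <- ta_long |>
    dplyr::filter(.data$person_location %in% c("left", "right"))
  anova_lr <- rm_anova(lr_long, "lr_bias", c("movement", "person_location"))

  # perspective-taking scores and direct left-vs-right comparisons
  pt <- perspective_scores(rt_biases)
  pt_tests <- pt |>
    dplyr::filter(!is.na(.data$pt_score)) |>
    dplyr::group_by(.data$movement) |>
    dplyr::group_modify(function(df, key) one_sample_t(df$pt_score)) |>
    dplyr::ungroup()

  # dual-viewpoint regressions per scope + movement x viewpoint ANOVA
  dual_fits <- dplyr::bind_rows(
    fit_dual_viewpoint(streams$rt_trials, "all"),
    fit_dual_viewpoint(streams$rt_trials, "free"),
    fit_dual_viewpoint(streams$rt_trials, "restricted")
  )
  beta_long <- dual_fits |>
    dplyr::filter(.data$scope != "all", !is.na(.data$beta_self)) |>
    dplyr::select("participant_id", "scope", "beta_self", "beta_other") |>
    tidyr::pivot_longer(c("beta_self", "beta_other"),
      names_to = "viewpoint", values_to = "beta"
    )
  complete_beta <- beta_long |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::filter(dplyr::n() == 4L) |>
    dplyr::ungroup()
  anova_beta <- rm_anova(complete_beta, "beta", c("scope", "viewpoint"))
  rotation <- list(
    fits = dual_fits,
    summary = summarise_fits(dual_fits),
    movement_by_viewpoint_anova = anova_beta
  )

  # error-rate analogues, laid out per condition
  err_biases <- error_rate_biases(streams$error_trials)
  error_table <- err_biases |>
    dplyr::filter(.data$complete) |>
    dplyr::group_by(.data$movement, .data$person_location) |>
    dplyr::summarise(
      n = dplyr::n(),
      ta_mean = mean(.data$ta_bias), ta_sd = stats::sd(.data$ta_bias),
      ta_p = one_sample_t(.data$ta_bias, bf = FALSE)$p,
      lr_mean = mean(.data$lr_bias), lr_sd = stats::sd(.data$lr_bias),
      lr_p = one_sample_t(.data$lr_bias, bf = FALSE)$p,
      .groups = "drop"
    )

  # individual differences
  individual_differences <- NULL
  if (!is.null(questionnaires)) {
    pt_overall <- pt |>
      dplyr::filter(.data$movement == "all", !is.na(.data$pt_score)) |>
      dplyr::select("participant_id", "pt_score")
    idf <- dplyr::inner_join(pt_overall, questionnaires, by = "participant_id")
    no_row <- setdiff(pt_overall$participant_id, idf$participant_id)
    trait_cols <- intersect(c("aq_total", "iri_total", "stq_sta"), names(idf))
    no_traits <- idf$participant_id[
      rowSums(!is.na(idf[, trait_cols, drop = FALSE])) == 0
    ]
    # trait correlations use pairwise-complete cases (age, a demographic, is
    # present even when the questionnaires are missing); the hierarchical
    # regression uses listwise-complete cases
    individual_differences <- list(
      correlations = trait_correlations(idf),
      regression = hierarchical_regression(idf),
      n_behavioural = nrow(pt_overall),
      dropped_no_questionnaire = union(no_row, no_traits)
    )
  }

  manifest <- list(
    package = "vptbias",
    version = as.character(utils::packageVersion("vptbias")),
    n_input_trials = nrow(trials),
    n_participants_input = length(unique(trials$participant_id)),
    n_participants_retained = length(excl$retained),
    exclusions = excl$report,
    filter_log = streams$log
  )

  results <- list(
    exclusions = excl$report,
    filter_log = streams$log,
    mental_rotation = mental_rotation,
    anova_towards_away = anova_ta,
    anova_left_right = anova_lr,
    perspective = list(scores = pt, tests = pt_tests),
    rotation = rotation,
    error_biases = error_table,
    individual_differences = individual_differences,
    manifest = manifest
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(excl$report, file.path(out_dir, "exclusions.csv"))
    readr::write_csv(ta_by_condition, file.path(out_dir, "mental_rotation.csv"))
    readr::write_csv(anova_ta, file.path(out_dir, "anova_towards_away.csv"))
    readr::write_csv(anova_lr, file.path(out_dir, "anova_left_right.csv"))
    readr::write_csv(pt, file.path(out_dir, "perspective_scores.csv"))
    readr::write_csv(pt_tests, file.path(out_dir, "perspective_tests.csv"))
    readr::write_csv(dual_fits, file.path(out_dir, "rotation_fits.csv"))
    readr::write_csv(rotation$summary, file.path(out_dir, "rotation_summary.csv"))
    readr::write_csv(error_table, file.path(out_dir, "error_biases.csv"))
    if (!is.null(individual_differences)) {
      readr::write_csv(
        individual_differences$correlations,
        file.path(out_dir, "trait_correlations.csv")
      )
      readr::write_csv(
        individual_differences$regression$steps,
        file.path(out_dir, "hierarchical_regression.csv")
      )
    }
    jsonlite::write_json(
      manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"
    )
  }
  results
}
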