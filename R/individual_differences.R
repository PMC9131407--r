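#' Correlations between perspective-taking scores and trait measures
#'
#' Pearson correlations (with t-based p-values and Jeffreys correlation
#' Bayes factors) between each participant's perspective-taking score and
#' their age and questionnaire totals, using pairwise-complete cases.
#' Predictors with degenerate variance yield `NA` rows rather than errors.
#'
#' @param data Data frame with the response and predictor columns (one row
#'   per participant).
#' @param response Name of the perspective-taking score column.
#' @param predictors Character vector of predictor columns.
#' @return Tibble with one row per predictor: `predictor`, `n`, `r`,
#'   `statistic`, `df`, `p`, `bf10`.
#' @export
trait_correlations <- function(data, response = "pt_score",
                               predictors = c(
                                 "age", "aq_total", "iri_total", "stq_sta"
                               )) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  purrr::map_dfr(predictors, function(pred) {
    res <- tryCatch(
      pearson_r(data[[response]], data[[pred]]),
      error = function(e) {
        tibble::tibble(
          n = NA_integer_, r = NA_real_, statistic = NA_real_,
          df = NA_real_, p = NA_real_, bf10 = NA_real_
        )
      }
    )
    dplyr::mutate(res, predictor = pred, .before = 1)
  })
}

#' Hierarchical (nested) regression of perspective-taking scores
#'
#' Enters predictor blocks one at a time into an OLS model of the
#' perspective-taking score, reporting per step the cumulative R squared,
#' the R-squared change, and the F test of that change (equivalent to
#' `anova()` on the nested fits). The full model is additionally refit on
#' standardised variables to report standardised coefficients with
#' t-tests. Only complete cases across all predictors are used, so every
#' step is computed on the same sample.
#'
#' @param data Data frame with response and predictors.
#' @param response Name of the response column.
#' @param blocks List of character vectors (or a character vector, one
#'   predictor per block), entered in order.
#' @return List with `steps` (per-step tibble), `coefficients`
#'   (standardised full-model betas), and `n` (complete cases).
#' @export
hierarchical_regression <- function(data, response = "pt_score",
                                    blocks = c(
                                      "age", "stq_sta", "aq_total", "iri_total"
                                    )) {
  if (!is.list(blocks)) blocks <- as.list(blocks)
  preds <- unlist(blocks)
  stopifnot(response %in% names(data), all(preds %in% names(data)))
  cc <- stats::complete.cases(data[, c(response, preds)])
  d <- as.data.frame(data[cc, c(response, preds)])
  n <- nrow(d)
  if (n <= length(preds) + 1) {
    stop("too few complete cases for the full model", call. = FALSE)
  }
  fits <- vector("list", length(blocks))
  steps <- vector("list", length(blocks))
  prev <- stats::lm(stats::reformulate("1", response), data = d)
  entered <- character(0)
  for (k in seq_along(blocks)) {
    entered <- c(entered, blocks[[k]])
    fit <- stats::lm(stats::reformulate(entered, response), data = d)
    if (anyNA(stats::coef(fit))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("collinear predictors: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    r2 <- summary(fit)$r.squared
    r2_prev <- summary(prev)$r.squared
    cmp <- stats::anova(prev, fit)
    steps[[k]] <- tibble::tibble(
      step = k,
      block = paste(blocks[[k]], collapse = "+"),
      predictors = paste(entered, collapse = "+"),
      r_squared = r2,
      r_squared_change = r2 - r2_prev,
      f_change = cmp$F[2],
      df1 = cmp$Df[2],
      df2 = cmp$Res.Df[2],
      p = cmp$`Pr(>F)`[2]
    )
    fits[[k]] <- fit
    prev <- fit
  }
  dz <- as.data.frame(lapply(d, function(x) as.numeric(scale(x))))
  full_z <- stats::lm(stats::reformulate(preds, response), data = dz)
  sz <- summary(full_z)$coefficients
  coef_tbl <- tibble::tibble(
    term = rownames(sz)[-1],
    beta = sz[-1, "Estimate"],
    statistic = sz[-1, "t value"],
    p = sz[-1, "Pr(>|t|)"]
  )
  list(
    steps = dplyr::bind_rows(steps),
    coefficients = coef_tbl,
    n = n
  )
}
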