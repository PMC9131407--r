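#' Default scoring key for the 50-item autism-spectrum questionnaire
#'
#' Logical vector of length 50; `TRUE` marks items keyed in the "agree"
#' direction (an agree response scores one point towards the total), `FALSE`
#' marks disagree-keyed items. This is the standard published key for the
#' instrument; pass a different key to [score_aq()] for variants.
#'
#' @return Logical vector of length 50.
#' @export
aq_default_key <- function() {
  key <- rep(FALSE, 50L)
  key[c(
    2, 4, 5, 6, 7, 9, 12, 13, 16, 18, 19, 20, 21, 22, 23, 26,
    33, 35, 39, 41, 42, 43, 45, 46
  )] <- TRUE
  key
}

#' Reverse-keyed items of the 28-item empathy questionnaire
#' @return Integer vector of item indices whose raw 0-4 response is
#'   reversed (`4 - raw`) before summing.
#' @export
iri_reverse_items <- function() {
  c(3L, 4L, 7L, 12L, 13L, 14L, 15L, 18L, 19L)
}

#' Subscale membership of the 28-item empathy questionnaire
#' @return Named list of four length-7 integer vectors (`fs` fantasy,
#'   `ec` empathic concern, `pt` perspective taking, `pd` personal
#'   distress) partitioning items 1-28.
#' @export
iri_subscales <- function() {
  list(
    fs = c(1L, 5L, 7L, 12L, 16L, 23L, 26L),
    ec = c(2L, 4L, 9L, 14L, 18L, 20L, 22L),
    pt = c(3L, 8L, 11L, 15L, 21L, 25L, 28L),
    pd = c(6L, 10L, 13L, 17L, 19L, 24L, 27L)
  )
}

#' Score the autism-spectrum questionnaire
#'
#' Binary scoring of 4-point responses: one point for each item answered on
#' the keyed side (definitely/slightly agree for agree-keyed items,
#' definitely/slightly disagree for disagree-keyed items).
#'
#' @param responses Integer vector of 50 raw responses coded 1 = definitely
#'   agree, 2 = slightly agree, 3 = slightly disagree, 4 = definitely
#'   disagree.
#' @param key Logical keyed-direction vector (see [aq_default_key()]).
#' @return Integer total in 0-50.
#' @export
score_aq <- function(responses, key = aq_default_key()) {
  if (length(responses) != 50L || anyNA(responses)) {
    stop(
      "AQ scoring requires 50 complete responses; missing/extra at: ",
      paste(which(is.na(responses) | seq_along(responses) > 50L), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(responses %in% 1:4)) {
    stop("AQ responses must be on the 1-4 scale", call. = FALSE)
  }
  agree <- responses <= 2L
  sum(agree == key)
}

#' Score the interpersonal-reactivity (empathy) questionnaire
#'
#' Items are scored 0-4 with reverse-keyed items flipped (`4 - raw`); the
#' total is the sum over all 28 items, and each of the four subscales sums
#' its seven items.
#'
#' @param responses Integer vector of 28 raw responses on the 0-4 scale.
#' @param reverse Indices of reverse-keyed items.
#' @param subscales Named list of subscale item indices.
#' @return Named list: `total` (0-112) and subscale totals `pt`, `ec`,
#'   `fs`, `pd` (each 0-28).
#' @export
score_iri <- function(responses, reverse = iri_reverse_items(),
                      subscales = iri_subscales()) {
  if (length(responses) != 28L || anyNA(responses)) {
    stop(
      "IRI scoring requires 28 complete responses; missing/extra at: ",
      paste(which(is.na(responses) | seq_along(responses) > 28L), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(responses %in% 0:4)) {
    stop("IRI responses must be on the 0-4 scale", call. = FALSE)
  }
  scored <- responses
  scored[reverse] <- 4L - scored[reverse]
  c(
    list(total = sum(scored)),
    lapply(subscales, function(idx) sum(scored[idx]))
  )
}

#' Score the schizotypal-trait questionnaire (STA part)
#'
#' One point per yes response over the 37 STA items.
#'
#' @param responses Logical or 0/1 vector of length 37.
#' @return Integer total in 0-37.
#' @export
score_stq <- function(responses) {
  if (length(responses) != 37L || anyNA(responses)) {
    stop("STQ-STA scoring requires 37 complete yes/no responses", call. = FALSE)
  }
  if (!all(responses %in% c(0, 1))) {
    stop("STQ responses must be yes (1) or no (0)", call. = FALSE)
  }
  sum(responses == 1)
}

# --- item-level generation ---------------------------------------------------
# The generator first draws target totals from the copula marginals and then
# allocates item-level responses that score back exactly to those totals, so
# the scoring functions are exercised end to end.

allocate_aq_responses <- function(total, key) {
  total <- as.integer(total)
  scored <- rep(FALSE, 50L)
  if (total > 0) scored[sample.int(50L, total)] <- TRUE
  # respond on the agree side iff that reproduces the item's scored status
  agree_side <- scored == key
  intensity <- sample(0:1, 50L, replace = TRUE)
  ifelse(agree_side, 1L, 3L) + intensity
}

allocate_iri_responses <- function(total, reverse) {
  total <- as.integer(total)
  base <- total %/% 28L
  rem <- total %% 28L
  scored <- rep(base, 28L)
  if (rem > 0) scored[sample.int(28L, rem)] <- base + 1L
  raw <- scored
  raw[reverse] <- 4L - raw[reverse]
  raw
}

allocate_stq_responses <- function(total) {
  total <- as.integer(total)
  resp <- rep(0L, 37L)
  if (total > 0) resp[sample.int(37L, total)] <- 1L
  resp
}

# Attenuation of a linear correlation through a monotone quantile map:
# for standard-normal L, a = cor(L, g(L)), computed by deterministic
# numerical integration. The generator divides the latent correlation by
# this factor so that the *linear* correlation with the transformed trait
# hits the configured target.
map_attenuation <- function(qmap) {
  z <- seq(-6, 6, length.out = 4001)
  w <- stats::dnorm(z)
  w <- w / sum(w)
  g <- qmap(stats::pnorm(z))
  mu <- sum(w * g)
  vg <- sum(w * (g - mu)^2)
  if (vg == 0) {
    return(1)
  }
  sum(w * z * (g - mu)) / sqrt(vg)
}

#' Generate questionnaire data for a cohort via a Gaussian copula
#'
#' Each participant's true other-perspective slope is the latent
#' perspective-taking propensity. For each trait, a latent standard normal
#' is drawn with the configured correlation to the standardised propensity
#' and mapped through a monotone quantile transform to the trait's marginal:
#' age as a discretised, young-skewed gamma over the configured range; AQ
#' and IRI as rounded truncated normals with the configured means/SDs; STQ
#' as a binomial over its 37 items. Totals are then decomposed into
#' item-level responses and re-scored with the package's scoring functions,
#' so the emitted totals are guaranteed scoring-consistent. The configured
#' number of non-lapse participants has missing questionnaires (`NA` trait
#' scores; age, a demographic, is always recorded).
#'
#' @param participants Tibble from [sample_participants()].
#' @param config A `cohort_config`.
#' @return Tibble with columns `participant_id`, `age`, `aq_total`,
#'   `iri_total`, `iri_pt`, `iri_ec`, `iri_fs`, `iri_pd`, `stq_sta`.
#'   Item-level responses are attached as attribute `"items"` (a list of
#'   `aq`, `iri`, `stq` matrices).
#' @export
generate_questionnaires <- function(participants, config) {
  config <- validate_cohort_config(config)
  n <- nrow(participants)
  z <- if (config$beta_other_sd > 0) {
    (participants$beta_other - config$beta_other_mean) / config$beta_other_sd
  } else {
    rep(0, n)
  }
  # marginal quantile maps
  q_age <- function(u) {
    pmin(
      config$age_range[2],
      config$age_range[1] + floor(stats::qgamma(u, shape = 1.2, scale = 2.55))
    )
  }
  q_aq <- function(u) {
    pmin(50, pmax(0, round(stats::qnorm(u, config$aq_mean, config$aq_sd))))
  }
  q_iri <- function(u) {
    pmin(112, pmax(0, round(stats::qnorm(u, config$iri_mean, config$iri_sd))))
  }
  q_stq <- function(u) stats::qbinom(u, 37, config$stq_prob)

  # latent normal for each trait, with the target correlation corrected for
  # the (deterministic, map-specific) attenuation so the linear correlation
  # of the transformed trait with the propensity lands on target
  latent <- function(rho, qmap) {
    rho_lat <- max(-1, min(1, rho / map_attenuation(qmap)))
    rho_lat * z + sqrt(1 - rho_lat^2) * stats::rnorm(n)
  }
  age <- q_age(stats::pnorm(latent(config$cor_age, q_age)))
  aq_target <- q_aq(stats::pnorm(latent(config$cor_aq, q_aq)))
  iri_target <- q_iri(stats::pnorm(latent(config$cor_iri, q_iri)))
  stq_target <- q_stq(stats::pnorm(latent(config$cor_stq, q_stq)))

  key <- aq_default_key()
  rev_items <- iri_reverse_items()
  aq_items <- t(vapply(aq_target, allocate_aq_responses, integer(50L), key = key))
  iri_items <- t(vapply(iri_target, allocate_iri_responses, integer(28L), reverse = rev_items))
  stq_items <- t(vapply(stq_target, allocate_stq_responses, integer(37L)))

  aq_total <- apply(aq_items, 1, score_aq, key = key)
  iri_scored <- apply(iri_items, 1, score_iri, reverse = rev_items)
  stq_sta <- apply(stq_items, 1, score_stq)

  out <- tibble::tibble(
    participant_id = participants$participant_id,
    age = as.integer(age),
    aq_total = as.integer(aq_total),
    iri_total = vapply(iri_scored, function(x) as.integer(x$total), integer(1)),
    iri_pt = vapply(iri_scored, function(x) as.integer(x$pt), integer(1)),
    iri_ec = vapply(iri_scored, function(x) as.integer(x$ec), integer(1)),
    iri_fs = vapply(iri_scored, function(x) as.integer(x$fs), integer(1)),
    iri_pd = vapply(iri_scored, function(x) as.integer(x$pd), integer(1)),
    stq_sta = as.integer(stq_sta)
  )
  if (config$n_missing_questionnaire > 0) {
    eligible <- which(!participants$lapse)
    missing <- sample(eligible, config$n_missing_questionnaire)
    trait_cols <- c(
      "aq_total", "iri_total", "iri_pt", "iri_ec", "iri_fs", "iri_pd", "stq_sta"
    )
    out[missing, trait_cols] <- NA_integer_
    aq_items[missing, ] <- NA_integer_
    iri_items[missing, ] <- NA_integer_
    stq_items[missing, ] <- NA_integer_
  }
  attr(out, "items") <- list(aq = aq_items, iri = iri_items, stq = stq_items)
  out
}
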