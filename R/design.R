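#' Stimulus orientations used in the rotated-character task
#'
#' The eight orientations at which a character can appear on the table,
#' in degrees. 0 denotes the canonical upright orientation from the
#' participant's point of view; angles increase counter-clockwise.
#'
#' @return Integer vector of length 8: 0, 45, ..., 315.
#' @export
orientation_angles <- function() {
  seq(0L, 315L, by = 45L)
}

#' Minimal angular disparity between an orientation and a viewpoint
#'
#' The angular disparity is the smallest rotation, in degrees, that maps an
#' item orientation onto a viewer's upright direction. Both arguments are
#' reduced modulo 360, and the function is symmetric in its arguments.
#' Disparity to the participant is `angular_disparity(theta, 0)`; disparity
#' to a person seated at azimuth `phi` is `angular_disparity(theta, phi)`.
#'
#' @param theta,phi Numeric vectors of angles in degrees (recycled against
#'   each other).
#' @return Numeric vector of disparities in `[0, 180]`.
#' @examples
#' angular_disparity(315, 0) # 45
#' angular_disparity(90, 270) # 180
#' @export
angular_disparity <- function(theta, phi) {
  if (!is.numeric(theta) || !is.numeric(phi)) {
    stop("`theta` and `phi` must be numeric", call. = FALSE)
  }
  if (anyNA(theta) || anyNA(phi) || !all(is.finite(theta)) || !all(is.finite(phi))) {
    stop("angles must be finite and non-missing", call. = FALSE)
  }
  delta <- abs(theta - phi) %% 360
  pmin(delta, 360 - delta)
}

#' Viewing azimuth of a viewer role
#'
#' Maps a viewer role to its azimuth in the scene's angular coordinate
#' system: the participant looks from 0 degrees, a person seated to the
#' left of the table from 90 degrees, and a person seated to the right
#' from 270 degrees (both perpendicular to the participant's line of
#' sight, which makes the two disparity predictors orthogonal across the
#' design).
#'
#' @param role Character vector; each element one of `"participant"`,
#'   `"person-left"`, `"person-right"`.
#' @return Numeric vector of azimuths in degrees.
#' @examples
#' viewpoint_azimuth("person-left") # 90
#' @export
viewpoint_azimuth <- function(role) {
  map <- c("participant" = 0, "person-left" = 90, "person-right" = 270)
  if (!is.character(role) || !all(role %in% names(map))) {
    stop("`role` must be one of: ", paste(names(map), collapse = ", "),
      call. = FALSE
    )
  }
  unname(map[role])
}

# Azimuth for the person_location coding used in trial tables.
# "none" has no defined azimuth and maps to NA.
location_azimuth <- function(person_location) {
  az <- rep(NA_real_, length(person_location))
  az[person_location == "left"] <- 90
  az[person_location == "right"] <- 270
  bad <- !person_location %in% c("none", "left", "right")
  if (any(bad)) {
    stop("unknown person_location: ",
      paste(unique(person_location[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  az
}

#' Enumerate the factorial trial design for one participant
#'
#' Builds the full 576-trial session: four blocks of 144 trials in which
#' movement condition alternates (ABAB or BABA), and each block contains
#' every combination of person location (none/left/right), character
#' (4/P/R), presentation form (canonical/mirror) and orientation (8 angles)
#' exactly once. Trial order within a block is pseudorandomised using the
#' current RNG state; the multiset of trials is identical for every seed.
#' For person-present trials, actor sex is a counterbalanced nuisance
#' factor (half male, half female per location within each block);
#' person-absent trials carry `NA`.
#'
#' @param block_order `"ABAB"` (free movement first) or `"BABA"`
#'   (restricted first).
#' @return A tibble with 576 rows and columns `block`, `trial_index`,
#'   `movement`, `person_location`, `actor_sex`, `character`, `form`,
#'   `orientation_deg`.
#' @export
enumerate_design <- function(block_order = c("ABAB", "BABA")) {
  block_order <- match.arg(block_order)
  movements <- if (block_order == "ABAB") {
    c("free", "restricted", "free", "restricted")
  } else {
    c("restricted", "free", "restricted", "free")
  }
  cells <- tidyr::expand_grid(
    person_location = c("none", "left", "right"),
    character = c("4", "P", "R"),
    form = c("canonical", "mirror"),
    orientation_deg = as.numeric(orientation_angles())
  )
  blocks <- lapply(seq_len(4L), function(b) {
    block <- cells[sample.int(nrow(cells)), ]
    block$actor_sex <- NA_character_
    for (loc in c("left", "right")) {
      i <- which(block$person_location == loc)
      block$actor_sex[i] <- sample(rep(c("male", "female"), length.out = length(i)))
    }
    block$block <- b
    block$movement <- movements[b]
    block
  })
  out <- dplyr::bind_rows(blocks)
  out$trial_index <- seq_len(nrow(out))
  out[, c(
    "block", "trial_index", "movement", "person_location", "actor_sex",
    "character", "form", "orientation_deg"
  )]
}
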