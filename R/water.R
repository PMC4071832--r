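#' Soil relative extractable water
#'
#' REW = (theta - theta_min) / (theta_max - theta_min), where theta is the
#' volumetric soil water content (averaged over measurement depths upstream),
#' theta_min the content at permanent wilting point and theta_max the content
#' at field capacity. Values above 1 can occur transiently after irrigation
#' while theta exceeds field capacity and are deliberately not clipped.
#'
#' @param theta Volumetric soil water content, m^3 m^-3, non-negative.
#' @param theta_min Soil water content at permanent wilting point, m^3 m^-3.
#'   Default 0.04.
#' @param theta_max Soil water content at field capacity, m^3 m^-3.
#'   Default 0.25.
#' @return REW, dimensionless. Vectorised.
#' @examples
#' rew(0.145) # 0.5
#' @export
rew <- function(theta, theta_min = 0.04, theta_max = 0.25) {
  if (any(theta_max <= theta_min)) {
    abort("`theta_max` must exceed `theta_min`.", class = "photolim_invalid_input")
  }
  if (any(theta < 0)) abort("`theta` must be non-negative.", class = "photolim_invalid_input")
  (theta - theta_min) / (theta_max - theta_min)
}

#' Leaf relative water content
#'
#' RWC = (fresh - dry) / (turgid - dry) x 100, the leaf water content as a
#' percentage of the content at full turgor.
#'
#' @param fresh_w Fresh mass at sampling, g.
#' @param dry_w Oven-dry mass, g.
#' @param turgid_w Mass at full turgor after rehydration, g; must exceed
#'   `dry_w`.
#' @return RWC in percent. Vectorised.
#' @examples
#' rwc(80, 40, 120) # 50
#' @export
rwc <- function(fresh_w, dry_w, turgid_w) {
  if (any(turgid_w <= dry_w)) {
    abort("`turgid_w` must exceed `dry_w`.", class = "photolim_invalid_input")
  }
  100 * (fresh_w - dry_w) / (turgid_w - dry_w)
}

#' Append water-status indices to soil and leaf tables
#'
#' Data-frame wrappers over [rew()] and [rwc()].
#'
#' @param data For `add_rew()`, a table with columns `theta`, `theta_min`,
#'   `theta_max`; for `add_rwc()`, a table with columns `fresh_w`, `dry_w`,
#'   `turgid_w`.
#' @return The input tibble with a `REW` (resp. `RWC`) column appended.
#' @export
add_rew <- function(data) {
  check_columns(data, c("theta", "theta_min", "theta_max"), "soil water")
  as_tibble(data) %>%
    mutate(REW = rew(.data$theta, .data$theta_min, .data$theta_max))
}

#' @rdname add_rew
#' @export
add_rwc <- function(data) {
  check_columns(data, c("fresh_w", "dry_w", "turgid_w"), "leaf water")
  as_tibble(data) %>%
    mutate(RWC = rwc(.data$fresh_w, .data$dry_w, .data$turgid_w))
}
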