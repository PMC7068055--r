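#' Viewing conditions for the light-adapted pupil model
#'
#' The visual field is described as a list of patches, each with a luminance
#' (cd/m^2) and an angular area (deg^2, `width_deg * height_deg` or `area`
#' directly); patch corneal fluxes (luminance x area) are summed. The age
#' adjustment is linear around the model's reference age.
#'
#' @param patches data frame with `luminance` and either `area` or
#'   `width_deg`/`height_deg` columns.
#' @param age observer age, years.
#' @param n_eyes 1 (monocular) or 2 (binocular).
#' @param reference_age reference age of the base curve, years.
#' @return A `viewing_conditions` list.
#' @export
viewing_conditions <- function(patches, age, n_eyes = 2,
                               reference_age = 28.58) {
  if (!"area" %in% names(patches))
    patches$area <- patches$width_deg * patches$height_deg
  if (any(patches$luminance <= 0) || any(patches$area <= 0))
    stopf("luminances and field areas must be positive")
  if (age <= 0 || age >= 120) stopf("age must lie in (0, 120)")
  if (!n_eyes %in% c(1, 2)) stopf("n_eyes must be 1 or 2")
  structure(list(patches = patches, age = age, n_eyes = n_eyes,
                 reference_age = reference_age),
            class = "viewing_conditions")
}

#' Viewing conditions of the oddball study
#'
#' Movie region of 18.9 x 10.3 degrees at 53.1 cd/m^2 on a grey background
#' of 2.9 cd/m^2; the background patch is the remainder of the monitor field
#' (23.6-inch 16:9 display at 60 cm), binocular viewing.
#'
#' @param age observer age, years.
#' @return A `viewing_conditions` list.
#' @export
study_viewing_conditions <- function(age) {
  screen_w_cm <- 23.6 * 2.54 * 16 / sqrt(16^2 + 9^2)
  screen_h_cm <- screen_w_cm * 9 / 16
  deg <- function(size_cm) 2 * atan(size_cm / 2 / 60) * 180 / pi
  screen_area <- deg(screen_w_cm) * deg(screen_h_cm)
  movie_area <- 18.9 * 10.3
  viewing_conditions(
    data.frame(luminance = c(53.1, 2.9),
               area = c(movie_area, screen_area - movie_area)),
    age = age, n_eyes = 2)
}

# Stanley-Davies base curve: diameter from corneal flux density (cd/m^2 deg^2)
stanley_davies <- function(flux) {
  fr <- (flux / 846)^0.41
  7.75 - 5.75 * fr / (fr + 2)
}

#' Predict light-adapted pupil diameter (unified formula)
#'
#' Stanley-Davies base curve evaluated at the corneal flux density
#' `F = sum(L_i * a_i) * M(e)` (monocular attenuation `M(1) = 0.1`,
#' `M(2) = 1`), plus the linear age adjustment
#' `(age - reference_age) * (0.02132 - 0.009562 * D_base)`.
#'
#' @param conditions a [viewing_conditions()] object.
#' @return Predicted diameter in mm.
#' @export
predict_diameter <- function(conditions) {
  stopifnot(inherits(conditions, "viewing_conditions"))
  m_e <- if (conditions$n_eyes == 2) 1 else 0.1
  flux <- sum(conditions$patches$luminance * conditions$patches$area) * m_e
  d0 <- stanley_davies(flux)
  d0 + (conditions$age - conditions$reference_age) *
    (0.02132 - 0.009562 * d0)
}

#' Percent deviation of an observed from a predicted value
#'
#' @param observed,predicted values in the same units; `predicted > 0`.
#' @return `(observed - predicted) / predicted * 100`.
#' @export
percent_deviation <- function(observed, predicted) {
  if (any(predicted <= 0)) stopf("predicted value must be positive")
  (observed - predicted) / predicted * 100
}
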