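#' Optical calibration profile for one handheld-microscope lens
#'
#' A magnification profile binds pixel measurements to physical units for a
#' given lens: the pixel density (pixels per millimetre on the leaf surface),
#' the physical field of view and the optical resolving power. Three built-in
#' profiles, `"100x"`, `"200x"` and `"400x"`, describe the handheld
#' microscope's lenses; custom profiles can be constructed for other optics.
#'
#' @param name Profile label, e.g. `"400x"` or a user-defined name.
#' @param px_per_mm Pixels per millimetre on the specimen plane (> 0).
#' @param fov_width_mm,fov_height_mm Field of view in millimetres (> 0).
#' @param resolving_power_um Smallest resolvable feature size in microns (> 0).
#'
#' @return An object of class `magnification_profile`.
#'
#' @examples
#' p400 <- get_profile("400x")
#' px_to_um(652, p400) # 652 px at 652 px/mm is exactly 1 mm = 1000 um
#'
#' @export
magnification_profile <- function(name, px_per_mm, fov_width_mm,
                                  fov_height_mm, resolving_power_um) {
  stopifnot(is.character(name), length(name) == 1L)
  vals <- c(px_per_mm = px_per_mm, fov_width_mm = fov_width_mm,
            fov_height_mm = fov_height_mm,
            resolving_power_um = resolving_power_um)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_stomapipe(
      sprintf("magnification profile '%s': all optical constants must be finite and > 0",
              name),
      "stomapipe_config_error"
    )
  }
  structure(
    list(name = name, px_per_mm = px_per_mm, fov_width_mm = fov_width_mm,
         fov_height_mm = fov_height_mm,
         resolving_power_um = resolving_power_um),
    class = "magnification_profile"
  )
}

#' @export
print.magnification_profile <- function(x, ...) {
  cat(sprintf(
    "<magnification_profile '%s': %g px/mm, FOV %g x %g mm, resolving power %g um>\n",
    x$name, x$px_per_mm, x$fov_width_mm, x$fov_height_mm,
    x$resolving_power_um))
  invisible(x)
}

#' Built-in registry of handheld-microscope lens profiles
#'
#' Returns the three standard lens profiles of the handheld microscope:
#' 100x (198 px/mm, 2.87 x 2.17 mm field of view, 4 um resolving power),
#' 200x (415 px/mm, 1.36 x 1.03 mm, 2 um) and 400x (652 px/mm,
#' 0.75 x 0.57 mm, 1 um).
#'
#' @return Named list of [magnification_profile()] objects.
#' @export
hhm_profiles <- function() {
  list(
    "100x" = magnification_profile("100x", 198, 2.87, 2.17, 4),
    "200x" = magnification_profile("200x", 415, 1.36, 1.03, 2),
    "400x" = magnification_profile("400x", 652, 0.75, 0.57, 1)
  )
}

#' Look up a built-in magnification profile by name
#'
#' @param name One of `"100x"`, `"200x"`, `"400x"`.
#' @return A [magnification_profile()].
#' @export
get_profile <- function(name) {
  reg <- hhm_profiles()
  if (!name %in% names(reg)) {
    stop_stomapipe(
      sprintf("unknown profile '%s' (built-in: %s)", name,
              paste(names(reg), collapse = ", ")),
      "stomapipe_config_error"
    )
  }
  reg[[name]]
}

check_profile <- function(profile) {
  if (!inherits(profile, "magnification_profile")) {
    stop_stomapipe("'profile' must be a magnification_profile",
                   "stomapipe_config_error")
  }
  if (!is.finite(profile$px_per_mm) || profile$px_per_mm <= 0) {
    stop_stomapipe("profile has non-positive px_per_mm",
                   "stomapipe_config_error")
  }
  invisible(profile)
}

#' Convert a pixel length to micrometres
#'
#' Uses the profile's pixel density: `length_px * 1000 / px_per_mm`.
#'
#' @param length_px Length in pixels (>= 0, vectorised).
#' @param profile A [magnification_profile()].
#' @return Length in micrometres.
#' @export
px_to_um <- function(length_px, profile) {
  check_profile(profile)
  stopifnot(all(length_px >= 0))
  length_px * 1000 / profile$px_per_mm
}

#' Convert a micrometre length to pixels
#'
#' Inverse of [px_to_um()].
#'
#' @param length_um Length in micrometres (>= 0, vectorised).
#' @inheritParams px_to_um
#' @return Length in pixels.
#' @export
um_to_px <- function(length_um, profile) {
  check_profile(profile)
  stopifnot(all(length_um >= 0))
  length_um * profile$px_per_mm / 1000
}

#' Convert a pixel area to square micrometres
#'
#' Squared form of the linear calibration: `area_px * (1000 / px_per_mm)^2`.
#'
#' @param area_px Area in square pixels (>= 0, vectorised).
#' @inheritParams px_to_um
#' @return Area in square micrometres.
#' @export
area_px_to_um2 <- function(area_px, profile) {
  check_profile(profile)
  stopifnot(all(area_px >= 0))
  area_px * (1000 / profile$px_per_mm)^2
}

#' Field-of-view area of a profile in square millimetres
#'
#' @inheritParams px_to_um
#' @return `fov_width_mm * fov_height_mm`.
#' @export
fov_area_mm2 <- function(profile) {
  check_profile(profile)
  profile$fov_width_mm * profile$fov_height_mm
}

#' Stomatal density from a per-image count
#'
#' Density is the stomatal count divided by the imaged leaf area. By default
#' the denominator is the full optical field of view of the profile (images
#' are captured at fixed FOV); pass `area_mm2` to override with an explicit
#' imaged area, e.g. for cropped images.
#'
#' @param count Stomata count (>= 0, vectorised).
#' @inheritParams px_to_um
#' @param area_mm2 Optional explicit imaged area in mm^2 (> 0).
#' @return Density in stomata per square millimetre.
#' @export
density_per_mm2 <- function(count, profile, area_mm2 = NULL) {
  stopifnot(all(count >= 0))
  a <- if (is.null(area_mm2)) fov_area_mm2(profile) else area_mm2
  if (!is.finite(a) || a <= 0) {
    stop_stomapipe("imaged area must be finite and > 0",
                   "stomapipe_config_error")
  }
  count / a
}

#' Warn when an image's pixel extent disagrees with the profile
#'
#' Capture software may letterbox or rescale frames, so a mismatch between
#' the image's pixel dimensions and `FOV x px_per_mm` beyond 5% triggers a
#' warning but processing proceeds using the profile's constants.
#'
#' @param width_px,height_px Image dimensions in pixels.
#' @inheritParams px_to_um
#' @return `TRUE` (invisibly) if consistent, `FALSE` if a warning was issued.
#' @export
check_image_extent <- function(width_px, height_px, profile) {
  check_profile(profile)
  exp_w <- profile$fov_width_mm * profile$px_per_mm
  exp_h <- profile$fov_height_mm * profile$px_per_mm
  rel <- max(abs(width_px - exp_w) / exp_w, abs(height_px - exp_h) / exp_h)
  if (rel > 0.05) {
    warning(sprintf(
      "image extent %d x %d px disagrees with profile '%s' (expected %.0f x %.0f px, %.1f%% off); proceeding with profile constants",
      width_px, height_px, profile$name, exp_w, exp_h, 100 * rel))
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

#' Expected image pixel extent for a profile's full field of view
#'
#' @inheritParams px_to_um
#' @return Integer vector `c(width_px, height_px)`.
#' @export
profile_image_size <- function(profile) {
  check_profile(profile)
  c(
    width_px = as.integer(round(profile$fov_width_mm * profile$px_per_mm)),
    height_px = as.integer(round(profile$fov_height_mm * profile$px_per_mm))
  )
}
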