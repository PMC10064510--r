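#' Species archetype for synthetic stomatal patterning
#'
#' An archetype parameterizes how stomata of a species group are arranged and
#' shaped: graminoids (grasses such as wheat and rice) carry dumbbell-type
#' stomatal complexes in longitudinal files ("rows"), while dicots such as
#' tomato scatter elliptical complexes over the epidermis. All dimensions are
#' in micrometres so archetypes are magnification-independent.
#'
#' The numeric defaults of the built-in archetypes are configurable model
#' parameters chosen to respect the qualitative size ordering seen in leaf
#' micrographs (wheat complexes much larger than rice or tomato); they are
#' not literature measurements and should be adjusted when emulating a
#' specific dataset.
#'
#' @param arrangement `"rows"` (graminoid files) or `"scattered"`
#'   (dicot hard-core point pattern).
#' @param complex_length_um,complex_length_sd_um Mean and sd of the full
#'   stomatal-complex length (guard + subsidiary cells), micrometres.
#' @param complex_width_um,complex_width_sd_um Mean and sd of complex width.
#' @param aperture_openness,aperture_openness_sd Mean and sd of the openness
#'   fraction (aperture width / complex width), truncated to \[0, 1\]. Draws
#'   at or below `closed_below` produce a closed stoma with no aperture.
#' @param aperture_length_frac Aperture length as a fraction of complex
#'   length.
#' @param orientation_sd_deg For `"rows"`: sd of orientation jitter about the
#'   row axis, degrees. Ignored for `"scattered"`, which draws uniform
#'   orientations.
#' @param min_spacing_um Hard-core inhibition distance between complex
#'   centres.
#' @param row_pitch_um Spacing between stomatal files (rows mode only).
#' @param closed_below Openness below which the stoma is rendered closed.
#' @param name Archetype label.
#'
#' @return An object of class `species_archetype`.
#' @seealso [archetype_graminoid_large()], [archetype_graminoid_small()],
#'   [archetype_dicot()]
#' @export
species_archetype <- function(name,
                              arrangement = c("rows", "scattered"),
                              complex_length_um, complex_width_um,
                              complex_length_sd_um = 0.08 * complex_length_um,
                              complex_width_sd_um = 0.08 * complex_width_um,
                              aperture_openness = 0.3,
                              aperture_openness_sd = 0.12,
                              aperture_length_frac = 0.5,
                              orientation_sd_deg = 5,
                              min_spacing_um = 1.2 * complex_length_um,
                              row_pitch_um = 3 * complex_width_um,
                              closed_below = 0.05) {
  arrangement <- match.arg(arrangement)
  dims <- c(complex_length_um, complex_width_um, complex_length_sd_um,
            complex_width_sd_um, row_pitch_um)
  if (any(!is.finite(dims)) || complex_length_um <= 0 ||
      complex_width_um <= 0 || row_pitch_um <= 0) {
    stop_stomapipe("archetype physical dimensions must be finite and > 0",
                   "stomapipe_config_error")
  }
  if (aperture_openness < 0 || aperture_openness > 1) {
    stop_stomapipe("aperture_openness must lie in [0, 1]",
                   "stomapipe_config_error")
  }
  if (min_spacing_um < 0) {
    stop_stomapipe("min_spacing_um must be >= 0", "stomapipe_config_error")
  }
  structure(
    list(name = name, arrangement = arrangement,
         complex_length_um = complex_length_um,
         complex_length_sd_um = complex_length_sd_um,
         complex_width_um = complex_width_um,
         complex_width_sd_um = complex_width_sd_um,
         aperture_openness = aperture_openness,
         aperture_openness_sd = aperture_openness_sd,
         aperture_length_frac = aperture_length_frac,
         orientation_sd_deg = orientation_sd_deg,
         min_spacing_um = min_spacing_um,
         row_pitch_um = row_pitch_um,
         closed_below = closed_below),
    class = "species_archetype"
  )
}

#' @export
print.species_archetype <- function(x, ...) {
  cat(sprintf(
    "<species_archetype '%s': %s, complex %g x %g um, min spacing %g um>\n",
    x$name, x$arrangement, x$complex_length_um, x$complex_width_um,
    x$min_spacing_um))
  invisible(x)
}

#' Built-in archetypes
#'
#' Three ready-made archetypes spanning the patterns the toolkit emulates:
#' a large-stoma graminoid in rows (wheat-like, ~60 um complexes), a
#' small-stoma graminoid in rows (rice-like, ~25 um) and a scattered dicot
#' (tomato-like, ~25 um elliptical complexes). Dimensions are model defaults,
#' not literature values.
#'
#' @return A `species_archetype`.
#' @rdname builtin_archetypes
#' @export
archetype_graminoid_large <- function() {
  species_archetype(
    name = "graminoid_large", arrangement = "rows",
    complex_length_um = 60, complex_width_um = 32,
    min_spacing_um = 75, row_pitch_um = 140
  )
}

#' @rdname builtin_archetypes
#' @export
archetype_graminoid_small <- function() {
  species_archetype(
    name = "graminoid_small", arrangement = "rows",
    complex_length_um = 25, complex_width_um = 14,
    min_spacing_um = 32, row_pitch_um = 60
  )
}

#' @rdname builtin_archetypes
#' @export
archetype_dicot <- function() {
  species_archetype(
    name = "dicot", arrangement = "scattered",
    complex_length_um = 26, complex_width_um = 18,
    min_spacing_um = 38, row_pitch_um = 60
  )
}

#' @noRd
get_archetype <- function(name) {
  switch(name,
    graminoid_large = archetype_graminoid_large(),
    graminoid_small = archetype_graminoid_small(),
    dicot = archetype_dicot(),
    stop_stomapipe(
      sprintf("unknown archetype '%s' (built-in: graminoid_large, graminoid_small, dicot)",
              name),
      "stomapipe_config_error")
  )
}
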