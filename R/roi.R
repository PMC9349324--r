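# Ocular magnification correction (Bennett's formula) and the
# fovea-centered annulus region of measurement.

#' Eye biometry for magnification correction
#'
#' @param axial_length_mm ocular axial length in mm (plausible range
#'   20-30 mm).
#' @param camera_factor_p instrument (camera) magnification factor. The
#'   default 3.382 calibrates the formula so that a nominal emmetropic eye
#'   with axial length 24.46 mm is magnification-neutral
#'   (`s_actual == s`); instruments do not publish this constant, so it is
#'   configurable.
#' @param nominal_scan_mm nominal scan width `s` in mm.
#' @return An object of class `eye_biometry`.
#' @export
eye_biometry <- function(axial_length_mm, camera_factor_p = 3.382,
                         nominal_scan_mm = 3.0) {
  assert_number(axial_length_mm, "axial_length_mm")
  if (axial_length_mm < 20 || axial_length_mm > 30)
    abort("axial length %.2f mm outside plausible range [20, 30] mm",
          axial_length_mm)
  assert_number(camera_factor_p, "camera_factor_p", lower = 1e-9)
  assert_number(nominal_scan_mm, "nominal_scan_mm", lower = 1e-9)
  structure(list(axial_length_mm = axial_length_mm,
                 camera_factor_p = camera_factor_p,
                 nominal_scan_mm = nominal_scan_mm),
            class = "eye_biometry")
}

#' Actual scan length by Bennett's formula
#'
#' `s_actual = p * q * s` with the ocular magnification factor
#' `q = 0.01306 * (axial_length - 1.82)`. Longer eyes image a wider
#' retinal patch for the same nominal scan angle, so fixed-millimeter
#' regions of interest must be rescaled per eye.
#'
#' @param biometry an [eye_biometry()].
#' @return Actual scan length in mm.
#' @export
bennett_actual_scan_length <- function(biometry) {
  if (!inherits(biometry, "eye_biometry"))
    abort("`biometry` must be an eye_biometry object")
  q <- 0.01306 * (biometry$axial_length_mm - 1.82)
  biometry$camera_factor_p * q * biometry$nominal_scan_mm
}

#' Physical size of one pixel
#'
#' @param actual_scan_mm actual scan width in mm.
#' @param n_px pixels per image side.
#' @return mm per pixel.
#' @export
pixel_scale <- function(actual_scan_mm, n_px) {
  assert_number(actual_scan_mm, "actual_scan_mm", lower = 1e-9)
  if (!is.numeric(n_px) || length(n_px) != 1L || n_px < 1)
    abort("`n_px` must be a positive pixel count")
  actual_scan_mm / n_px
}

#' Annulus region-of-measurement specification
#'
#' @param inner_diameter_mm inner diameter in mm (default 1.0).
#' @param outer_diameter_mm outer diameter in mm (default 2.5).
#' @param center_px optional `(x, y)` center in 0-based pixel
#'   coordinates; `NULL` means the geometric image center.
#' @return An object of class `annulus_spec`.
#' @export
annulus_spec <- function(inner_diameter_mm = 1.0, outer_diameter_mm = 2.5,
                         center_px = NULL) {
  assert_number(inner_diameter_mm, "inner_diameter_mm", lower = 0)
  assert_number(outer_diameter_mm, "outer_diameter_mm", lower = 0)
  if (inner_diameter_mm >= outer_diameter_mm)
    abort("inner diameter must be smaller than outer diameter")
  structure(list(inner_diameter_mm = inner_diameter_mm,
                 outer_diameter_mm = outer_diameter_mm,
                 center_px = center_px),
            class = "annulus_spec")
}

#' Fovea-centered annulus mask in pixel space
#'
#' The annulus radii, fixed in millimeters on the retina, are converted
#' to pixels with the eye-specific scale (mm per pixel) obtained from
#' Bennett's formula, so that the physical area analyzed is the same for
#' every eye regardless of axial length.
#'
#' @param n_px side length of the square pixel grid.
#' @param spec an [annulus_spec()].
#' @param scale_mm_per_px eye-specific pixel size in mm.
#' @return A [binary_map()] of kind `"annulus"`.
#' @export
annulus_mask <- function(n_px, spec = annulus_spec(), scale_mm_per_px) {
  assert_number(scale_mm_per_px, "scale_mm_per_px", lower = 1e-12)
  r_in <- (spec$inner_diameter_mm / 2) / scale_mm_per_px
  r_out <- (spec$outer_diameter_mm / 2) / scale_mm_per_px
  if (r_out > n_px / 2)
    abort("annulus outer radius (%.1f px) exceeds grid half-width (%.1f px)",
          r_out, n_px / 2)
  ctr <- spec$center_px %||% c((n_px - 1) / 2, (n_px - 1) / 2)
  g <- pixel_centers(n_px)
  d <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2)
  mask <- d >= r_in & d < r_out
  binary_map(mask, "annulus",
             provenance = list(op = "annulus_mask",
                               inner_diameter_mm = spec$inner_diameter_mm,
                               outer_diameter_mm = spec$outer_diameter_mm,
                               scale_mm_per_px = scale_mm_per_px,
                               center_px = ctr))
}
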