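# Parameter types for the synthetic-eye generator.

#' Vessel field parameters
#'
#' Controls one synthetic capillary plexus. `target_density` is the
#' fraction of region pixels that are vessel in the emitted truth mask;
#' for the superficial plexus, `target_density` is the total perfusion
#' density (large vessels included) and the optional
#' `target_density_wo_lv` additionally pins the density outside the
#' dilated large-vessel halo, which makes the generated eye realize both
#' printed perfusion-density rows at once.
#'
#' @param target_density fraction in `[0, 1]`.
#' @param capillary_scale characteristic capillary spacing in px.
#' @param n_large_vessels number of trunk vessels entering from the
#'   image edge (superficial plexus only).
#' @param lv_width_px trunk-vessel stroke width in px.
#' @param noise_sd additive intensity noise SD (grayscale units).
#' @param seed integer RNG seed.
#' @param target_density_wo_lv optional fraction in `[0, 1]`; density of
#'   the truth mask outside the dilated large-vessel halo.
#' @param background_level,vessel_level grayscale levels of background
#'   and capillary pixels; trunk vessels are drawn brighter
#'   (`lv_level`).
#' @param lv_level grayscale level of trunk-vessel pixels.
#' @return An object of class `vessel_field_params`.
#' @export
vessel_field_params <- function(target_density, capillary_scale = 5,
                                n_large_vessels = 0L, lv_width_px = 5L,
                                noise_sd = 10, seed = 1L,
                                target_density_wo_lv = NULL,
                                background_level = 60, vessel_level = 170,
                                lv_level = 230) {
  assert_number(target_density, "target_density", 0, 1)
  assert_number(capillary_scale, "capillary_scale", lower = 1)
  if (n_large_vessels < 0) abort("n_large_vessels must be >= 0")
  assert_number(lv_width_px, "lv_width_px", lower = 1)
  assert_number(noise_sd, "noise_sd", lower = 0)
  if (!is.null(target_density_wo_lv))
    assert_number(target_density_wo_lv, "target_density_wo_lv", 0, 1)
  structure(list(target_density = target_density,
                 capillary_scale = capillary_scale,
                 n_large_vessels = as.integer(n_large_vessels),
                 lv_width_px = as.integer(lv_width_px),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 target_density_wo_lv = target_density_wo_lv,
                 background_level = background_level,
                 vessel_level = vessel_level, lv_level = lv_level),
            class = "vessel_field_params")
}

#' FAZ generator parameters
#'
#' @param area_mm2 target FAZ area (mm^2).
#' @param irregularity boundary perturbation amplitude (0 gives a
#'   circle; the emitted polygon's radial profile is
#'   `R * (1 + irregularity * g(theta))` for a random smooth `g` with
#'   `max |g| = 1`).
#' @param n_vertices polygon resolution.
#' @param seed integer RNG seed (fixes `g`).
#' @param target_circularity optional; when set, `irregularity` is
#'   solved by root-finding so the emitted polygon has this perimeter-
#'   ratio circularity (within 1e-3).
#' @return An object of class `faz_params`.
#' @export
faz_params <- function(area_mm2, irregularity = 0, n_vertices = 180L,
                       seed = 1L, target_circularity = NULL) {
  assert_number(area_mm2, "area_mm2", lower = 1e-6)
  assert_number(irregularity, "irregularity", lower = 0)
  if (n_vertices < 8L) abort("n_vertices must be >= 8")
  if (!is.null(target_circularity))
    assert_number(target_circularity, "target_circularity", lower = 1)
  structure(list(area_mm2 = area_mm2, irregularity = irregularity,
                 n_vertices = as.integer(n_vertices), seed = as.integer(seed),
                 target_circularity = target_circularity),
            class = "faz_params")
}

#' Choriocapillaris texture parameters
#'
#' The emitted image is a granular two-level texture plus noise whose
#' two levels are placed so the image has approximately the requested
#' mean and SD given the void fraction; the flow-void truth mask
#' occupies exactly `deficit_fraction` of the annulus.
#'
#' @param mean_intensity target grayscale mean.
#' @param sd_intensity target grayscale SD (must exceed `noise_sd`).
#' @param deficit_fraction target fraction of annulus pixels that are
#'   flow voids, in `[0, 1]`. Mean-minus-one-SD thresholding can only
#'   re-detect the truth mask when the two texture levels remain
#'   separated, which holds for fractions up to roughly 0.3.
#' @param granule_scale void blob size in px.
#' @param noise_sd additive noise SD.
#' @param seed integer RNG seed.
#' @return An object of class `cc_params`.
#' @export
cc_params <- function(mean_intensity = 160, sd_intensity = 46,
                      deficit_fraction = 0.16, granule_scale = 6,
                      noise_sd = 10, seed = 1L) {
  assert_number(mean_intensity, "mean_intensity", 1, 254)
  assert_number(sd_intensity, "sd_intensity", lower = 1)
  assert_number(deficit_fraction, "deficit_fraction", 0, 1)
  assert_number(granule_scale, "granule_scale", lower = 1)
  if (sd_intensity <= noise_sd)
    abort("sd_intensity must exceed noise_sd")
  structure(list(mean_intensity = mean_intensity,
                 sd_intensity = sd_intensity,
                 deficit_fraction = deficit_fraction,
                 granule_scale = granule_scale, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cc_params")
}
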