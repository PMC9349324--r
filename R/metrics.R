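# Per-eye outcome metrics: perfusion densities, flow deficit, FAZ
# morphometry, and the per-eye composition of the whole pipeline.

density_in_region <- function(num_mask, region_mask) {
  if (!identical(dim(num_mask), dim(region_mask)))
    abort("mask shapes do not match")
  n <- sum(region_mask)
  if (n == 0L) abort("empty annulus region")
  100 * sum(num_mask & region_mask) / n
}

#' Perfusion density inside the annulus
#'
#' Percentage of annulus pixels occupied by binarized vessel signal.
#'
#' @param vessels a [binary_map()] of kind `"vessel"` (or any mask).
#' @param annulus a [binary_map()] of kind `"annulus"`.
#' @return Percent in `[0, 100]`.
#' @export
perfusion_density <- function(vessels, annulus) {
  density_in_region(vessels$mask, annulus$mask)
}

#' Perfusion density with large vessels removed
#'
#' Large vessels plus a safety halo (the mask dilated by
#' `removal_dilate_px`) are removed from the numerator; the annulus
#' denominator is unchanged. The default halo of 8 px (about 0.1 mm)
#' reflects the perivascular capillary-free zone around trunk vessels.
#'
#' @param vessels vessel [binary_map()].
#' @param lv large-vessel [binary_map()].
#' @param annulus annulus [binary_map()].
#' @param removal_dilate_px dilation radius in px (default 8).
#' @return Percent in `[0, 100]`.
#' @export
pd_without_lv <- function(vessels, lv, annulus, removal_dilate_px = 8L) {
  lv_dil <- dilate_mask(lv$mask, removal_dilate_px)
  density_in_region(vessels$mask & !lv_dil, annulus$mask)
}

#' Large-vessel perfusion density
#'
#' @param lv large-vessel [binary_map()].
#' @param annulus annulus [binary_map()].
#' @return Percent in `[0, 100]`.
#' @export
lv_density <- function(lv, annulus) {
  density_in_region(lv$mask, annulus$mask)
}

#' Choriocapillaris flow deficit
#'
#' Percentage of annulus pixels occupied by binarized flow voids.
#'
#' @param voids flow-void [binary_map()].
#' @param annulus annulus [binary_map()].
#' @return Percent in `[0, 100]`.
#' @export
flow_deficit <- function(voids, annulus) {
  density_in_region(voids$mask, annulus$mask)
}

#' FAZ area in physical units
#'
#' Shoelace area of the annotation polygon (vertices in pixel units)
#' converted by the eye-specific pixel scale. The polygon rather than a
#' raster mask is used because raster boundaries systematically distort
#' perimeters and the FAZ outline is a traced curve.
#'
#' @param annotation a [faz_annotation()].
#' @param scale_mm_per_px eye-specific pixel size in mm.
#' @return Area in mm^2.
#' @export
faz_area <- function(annotation, scale_mm_per_px) {
  poly <- annotation$polygon_px
  if (!is_simple_polygon(poly)) abort("FAZ polygon is self-intersecting")
  polygon_area(poly) * scale_mm_per_px^2
}

#' FAZ circularity
#'
#' Ratio of the polygon perimeter to the perimeter of the circle with
#' the same area, `P / (2 * sqrt(pi * A))`. The isoperimetric inequality
#' bounds it below by 1 (up to polygonization error); 1 means a perfect
#' circle and larger values mean a more irregular boundary. The ratio is
#' scale-invariant, so it is computed directly in pixel units.
#'
#' @param annotation a [faz_annotation()].
#' @return Dimensionless ratio >= 1 (up to polygonization tolerance).
#' @export
faz_circularity <- function(annotation) {
  poly <- annotation$polygon_px
  if (!is_simple_polygon(poly)) abort("FAZ polygon is self-intersecting")
  a <- polygon_area(poly)
  if (a <= 0) abort("FAZ polygon has zero area")
  polygon_perimeter(poly) / (2 * sqrt(pi * a))
}

#' Measurement parameters for the per-eye pipeline
#'
#' @param enhancement an [enhancement_params()].
#' @param annulus an [annulus_spec()].
#' @param camera_factor_p Bennett camera factor.
#' @param lv_removal_dilate_px halo radius for large-vessel removal and
#'   CC artifact masking (px).
#' @return An object of class `measure_params`.
#' @export
measure_params <- function(enhancement = enhancement_params(),
                           annulus = annulus_spec(),
                           camera_factor_p = 3.382,
                           lv_removal_dilate_px = 8L) {
  structure(list(enhancement = enhancement, annulus = annulus,
                 camera_factor_p = camera_factor_p,
                 lv_removal_dilate_px = as.integer(lv_removal_dilate_px)),
            class = "measure_params")
}

#' Compute all per-eye outcomes for one eye
#'
#' Runs the full per-eye pipeline: Bennett magnification correction,
#' annulus construction, large-vessel segmentation on the SCP, plexus
#' binarization with FAZ masking, choriocapillaris flow-void
#' binarization with large-vessel artifact removal, and the nine outcome
#' metrics.
#'
#' @param scp,dcp,cc [en_face_angiogram()] objects for the three slabs.
#' @param faz_scp,faz_dcp [faz_annotation()] objects.
#' @param biometry an [eye_biometry()].
#' @param params a [measure_params()].
#' @return One-row data frame with columns `pd_scp_pct`,
#'   `pd_scp_wo_lv_pct`, `pd_lv_pct`, `pd_dcp_pct`, `faz_area_s_mm2`,
#'   `faz_circ_s`, `faz_area_d_mm2`, `faz_circ_d`, `fd_cc_pct`, plus
#'   provenance columns `scale_mm_per_px` and `annulus_px`.
#' @export
compute_eye_metrics <- function(scp, dcp, cc, faz_scp, faz_dcp, biometry,
                                params = measure_params()) {
  for (nm in c("scp", "dcp", "cc")) {
    obj <- switch(nm, scp = scp, dcp = dcp, cc = cc)
    if (!inherits(obj, "en_face_angiogram"))
      abort("missing or invalid slab input: %s", toupper(nm))
  }
  n_px <- scp$n_px
  scale <- pixel_scale(bennett_actual_scan_length(
    eye_biometry(biometry$axial_length_mm, params$camera_factor_p,
                 scp$nominal_scan_mm)), n_px)
  ann <- annulus_mask(n_px, params$annulus, scale)
  faz_s_mask <- rasterize_faz(faz_scp, n_px)
  faz_d_mask <- rasterize_faz(faz_dcp, n_px)
  lv <- segment_large_vessels(scp, params$enhancement)
  vess_s <- binarize_plexus(scp, faz_s_mask)
  vess_d <- binarize_plexus(dcp, faz_d_mask)
  voids <- binarize_flow_voids(cc, lv, params$lv_removal_dilate_px)
  data.frame(
    pd_scp_pct = perfusion_density(vess_s, ann),
    pd_scp_wo_lv_pct = pd_without_lv(vess_s, lv, ann,
                                     params$lv_removal_dilate_px),
    pd_lv_pct = lv_density(lv, ann),
    pd_dcp_pct = perfusion_density(vess_d, ann),
    faz_area_s_mm2 = faz_area(faz_scp, scale),
    faz_circ_s = faz_circularity(faz_scp),
    faz_area_d_mm2 = faz_area(faz_dcp, scale),
    faz_circ_d = faz_circularity(faz_dcp),
    fd_cc_pct = flow_deficit(voids, ann),
    scale_mm_per_px = scale,
    annulus_px = sum(ann$mask)
  )
}

#' Names of the nine per-eye outcome metrics
#' @return Character vector.
#' @export
outcome_names <- function() {
  c("pd_scp_pct", "pd_scp_wo_lv_pct", "pd_lv_pct", "pd_dcp_pct",
    "faz_area_s_mm2", "faz_circ_s", "faz_area_d_mm2", "faz_circ_d",
    "fd_cc_pct")
}
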