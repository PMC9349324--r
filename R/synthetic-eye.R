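# Assembly of one synthetic eye: three slab images, two FAZ outlines,
# the trunk-vessel truth mask, and exact ground-truth outcome metrics.

#' Generate one synthetic eye
#'
#' Builds the three en-face slab images (SCP with trunk vessels, DCP,
#' choriocapillaris), the two FAZ annotations, and the ground-truth
#' masks, then derives the ground-truth outcome metrics by direct pixel
#' counting on the emitted masks inside the eye's magnification-
#' corrected annulus, so truth and masks are exactly self-consistent.
#'
#' Density targets are realized exactly (to one pixel) inside the
#' annulus: `vf_scp$target_density` is the total superficial perfusion
#' density, `vf_scp$target_density_wo_lv` the density outside the
#' dilated trunk-vessel halo, `vf_dcp$target_density` the deep
#' perfusion density, and `cc$deficit_fraction` the flow-deficit
#' fraction. The FAZ region is carved vessel-free in both plexuses.
#'
#' @param vf_scp,vf_dcp [vessel_field_params()] for the two plexuses.
#' @param faz_s,faz_d [faz_params()] for the two FAZ outlines.
#' @param cc a [cc_params()].
#' @param biometry an [eye_biometry()].
#' @param n_px grid side length (default 245).
#' @param annulus an [annulus_spec()].
#' @param lv_halo_px trunk-vessel halo radius in px used for the
#'   without-large-vessel truth and the CC artifact region (default 8,
#'   matching the measurement default).
#' @return List of class `synthetic_eye` with elements `scp`, `dcp`,
#'   `cc` ([en_face_angiogram()]), `faz_scp`, `faz_dcp`
#'   ([faz_annotation()]), `lv_truth`, `vessel_scp_truth`,
#'   `vessel_dcp_truth`, `void_truth` ([binary_map()]), `annulus`,
#'   `biometry`, `scale_mm_per_px` and `truth` (one-row data frame of
#'   ground-truth outcomes).
#' @export
generate_eye <- function(vf_scp, vf_dcp, faz_s, faz_d, cc,
                         biometry = eye_biometry(23.3), n_px = 245L,
                         annulus = annulus_spec(), lv_halo_px = 8L) {
  scale <- pixel_scale(bennett_actual_scan_length(biometry), n_px)
  ann <- annulus_mask(n_px, annulus, scale)
  ann_n <- sum(ann$mask)

  fz_s <- generate_faz(faz_s, scale, n_px, slab = "SCP")
  fz_d <- generate_faz(faz_d, scale, n_px, slab = "DCP")
  faz_s_mask <- rasterize_faz(fz_s, n_px)$mask
  faz_d_mask <- rasterize_faz(fz_d, n_px)$mask

  # ---- superficial plexus with trunk vessels -------------------------------
  lv <- withr::with_seed(spawn_seed(vf_scp$seed, 11L), {
    draw_large_vessels(vf_scp$n_large_vessels, vf_scp$lv_width_px, n_px)
  })
  lv <- lv & !faz_s_mask
  halo <- dilate_mask(lv, lv_halo_px)
  lv_ann <- sum(lv & ann$mask)

  wo_lv_target <- vf_scp$target_density_wo_lv %||% vf_scp$target_density
  k_out <- round(wo_lv_target * ann_n)
  k_ring <- round(vf_scp$target_density * ann_n) - lv_ann - k_out

  scp_parts <- withr::with_seed(vf_scp$seed, {
    f <- bandpass_field(n_px, vf_scp$capillary_scale)
    region_out <- ann$mask & !faz_s_mask & !halo
    cap_out <- if (k_out > 0)
      nodal_band_mask(f, region_out, min(k_out, sum(region_out)),
                      support = !halo & !faz_s_mask)
    else matrix(FALSE, n_px, n_px)
    region_ring <- ann$mask & !faz_s_mask & halo & !lv
    ring_support <- halo & !lv & !faz_s_mask
    cap_ring <- if (k_ring > 0 && sum(region_ring) > 0)
      nodal_band_mask(f, region_ring, min(k_ring, sum(region_ring)),
                      support = ring_support)
    else matrix(FALSE, n_px, n_px)
    noise <- vf_scp$noise_sd * matrix(rnorm(n_px * n_px), n_px, n_px)
    list(cap = cap_out | cap_ring, noise = noise)
  })
  cap_s <- scp_parts$cap
  vessel_s <- (cap_s | lv) & !faz_s_mask
  img_s <- vf_scp$background_level +
    (vf_scp$vessel_level - vf_scp$background_level) * cap_s
  img_s[lv] <- vf_scp$lv_level
  img_s <- quantize8(img_s + scp_parts$noise)

  # ---- deep plexus ---------------------------------------------------------
  dcp_parts <- withr::with_seed(vf_dcp$seed, {
    f <- bandpass_field(n_px, vf_dcp$capillary_scale)
    region <- ann$mask & !faz_d_mask
    k <- round(vf_dcp$target_density * ann_n)
    cap <- if (k > 0)
      nodal_band_mask(f, region, min(k, sum(region)), support = !faz_d_mask)
    else matrix(FALSE, n_px, n_px)
    noise <- vf_dcp$noise_sd * matrix(rnorm(n_px * n_px), n_px, n_px)
    list(cap = cap, noise = noise)
  })
  vessel_d <- dcp_parts$cap
  img_d <- quantize8(vf_dcp$background_level +
                       (vf_dcp$vessel_level - vf_dcp$background_level) *
                       vessel_d + dcp_parts$noise)

  # ---- choriocapillaris ----------------------------------------------------
  cc_out <- withr::with_seed(cc$seed, {
    f <- bandpass_field(n_px, cc$granule_scale)
    region <- ann$mask & !halo
    k <- round(cc$deficit_fraction * ann_n)
    if (k > sum(region))
      abort("deficit_fraction %.2f unreachable: annulus outside the vessel halo has only %d px",
            cc$deficit_fraction, sum(region))
    voids_all <- if (k > 0) {
      vals <- sort(f[region], partial = k)[k]  # low tail of the field
      f <= vals
    } else matrix(FALSE, n_px, n_px)
    frac <- max(mean(voids_all), 1e-6)
    delta <- sqrt(max(cc$sd_intensity^2 - cc$noise_sd^2, 1) /
                    (frac * (1 - frac)))
    hi <- cc$mean_intensity + frac * delta
    lo <- hi - delta
    img <- hi - delta * voids_all
    img[lv] <- max(lo - 10, 0)  # trunk-vessel shadow artifact
    img <- quantize8(img + cc$noise_sd * matrix(rnorm(n_px * n_px), n_px, n_px))
    list(img = img, voids = voids_all & !halo)
  })

  # ---- ground truth by direct counting ------------------------------------
  truth <- data.frame(
    pd_scp_pct = 100 * sum(vessel_s & ann$mask) / ann_n,
    pd_scp_wo_lv_pct = 100 * sum(vessel_s & !halo & ann$mask) / ann_n,
    pd_lv_pct = 100 * lv_ann / ann_n,
    pd_dcp_pct = 100 * sum(vessel_d & ann$mask) / ann_n,
    faz_area_s_mm2 = faz_area(fz_s, scale),
    faz_circ_s = faz_circularity(fz_s),
    faz_area_d_mm2 = faz_area(fz_d, scale),
    faz_circ_d = faz_circularity(fz_d),
    fd_cc_pct = 100 * sum(cc_out$voids & ann$mask) / ann_n
  )

  nominal <- biometry$nominal_scan_mm
  structure(list(
    scp = en_face_angiogram(img_s, "SCP", nominal),
    dcp = en_face_angiogram(img_d, "DCP", nominal),
    cc = en_face_angiogram(cc_out$img, "CC", nominal),
    faz_scp = fz_s, faz_dcp = fz_d,
    lv_truth = binary_map(lv, "large_vessel",
                          provenance = list(op = "generate_eye")),
    vessel_scp_truth = binary_map(vessel_s, "vessel"),
    vessel_dcp_truth = binary_map(vessel_d, "vessel"),
    void_truth = binary_map(cc_out$voids, "flow_void"),
    annulus = ann, biometry = biometry, scale_mm_per_px = scale,
    truth = truth
  ), class = "synthetic_eye")
}
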