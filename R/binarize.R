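# Intensity binarization: plexus vessels at the image mean, and
# choriocapillaris flow voids at one standard deviation below the mean.

#' Binarize a capillary plexus at its mean intensity
#'
#' A pixel is vessel when its intensity is greater than or equal to the
#' mean intensity of the whole image (ties count as vessel, which fixes
#' the degenerate constant-image case); pixels inside the FAZ mask are
#' then set to non-vessel. The mean is invariant in rank under positive
#' affine rescaling of the intensities, so the mask is too.
#'
#' @param img an [en_face_angiogram()] with slab `"SCP"` or `"DCP"`.
#' @param faz optional [binary_map()] of kind `"faz"`, same shape.
#' @return A [binary_map()] of kind `"vessel"`.
#' @export
binarize_plexus <- function(img, faz = NULL) {
  if (!inherits(img, "en_face_angiogram") || !(img$slab %in% c("SCP", "DCP")))
    abort("plexus binarization requires an SCP or DCP angiogram")
  thr <- mean(img$pixels)
  mask <- img$pixels >= thr
  if (!is.null(faz)) {
    if (!identical(dim(faz$mask), dim(mask)))
      abort("FAZ mask shape does not match the image")
    mask[faz$mask] <- FALSE
  }
  binary_map(mask, "vessel",
             provenance = list(op = "binarize_plexus", slab = img$slab,
                               threshold = thr, faz_masked = !is.null(faz)))
}

#' Binarize choriocapillaris flow voids
#'
#' Large-vessel artifacts (the SCP-derived large-vessel map dilated by
#' `artifact_dilate_px`) are excluded from both the statistics and the
#' output; over the remaining pixels a flow void is a pixel strictly
#' below mean minus one (sample) standard deviation.
#'
#' @param cc an [en_face_angiogram()] with slab `"CC"`.
#' @param lv_artifact optional [binary_map()] of kind `"large_vessel"`.
#' @param artifact_dilate_px dilation radius (px) applied to the
#'   large-vessel map before exclusion (default 8).
#' @return A [binary_map()] of kind `"flow_void"`; excluded pixels are
#'   `FALSE` and the exclusion mask is recorded in the provenance.
#' @export
binarize_flow_voids <- function(cc, lv_artifact = NULL,
                                artifact_dilate_px = 8L) {
  if (!inherits(cc, "en_face_angiogram") || cc$slab != "CC")
    abort("flow-void binarization requires a CC angiogram")
  excl <- matrix(FALSE, nrow(cc$pixels), ncol(cc$pixels))
  if (!is.null(lv_artifact)) {
    if (!identical(dim(lv_artifact$mask), dim(cc$pixels)))
      abort("large-vessel mask shape does not match the CC image")
    excl <- dilate_mask(lv_artifact$mask, artifact_dilate_px)
  }
  valid <- !excl
  if (!any(valid)) abort("large-vessel mask covers the whole image")
  vals <- cc$pixels[valid]
  m <- mean(vals)
  s <- sd(vals)  # sample SD; negligible vs population SD at 60,025 px
  thr <- m - s
  mask <- valid & (cc$pixels < thr)
  binary_map(mask, "flow_void",
             provenance = list(op = "binarize_flow_voids", mean = m, sd = s,
                               threshold = thr,
                               artifact_dilate_px = artifact_dilate_px,
                               n_excluded = sum(excl)))
}
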