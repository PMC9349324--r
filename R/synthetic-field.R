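# Capillary-bed texture and trunk-vessel strokes.

#' Band-pass Gaussian random field
#' @noRd
bandpass_field <- function(n_px, scale_px) {
  z <- matrix(rnorm(n_px * n_px), n_px, n_px)
  s1 <- max(scale_px / 2, 0.8)
  EBImage::gblur(z, sigma = s1) - EBImage::gblur(z, sigma = 2 * s1)
}

#' Quantile threshold on |field| hitting an exact pixel count in a region
#'
#' Returns the mask `|field| <= t` (applied over `support`) where `t` is
#' chosen so that exactly `k` pixels of `region` are on. The level sets
#' of `|field|` near zero are thin bands along the nodal lines of the
#' field, giving a connected, capillary-like mesh at any density.
#' @noRd
nodal_band_mask <- function(field, region, k, support = NULL) {
  af <- abs(field)
  n_region <- sum(region)
  k <- as.integer(round(k))
  if (k <= 0L) return(matrix(FALSE, nrow(field), ncol(field)))
  if (k > n_region) abort("requested density exceeds region capacity")
  vals <- sort(af[region], partial = k)[k]
  m <- af <= vals
  if (!is.null(support)) m <- m & support
  m
}

#' Generate a synthetic capillary bed
#'
#' Emits a grayscale plexus-like image and its ground-truth vessel mask.
#' The mask is the set of pixels where a band-pass Gaussian random field
#' is closest to zero (the field's nodal bands), thresholded at the
#' quantile that makes the mask density match `target_density` exactly
#' (to within one pixel) inside `region` - the whole grid by default.
#'
#' @param params a [vessel_field_params()].
#' @param n_px side length of the square grid.
#' @param region optional logical matrix; density is matched inside it.
#' @return List with `image` (numeric matrix, 8-bit grayscale levels)
#'   and `mask` (logical truth matrix).
#' @export
generate_capillary_bed <- function(params, n_px = 245L, region = NULL) {
  if (!inherits(params, "vessel_field_params"))
    abort("`params` must be vessel_field_params")
  if (n_px < 8L) abort("grid too small")
  if (params$capillary_scale > n_px / 4)
    abort("capillary_scale %.1f px too coarse for a %d px grid: density is not controllable",
          params$capillary_scale, n_px)
  if (is.null(region)) region <- matrix(TRUE, n_px, n_px)
  withr::with_seed(params$seed, {
    d <- params$target_density
    if (d >= 1) {
      mask <- matrix(TRUE, n_px, n_px)
    } else if (d <= 0) {
      mask <- matrix(FALSE, n_px, n_px)
    } else {
      f <- bandpass_field(n_px, params$capillary_scale)
      mask <- nodal_band_mask(f, region, d * sum(region))
    }
    img <- params$background_level +
      (params$vessel_level - params$background_level) * mask +
      params$noise_sd * matrix(rnorm(n_px * n_px), n_px, n_px)
    list(image = quantize8(img), mask = mask)
  })
}

#' Draw trunk-vessel strokes entering from the image edge
#'
#' Each stroke starts at a random edge point, heads inward with smoothly
#' varying direction, and is steered away from the fovea (large vessels
#' do not cross the foveal center). The polyline is dilated to the
#' requested caliber.
#'
#' @param n_vessels number of strokes.
#' @param width_px stroke caliber in px.
#' @param n_px grid side length.
#' @param avoid_center_px minimum distance of the path from the image
#'   center.
#' @return Logical mask. Uses the current RNG state.
#' @export
draw_large_vessels <- function(n_vessels, width_px = 5L, n_px = 245L,
                               avoid_center_px = 50) {
  mask <- matrix(FALSE, n_px, n_px)
  if (n_vessels < 1L) return(mask)
  ctr <- (n_px - 1) / 2
  for (v in seq_len(n_vessels)) {
    side <- sample.int(4L, 1L)
    t0 <- runif(1, 0.1, 0.9) * (n_px - 1)
    pos <- switch(side,
                  c(t0, 0), c(t0, n_px - 1), c(0, t0), c(n_px - 1, t0))
    # aim past an off-center waypoint so paths cross the parafovea
    ang <- runif(1, 0, 2 * pi)
    way <- c(ctr, ctr) + runif(1, avoid_center_px + 15, n_px * 0.38) *
      c(cos(ang), sin(ang))
    heading <- atan2(way[2] - pos[2], way[1] - pos[1])
    for (step in seq_len(3L * n_px)) {
      heading <- heading + rnorm(1, 0, 0.07)
      d2c <- sqrt(sum((pos - ctr)^2))
      if (d2c < avoid_center_px + 12) {
        # steer away from the fovea
        away <- atan2(pos[2] - ctr, pos[1] - ctr)
        delta <- atan2(sin(away - heading), cos(away - heading))
        heading <- heading + 0.25 * delta
      }
      pos <- pos + 2 * c(cos(heading), sin(heading))
      if (any(pos < 0) || any(pos > n_px - 1)) break
      xi <- round(pos[1]) + 1L; yi <- round(pos[2]) + 1L
      mask[yi, xi] <- TRUE
      # thick pen: mark the 3x3 neighbourhood to avoid gaps at step 2
      mask[clamp(yi + (-1:1), 1, n_px), clamp(xi + (-1:1), 1, n_px)] <- TRUE
    }
  }
  r <- max(0L, as.integer(floor((width_px - 3) / 2)))
  dilate_mask(mask, r)
}
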