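# Large-vessel enhancement on the superficial plexus: an oriented Gabor
# filter bank combined with multiscale Hessian (Frangi-style) vesselness.

#' Enhancement parameters for large-vessel segmentation
#'
#' Defaults reflect trunk-vessel calibers of roughly 4-10 px at 245-px
#' sampling of a 3-mm scan.
#'
#' @param gabor_wavelengths_px Gabor carrier wavelengths in px.
#' @param gabor_orientations number of evenly spaced orientations (>= 4).
#' @param hessian_scales_px Gaussian scales (sigma, px) for the Hessian.
#' @param combination combination rule for the two responses; only
#'   `"product"` (pixelwise product of min-max-normalized responses,
#'   rewarding agreement) is implemented.
#' @param min_component_px connected components smaller than this are
#'   dropped from the binarized large-vessel map.
#' @param min_caliber_px minimum large-vessel caliber; the binarized map
#'   is morphologically opened with a disc of this diameter so that
#'   capillary-scale strokes cannot survive.
#' @return An object of class `enhancement_params`.
#' @export
enhancement_params <- function(gabor_wavelengths_px = c(8, 12, 16),
                               gabor_orientations = 8L,
                               hessian_scales_px = c(3, 5, 7),
                               combination = "product",
                               min_component_px = 100L,
                               min_caliber_px = 5L) {
  if (length(gabor_wavelengths_px) < 1L || any(gabor_wavelengths_px <= 0))
    abort("gabor wavelengths must be positive")
  if (gabor_orientations < 4L) abort("need at least 4 orientations")
  if (length(hessian_scales_px) < 1L || any(hessian_scales_px <= 0))
    abort("hessian scales must be positive")
  combination <- match.arg(combination, "product")
  structure(list(gabor_wavelengths_px = gabor_wavelengths_px,
                 gabor_orientations = as.integer(gabor_orientations),
                 hessian_scales_px = hessian_scales_px,
                 combination = combination,
                 min_component_px = as.integer(min_component_px),
                 min_caliber_px = as.integer(min_caliber_px)),
            class = "enhancement_params")
}

#' Zero-mean real Gabor kernel
#'
#' Even (cosine) Gabor with sigma = 0.56 * wavelength and aspect ratio
#' 0.5; the kernel mean is removed so a constant image gives zero
#' response.
#' @noRd
gabor_kernel <- function(wavelength, theta, gamma = 0.5) {
  sigma <- 0.56 * wavelength
  half <- ceiling(3 * sigma)
  xs <- -half:half
  x <- matrix(rep(xs, each = length(xs)), nrow = length(xs))  # [y, x]
  y <- matrix(rep(xs, times = length(xs)), nrow = length(xs))
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  k <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2)) *
    cos(2 * pi * xr / wavelength)
  k - mean(k)
}

#' Maximum-magnitude Gabor filter-bank response
#'
#' Convolves the image with an even Gabor bank over all combinations of
#' wavelength and orientation and keeps the per-pixel maximum absolute
#' response.
#'
#' @param img an [en_face_angiogram()] or numeric matrix.
#' @param wavelengths_px carrier wavelengths in px.
#' @param n_orientations number of evenly spaced orientations in
#'   `[0, pi)`.
#' @return List with `response` (non-negative matrix) and `orientation`
#'   (argmax filter angle, radians).
#' @export
gabor_response <- function(img, wavelengths_px = c(8, 12, 16),
                           n_orientations = 8L) {
  px <- if (inherits(img, "en_face_angiogram")) img$pixels else img
  if (length(px) == 0L) abort("empty image")
  if (length(wavelengths_px) < 1L || n_orientations < 1L)
    abort("empty filter bank")
  thetas <- seq(0, pi, length.out = n_orientations + 1L)[seq_len(n_orientations)]
  best <- matrix(0, nrow(px), ncol(px))
  arg <- matrix(0, nrow(px), ncol(px))
  for (wl in wavelengths_px) {
    for (th in thetas) {
      r <- abs(EBImage::filter2(px, gabor_kernel(wl, th)))
      upd <- r > best
      best[upd] <- r[upd]
      # the even Gabor oscillates across the stroke: the stroke runs
      # perpendicular to the filter axis
      arg[upd] <- (th + pi / 2) %% pi
    }
  }
  list(response = best, orientation = arg)
}

#' Gaussian second-derivative kernels for one scale
#' @noRd
hessian_kernels <- function(sigma) {
  half <- ceiling(3 * sigma)
  xs <- -half:half
  x <- matrix(rep(xs, each = length(xs)), nrow = length(xs))
  y <- matrix(rep(xs, times = length(xs)), nrow = length(xs))
  g <- exp(-(x^2 + y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  zs <- function(k) k - mean(k)  # truncation leaves a tiny DC term
  list(
    xx = zs(g * (x^2 - sigma^2) / sigma^4),
    yy = zs(g * (y^2 - sigma^2) / sigma^4),
    xy = g * x * y / sigma^4
  )
}

#' Multiscale Hessian vesselness (Frangi)
#'
#' Bright-on-dark tubular-structure response in `[0, 1]`, maximal over
#' the offered scales. Scale-normalized (gamma = 2) second derivatives;
#' blobness beta = 0.5; the structureness cutoff is half the maximum
#' Frobenius norm over the whole multiscale stack, so the response
#' magnitude stays comparable across scales and the strongest response
#' selects the scale matching the vessel caliber.
#'
#' @param img an [en_face_angiogram()] or numeric matrix.
#' @param scales_px Gaussian scales (sigma, px).
#' @return Non-negative matrix in `[0, 1]`; attribute `"scale"` holds
#'   the per-pixel argmax scale.
#' @export
hessian_vesselness <- function(img, scales_px = c(3, 5, 7)) {
  px <- if (inherits(img, "en_face_angiogram")) img$pixels else img
  if (any(scales_px <= 0)) abort("scales must be positive")
  beta <- 0.5
  per_scale <- lapply(scales_px, function(s) {
    k <- hessian_kernels(s)
    hxx <- s^2 * EBImage::filter2(px, k$xx)
    hyy <- s^2 * EBImage::filter2(px, k$yy)
    hxy <- s^2 * EBImage::filter2(px, k$xy)
    tmp <- sqrt(pmax((hxx - hyy)^2 + 4 * hxy^2, 0))
    l1 <- (hxx + hyy + tmp) / 2   # larger algebraic eigenvalue
    l2 <- (hxx + hyy - tmp) / 2
    swap <- abs(l1) > abs(l2)    # order by magnitude: lam2 = larger |.|
    lam1 <- ifelse(swap, l2, l1)
    lam2 <- ifelse(swap, l1, l2)
    list(S2 = lam1^2 + lam2^2,
         rb2 = ifelse(lam2 != 0, (lam1 / lam2)^2, 0),
         dark = lam2 >= 0)
  })
  out <- matrix(0, nrow(px), ncol(px))
  argscale <- matrix(scales_px[1], nrow(px), ncol(px))
  cmax <- max(vapply(per_scale, function(z) max(sqrt(z$S2)), numeric(1)))
  # floor against pure round-off on structureless images
  if (cmax <= 1e-8 * (max(abs(px)) + 1)) {
    attr(out, "scale") <- argscale
    return(out)
  }
  c2 <- (cmax / 2)^2
  for (i in seq_along(per_scale)) {
    z <- per_scale[[i]]
    v <- exp(-z$rb2 / (2 * beta^2)) * (1 - exp(-z$S2 / (2 * c2)))
    v[z$dark] <- 0  # bright vessels: strongly negative lam2
    upd <- v > out
    out[upd] <- v[upd]
    argscale[upd] <- scales_px[i]
  }
  attr(out, "scale") <- argscale
  out
}

#' Min-max normalization to [0, 1]
#' @noRd
norm01 <- function(x) {
  r <- range(x)
  if (r[2] <= r[1]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' Otsu threshold of a grayscale sample (256 bins over [0, 255])
#' @noRd
otsu_threshold <- function(v) {
  h <- tabulate(pmin(pmax(floor(v), 0), 255) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  which.max(sb2) - 1L  # lower edge of the upper class
}

#' Segment large vessels on the superficial plexus
#'
#' Combines the Gabor and Hessian responses (pixelwise product of
#' min-max-normalized responses), binarizes the combined response at its
#' mean, and refines the candidate map: trunk vessels carry the
#' brightest flow signal, so candidates are intersected with the upper
#' Otsu class of the vessel-pixel intensities; small gaps are closed,
#' the map is opened with a disc of the minimum trunk caliber so that
#' capillary-scale strokes vanish, and connected components below the
#' minimum size are dropped so only trunk vessels remain.
#'
#' @param scp an [en_face_angiogram()] with slab `"SCP"`.
#' @param params an [enhancement_params()].
#' @return A [binary_map()] of kind `"large_vessel"`.
#' @export
segment_large_vessels <- function(scp, params = enhancement_params()) {
  if (!inherits(scp, "en_face_angiogram") || scp$slab != "SCP")
    abort("large-vessel segmentation requires an SCP angiogram")
  gb <- gabor_response(scp, params$gabor_wavelengths_px,
                       params$gabor_orientations)$response
  hv <- hessian_vesselness(scp, params$hessian_scales_px)
  combined <- norm01(gb) * norm01(hv)
  cand <- combined >= mean(combined)
  vessel_px <- scp$pixels >= mean(scp$pixels)
  bright_thr <- if (any(vessel_px)) otsu_threshold(scp$pixels[vessel_px])
  else mean(scp$pixels)
  cand <- cand & vessel_px & (scp$pixels >= bright_thr)
  if (any(cand)) {
    cand <- EBImage::closing(cand * 1, disc_brush(1L)) > 0.5
    op_brush <- EBImage::makeBrush(params$min_caliber_px, shape = "disc")
    cand <- EBImage::opening(cand * 1, op_brush) > 0.5
  }
  if (any(cand)) {
    lab <- EBImage::bwlabel(cand * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= params$min_component_px)
    cand <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  }
  binary_map(cand, "large_vessel",
             provenance = list(op = "segment_large_vessels",
                               gabor_wavelengths_px = params$gabor_wavelengths_px,
                               gabor_orientations = params$gabor_orientations,
                               hessian_scales_px = params$hessian_scales_px,
                               combination = params$combination,
                               min_component_px = params$min_component_px,
                               min_caliber_px = params$min_caliber_px))
}
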