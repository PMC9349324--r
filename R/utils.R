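#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message, no call
#' @noRd
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Check a scalar numeric
#' @noRd
assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    abort("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

#' Clamp values into a range
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Disc structuring element of a given dilation radius (in pixels)
#' @noRd
disc_brush <- function(radius_px) {
  size <- 2L * as.integer(radius_px) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

#' Dilate a logical matrix by a disc of the given radius; radius 0 is a no-op
#' @noRd
dilate_mask <- function(mask, radius_px) {
  if (radius_px <= 0 || !any(mask)) return(mask)
  out <- EBImage::dilate(mask * 1, disc_brush(radius_px))
  out > 0.5
}

#' Pixel-center coordinate grids (0-based: x rightward, y downward)
#'
#' Matrices are indexed `[y + 1, x + 1]` throughout the package.
#' @noRd
pixel_centers <- function(n_px) {
  x <- matrix(rep(0:(n_px - 1L), each = n_px), nrow = n_px)
  y <- matrix(rep(0:(n_px - 1L), times = n_px), nrow = n_px)
  list(x = x, y = y)
}

#' Deterministic per-item seed derived from a master seed
#'
#' Simple documented counter scheme; keeps seeds inside 32-bit range.
#' @noRd
spawn_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 7919 + index * 104729) %% 2147483647)
}

#' Round to 8-bit grayscale
#' @noRd
quantize8 <- function(x) round(clamp(x, 0, 255))
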