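# Synthetic FAZ outlines: star-shaped polygons with controllable area
# and boundary irregularity (standing in for a human grader's tracing).

#' Random smooth angular profile with max |g| = 1
#' @noRd
faz_profile <- function(n_vertices, seed) {
  withr::with_seed(seed, {
    th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[seq_len(n_vertices)]
    g <- rep(0, n_vertices)
    for (k in 2:8) {
      g <- g + rnorm(1, 0, 1 / k) * cos(k * th) +
        rnorm(1, 0, 1 / k) * sin(k * th)
    }
    list(theta = th, g = g / max(abs(g)))
  })
}

#' Polygon for a given amplitude of the radial perturbation
#' @noRd
faz_polygon_at <- function(prof, amp, r0_px, center_px, target_area_px2) {
  rad <- r0_px * (1 + pmax(amp * prof$g, -0.85))
  poly <- cbind(center_px[1] + rad * cos(prof$theta),
                center_px[2] + rad * sin(prof$theta))
  # rescale about the centroid so the shoelace area is exact;
  # circularity is scale-invariant so this does not disturb the shape
  a <- polygon_area(poly)
  ctr <- colMeans(poly)
  sweep(poly, 2, ctr) * sqrt(target_area_px2 / a) +
    matrix(ctr, nrow(poly), 2, byrow = TRUE)
}

#' Generate a synthetic FAZ annotation
#'
#' Builds a simple star-shaped polygon of exactly the requested area
#' whose boundary is a smooth random radial perturbation of a circle.
#' With `irregularity = 0` the polygon is a regular n-gon (circularity
#' 1 up to polygonization error); larger amplitudes give progressively
#' less circular outlines. When `target_circularity` is set in the
#' parameters, the amplitude is solved by root-finding instead.
#'
#' @param params a [faz_params()].
#' @param scale_mm_per_px pixel size in mm.
#' @param n_px grid side length (the polygon must fit inside).
#' @param slab slab label for the annotation.
#' @param center_px `(x, y)` center, default the image center.
#' @return A [faz_annotation()]; attribute `irregularity` records the
#'   amplitude actually used.
#' @export
generate_faz <- function(params, scale_mm_per_px, n_px = 245L,
                         slab = "SCP", center_px = NULL) {
  if (!inherits(params, "faz_params")) abort("`params` must be faz_params")
  center_px <- center_px %||% c((n_px - 1) / 2, (n_px - 1) / 2)
  r0 <- sqrt(params$area_mm2 / pi) / scale_mm_per_px
  target_area_px2 <- params$area_mm2 / scale_mm_per_px^2
  prof <- faz_profile(params$n_vertices, params$seed)
  amp_max <- 2.5
  circ_of <- function(amp) {
    poly <- faz_polygon_at(prof, amp, r0, center_px, target_area_px2)
    polygon_perimeter(poly) / (2 * sqrt(pi * polygon_area(poly)))
  }
  amp <- params$irregularity
  if (!is.null(params$target_circularity)) {
    tc <- params$target_circularity
    if (tc <= circ_of(0)) {
      amp <- 0
    } else if (tc >= circ_of(amp_max)) {
      amp <- amp_max
      warning(sprintf("target circularity %.3f beyond reachable %.3f; using maximum amplitude",
                      tc, circ_of(amp_max)))
    } else {
      amp <- uniroot(function(a) circ_of(a) - tc, c(0, amp_max),
                     tol = 1e-6)$root
    }
  }
  poly <- faz_polygon_at(prof, amp, r0, center_px, target_area_px2)
  if (any(poly < 0) || any(poly > n_px - 1))
    abort("FAZ polygon (area %.2f mm^2) does not fit inside the %d px grid",
          params$area_mm2, n_px)
  if (!is_simple_polygon(poly))
    abort("generated FAZ polygon self-intersects; reduce irregularity")
  ann <- faz_annotation(poly, slab = slab)
  attr(ann, "irregularity") <- amp
  ann
}
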