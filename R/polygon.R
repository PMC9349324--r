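# Planar polygon geometry for FAZ morphometry. Vertices are n x 2
# matrices of (x, y); polygons are implicitly closed.

#' Shoelace area of a simple polygon
#' @param poly n x 2 vertex matrix.
#' @return Unsigned area in squared vertex units.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Perimeter of a closed polygon
#' @param poly n x 2 vertex matrix.
#' @return Total edge length.
#' @export
polygon_perimeter <- function(poly) {
  poly <- as.matrix(poly)
  d <- poly - poly[c(2:nrow(poly), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' Pairwise segment intersection test over all non-adjacent edge pairs.
#' @param poly n x 2 vertex matrix.
#' @return `TRUE` if no two non-adjacent edges intersect.
#' @export
is_simple_polygon <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  p <- poly
  q <- poly[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    # skip adjacent edges (share a vertex)
    j <- if (i == 1L) seq(i + 2L, n - 1L) else seq(i + 2L, n)
    d1 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], p[j, 1], p[j, 2])
    d2 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], q[j, 1], q[j, 2])
    d3 <- cross(p[j, 1], p[j, 2], q[j, 1], q[j, 2], p[i, 1], p[i, 2])
    d4 <- cross(p[j, 1], p[j, 2], q[j, 1], q[j, 2], q[i, 1], q[i, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Rasterize a FAZ polygon onto a pixel grid
#'
#' Scanline even-odd fill: a pixel belongs to the mask exactly when its
#' center (0-based integer coordinates) lies inside the polygon.
#'
#' @param annotation a [faz_annotation()], or an n x 2 vertex matrix.
#' @param n_px side length of the square pixel grid.
#' @return A [binary_map()] of kind `"faz"`.
#' @export
rasterize_faz <- function(annotation, n_px) {
  poly <- if (inherits(annotation, "faz_annotation"))
    annotation$polygon_px else as.matrix(annotation)
  if (nrow(poly) < 3L) abort("polygon must have at least 3 vertices")
  if (!is_simple_polygon(poly)) abort("polygon is self-intersecting")
  mask <- matrix(FALSE, n_px, n_px)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  nv <- nrow(poly)
  x2 <- x1[c(2:nv, 1)]; y2 <- y1[c(2:nv, 1)]
  ymin <- max(0L, floor(min(y1)))
  ymax <- min(n_px - 1L, ceiling(max(y1)))
  if (ymin > ymax) return(binary_map(mask, "faz"))
  xc <- 0:(n_px - 1L)
  for (y in ymin:ymax) {
    # half-open rule in y avoids double-counting vertices on scanlines
    sel <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)
    if (!any(sel)) next
    xs <- x1[sel] + (y - y1[sel]) / (y2[sel] - y1[sel]) * (x2[sel] - x1[sel])
    inside <- (findInterval(xc, sort(xs)) %% 2L) == 1L
    mask[y + 1L, inside] <- TRUE
  }
  binary_map(mask, "faz",
             provenance = list(op = "rasterize_faz", n_vertices = nv))
}

#' Regular polygon approximating a circle
#' @param center length-2 `(x, y)` center.
#' @param radius circle radius.
#' @param n_vertices number of vertices.
#' @return n x 2 vertex matrix.
#' @export
circle_polygon <- function(center, radius, n_vertices = 360L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}
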