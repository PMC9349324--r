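#' En-face angiogram container
#'
#' Wraps one grayscale en-face OCTA slab image together with its layer
#' label and nominal scan geometry. Pixel values are 8-bit grayscale
#' intensities (0-255); matrices are indexed `[y + 1, x + 1]` with x
#' rightward and y downward, 0-based pixel coordinates.
#'
#' @param pixels numeric matrix of intensities (square).
#' @param slab one of `"SCP"`, `"DCP"`, `"CC"`.
#' @param nominal_scan_mm nominal scan width in mm (default 3.0).
#' @return An object of class `en_face_angiogram`.
#' @export
en_face_angiogram <- function(pixels, slab, nominal_scan_mm = 3.0) {
  slab <- match.arg(slab, c("SCP", "DCP", "CC"))
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels))
    abort("`pixels` must be a square matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    abort("intensities must be finite and non-negative")
  assert_number(nominal_scan_mm, "nominal_scan_mm", lower = 0.1)
  structure(
    list(pixels = pixels, slab = slab,
         nominal_scan_mm = nominal_scan_mm, n_px = nrow(pixels)),
    class = "en_face_angiogram")
}

#' @export
print.en_face_angiogram <- function(x, ...) {
  cat(sprintf("<en_face_angiogram> slab=%s %dx%d px, nominal %.1f mm\n",
              x$slab, x$n_px, x$n_px, x$nominal_scan_mm))
  invisible(x)
}

#' Binary map container
#'
#' A boolean mask aligned with a source angiogram, labelled by what it
#' represents and carrying the parameters that produced it.
#'
#' @param mask logical matrix.
#' @param kind one of `"vessel"`, `"large_vessel"`, `"flow_void"`,
#'   `"faz"`, `"annulus"`.
#' @param provenance named list recording the producing operation and its
#'   parameters.
#' @return An object of class `binary_map`.
#' @export
binary_map <- function(mask, kind, provenance = list()) {
  kind <- match.arg(kind,
                    c("vessel", "large_vessel", "flow_void", "faz", "annulus"))
  if (!is.matrix(mask) || !is.logical(mask))
    abort("`mask` must be a logical matrix")
  structure(list(mask = mask, kind = kind, provenance = provenance),
            class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map> kind=%s %dx%d, %.1f%% on\n",
              x$kind, nrow(x$mask), ncol(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' FAZ boundary annotation
#'
#' A closed simple polygon outlining the foveal avascular zone of one
#' slab, in 0-based pixel coordinates (x rightward, y downward); the
#' polygon is implicitly closed (last vertex joins the first).
#'
#' @param polygon_px two-column numeric matrix of `(x, y)` vertices.
#' @param slab `"SCP"` or `"DCP"`.
#' @return An object of class `faz_annotation`.
#' @export
faz_annotation <- function(polygon_px, slab) {
  slab <- match.arg(slab, c("SCP", "DCP"))
  polygon_px <- as.matrix(polygon_px)
  if (ncol(polygon_px) != 2L || nrow(polygon_px) < 3L)
    abort("`polygon_px` must be an n x 2 matrix with n >= 3")
  if (any(!is.finite(polygon_px))) abort("polygon vertices must be finite")
  structure(list(polygon_px = polygon_px, slab = slab),
            class = "faz_annotation")
}

# ---- file I/O ---------------------------------------------------------------

#' Read a grayscale en-face angiogram from a PNG file
#'
#' @param path PNG file path.
#' @param slab slab label (`"SCP"`, `"DCP"`, `"CC"`).
#' @param nominal_scan_mm nominal scan width in mm.
#' @return An [en_face_angiogram()].
#' @export
read_angiogram <- function(path, slab, nominal_scan_mm = 3.0) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]  # collapse gray-alpha / RGB
  en_face_angiogram(round(arr * 255), slab = slab,
                    nominal_scan_mm = nominal_scan_mm)
}

#' Write an en-face angiogram as an 8-bit grayscale PNG
#'
#' @param img an [en_face_angiogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_angiogram <- function(img, path) {
  png::writePNG(quantize8(img$pixels) / 255, path)
  invisible(path)
}

#' Write a binary map as a 0/255 PNG with a JSON provenance sidecar
#'
#' @param bm a [binary_map()].
#' @param path output PNG path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(bm, path) {
  png::writePNG((bm$mask * 1), path)
  jsonlite::write_json(list(kind = bm$kind, provenance = bm$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a FAZ annotation from its JSON file
#'
#' Dialect: `{"slab": "SCP"|"DCP", "polygon_px": [[x, y], ...]}` with
#' 0-based pixel coordinates, implicitly closed.
#'
#' @param path JSON file path.
#' @return A [faz_annotation()].
#' @export
read_faz_annotation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  faz_annotation(obj$polygon_px, slab = obj$slab)
}

#' Write a FAZ annotation to JSON
#'
#' @param ann a [faz_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_faz_annotation <- function(ann, path) {
  jsonlite::write_json(
    list(slab = ann$slab, polygon_px = unname(ann$polygon_px)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
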