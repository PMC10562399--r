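#' En-face OCTA angiogram
#'
#' Container for a grayscale en-face angiogram of the superficial retinal
#' plexus: an integer intensity matrix together with its physical pixel scale,
#' laterality (which eye was imaged, OD = right, OS = left) and the pixel
#' coordinates of the foveal center. Nominal acquisitions are 6 x 6 mm
#' fovea-centered scans, so `scale_mm_per_px` is typically 6 divided by the
#' image width.
#'
#' @param pixels integer-valued matrix of non-negative intensities
#'   (rows = vertical, increasing downwards; columns = horizontal).
#' @param bit_depth 8 or 16; all intensities must be `< 2^bit_depth`.
#' @param scale_mm_per_px physical size of one pixel in millimetres.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param fovea_center numeric `(row, col)` of the foveal center, defaulting
#'   to the image center. Must lie inside the image.
#' @return An object of class `en_face_angiogram`.
#' @export
en_face_angiogram <- function(pixels, bit_depth = 8L, scale_mm_per_px,
                              laterality = c("OD", "OS"),
                              fovea_center = NULL) {
  laterality <- match.arg(laterality)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("`pixels` must be a numeric matrix")
  if (any(pixels < 0) || any(pixels != floor(pixels)))
    stopf("`pixels` must contain non-negative integer intensities")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stopf("unsupported bit depth %d (must be 8 or 16)", bit_depth)
  if (any(pixels >= 2^bit_depth))
    stopf("intensities exceed the %d-bit range", bit_depth)
  if (!is_scalar_number(scale_mm_per_px) || scale_mm_per_px <= 0)
    stopf("`scale_mm_per_px` must be a positive number")
  if (is.null(fovea_center))
    fovea_center <- c((nrow(pixels) + 1) / 2, (ncol(pixels) + 1) / 2)
  if (length(fovea_center) != 2L ||
      fovea_center[1] < 1 || fovea_center[1] > nrow(pixels) ||
      fovea_center[2] < 1 || fovea_center[2] > ncol(pixels))
    stopf("`fovea_center` must be a (row, col) pair inside the image")
  structure(
    list(pixels = pixels, bit_depth = bit_depth,
         scale_mm_per_px = scale_mm_per_px, laterality = laterality,
         fovea_center = as.numeric(fovea_center)),
    class = "en_face_angiogram")
}

#' @export
print.en_face_angiogram <- function(x, ...) {
  cat(sprintf("<en_face_angiogram> %d x %d px, %d-bit, %.4f mm/px, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$scale_mm_per_px, x$laterality))
  cat(sprintf("  fovea at (%.1f, %.1f); intensity range [%d, %d]\n",
              x$fovea_center[1], x$fovea_center[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.en_face_angiogram <- function(x) dim(x$pixels)

#' Foveal avascular zone selection
#'
#' Represents the manually outlined FAZ region that the Mexican-hat pipeline
#' removes before filtering (freehand selection + cut in the original
#' workflow). The selection is supplied either as a binary mask or as a closed
#' polygon of `(row, col)` vertices, which is rasterized by the even-odd rule.
#'
#' @param mask logical matrix, `TRUE` inside the FAZ. Mutually exclusive with
#'   `polygon`.
#' @param polygon numeric matrix with two columns `(row, col)` listing the
#'   vertices of a closed freehand outline (the last vertex is implicitly
#'   joined to the first). Requires `shape`.
#' @param shape `(rows, cols)` of the target image when rasterizing a polygon.
#' @param provenance `"manual"` (default) or `"automatic"`. A manual selection
#'   must form a single connected region.
#' @return An object of class `faz_selection`.
#' @export
faz_selection <- function(mask = NULL, polygon = NULL, shape = NULL,
                          provenance = c("manual", "automatic")) {
  provenance <- match.arg(provenance)
  if (is.null(mask) == is.null(polygon))
    stopf("supply exactly one of `mask` or `polygon`")
  if (!is.null(polygon)) {
    if (is.null(shape)) stopf("`shape` is required with `polygon`")
    mask <- rasterize_polygon(polygon, shape)
  }
  mask <- as_mask(mask, "mask")
  if (provenance == "manual" && any(mask)) {
    ncomp <- count_components(mask, connectivity = 8L)
    if (ncomp > 1L)
      stopf("a manual FAZ selection must be a single connected region (found %d)",
            ncomp)
  }
  structure(list(mask = mask, provenance = provenance),
            class = "faz_selection")
}

# even-odd rule point-in-polygon rasterization; vertices are (row, col) pairs
rasterize_polygon <- function(polygon, shape) {
  if (!is.matrix(polygon) || ncol(polygon) != 2L || nrow(polygon) < 3L)
    stopf("`polygon` must be a matrix of >= 3 (row, col) vertices")
  nr <- shape[1]; nc <- shape[2]
  py <- matrix(seq_len(nr), nr, nc)        # row coordinate of each pixel
  px <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  inside <- matrix(FALSE, nr, nc)
  n <- nrow(polygon)
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    y1 <- polygon[i, 1]; x1 <- polygon[i, 2]
    y2 <- polygon[j, 1]; x2 <- polygon[j, 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Read and write en-face angiograms
#'
#' Grayscale PNG (8- or 16-bit) and plain-text PGM (P2) are supported. Since
#' physical scale and laterality are not stored in these formats they must be
#' supplied on read.
#'
#' @param path file path; format chosen by extension (`.png` or `.pgm`).
#' @param scale_mm_per_px,laterality,fovea_center passed to
#'   [en_face_angiogram()].
#' @return [read_angiogram()] returns an `en_face_angiogram`;
#'   [write_angiogram()] invisibly returns `path`.
#' @export
read_angiogram <- function(path, scale_mm_per_px, laterality = "OD",
                           fovea_center = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1L]   # take first channel
    # png scales to [0,1]; recover the stored integer code
    bit_depth <- if (attr(arr, "bit.depth") %||% 8L >= 16L) 16L else 8L
    pixels <- round(arr * (2^bit_depth - 1))
  } else if (ext == "pgm") {
    parsed <- read_pgm(path)
    pixels <- parsed$pixels
    bit_depth <- if (parsed$maxval > 255) 16L else 8L
  } else stopf("unsupported image format '.%s'", ext)
  en_face_angiogram(pixels, bit_depth = bit_depth,
                    scale_mm_per_px = scale_mm_per_px,
                    laterality = laterality, fovea_center = fovea_center)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_angiogram
#' @param image an `en_face_angiogram` (or a logical mask for PNG masks,
#'   written as 0/255).
#' @export
write_angiogram <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (is.matrix(image) && is.logical(image))
    image <- en_face_angiogram(matrix(as.integer(image) * 255L,
                                      nrow(image), ncol(image)),
                               bit_depth = 8L, scale_mm_per_px = 1)
  if (!inherits(image, "en_face_angiogram"))
    stopf("`image` must be an en_face_angiogram or a logical mask")
  if (ext == "png") {
    png::writePNG(image$pixels / (2^image$bit_depth - 1), path)
  } else if (ext == "pgm") {
    write_pgm(image$pixels, 2^image$bit_depth - 1, path)
  } else stopf("unsupported image format '.%s'", ext)
  invisible(path)
}

read_pgm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (tok[1] != "P2") stopf("only plain (P2) PGM files are supported")
  nc <- as.integer(tok[2]); nr <- as.integer(tok[3])
  maxval <- as.integer(tok[4])
  vals <- as.integer(tok[-(1:4)])
  if (length(vals) != nr * nc) stopf("corrupt PGM: wrong pixel count")
  list(pixels = matrix(vals, nr, nc, byrow = TRUE), maxval = maxval)
}

write_pgm <- function(pixels, maxval, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(pixels), nrow(pixels)), as.character(maxval)),
             con)
  apply(pixels, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
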