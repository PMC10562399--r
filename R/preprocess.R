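#' Convert an angiogram to 16-bit
#'
#' First shared stage of both pipelines. Conversion preserves the stored
#' intensity values unchanged (no rescaling to the full 16-bit range), the
#' convention of the image-editor workflow this emulates; a 16-bit input is
#' returned as-is.
#'
#' @param image an [en_face_angiogram()].
#' @return The same angiogram with `bit_depth = 16`.
#' @export
convert_to_16bit <- function(image) {
  stopifnot(inherits(image, "en_face_angiogram"))
  if (!image$bit_depth %in% c(8L, 16L))
    stopf("unsupported bit depth %s", image$bit_depth)
  image$bit_depth <- 16L
  image
}

#' Minimum (erosion) filter
#'
#' Replaces every pixel by the darkest value in its running window, the noise
#' reduction step shared by both pipelines. On the white-vessels-on-black
#' images used here this removes small bright speckle. The window anchored at
#' pixel `(r, c)` covers rows `r .. r+window-1` and columns `c .. c+window-1`,
#' with replicate padding at the borders; the default reproduces the 2 x 2
#' minimum filter of the original workflow.
#'
#' @param image an [en_face_angiogram()].
#' @param window side length of the square window (default 2).
#' @return The filtered angiogram (never brighter than the input anywhere).
#' @export
minimum_filter <- function(image, window = 2L) {
  stopifnot(inherits(image, "en_face_angiogram"))
  window <- as.integer(window)
  if (window < 1L) stopf("`window` must be >= 1")
  px <- image$pixels
  if (window > min(dim(px)))
    stopf("window (%d) larger than the image (%d x %d)",
          window, nrow(px), ncol(px))
  nr <- nrow(px); nc <- ncol(px)
  out <- px
  for (off in seq_len(window - 1L)) {           # separable min: rows, then cols
    idx <- pmin(seq_len(nr) + off, nr)
    out <- pmin(out, px[idx, , drop = FALSE])
  }
  acc <- out
  for (off in seq_len(window - 1L)) {
    idx <- pmin(seq_len(nc) + off, nc)
    acc <- pmin(acc, out[, idx, drop = FALSE])
  }
  image$pixels <- acc
  image
}

#' Remove the foveal avascular zone
#'
#' Emulates the manual freehand-select-and-cut step of the Mexican-hat
#' pipeline: all intensities inside the selection are set to 0 (background).
#' Cut pixels stay part of the image and keep counting towards sector areas,
#' so central-sector densities remain defined.
#'
#' @param image an [en_face_angiogram()].
#' @param faz a [faz_selection()]; an all-`FALSE` mask is a permitted no-op.
#' @return The angiogram with the FAZ blacked out.
#' @export
cut_faz <- function(image, faz) {
  stopifnot(inherits(image, "en_face_angiogram"))
  if (!inherits(faz, "faz_selection")) stopf("`faz` must be a faz_selection")
  if (!identical(dim(faz$mask), dim(image$pixels)))
    stopf("FAZ mask shape (%d x %d) does not match the image (%d x %d)",
          nrow(faz$mask), ncol(faz$mask),
          nrow(image$pixels), ncol(image$pixels))
  image$pixels[faz$mask] <- 0L
  image
}
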