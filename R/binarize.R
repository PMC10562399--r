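#' Binary vessel map
#'
#' Boolean vessel mask tagged with the method that produced it (`"MHF"` for
#' Mexican-hat ridge binarization, `"ST"` for Shanbhag thresholding) and the
#' threshold that was applied.
#'
#' @param mask logical matrix, `TRUE` = vessel (white).
#' @param method `"MHF"` or `"ST"`.
#' @param threshold_used the Shanbhag grey-level bin (ST) or the response
#'   cutoff (MHF).
#' @return An object of class `binary_vessel_map`.
#' @export
binary_vessel_map <- function(mask, method = c("MHF", "ST"),
                              threshold_used = NA_real_) {
  method <- match.arg(method)
  mask <- as_mask(mask)
  structure(list(mask = mask, method = method,
                 threshold_used = threshold_used,
                 source_shape = dim(mask)),
            class = "binary_vessel_map")
}

#' @export
print.binary_vessel_map <- function(x, ...) {
  cat(sprintf("<binary_vessel_map> %s, %d x %d px, %.1f%% white, threshold %s\n",
              x$method, nrow(x$mask), ncol(x$mask), 100 * mean(x$mask),
              format(x$threshold_used)))
  invisible(x)
}

#' Mexican-hat (Laplacian of Gaussian) ridge filter
#'
#' Convolves the image with the negated Laplacian of a Gaussian of standard
#' deviation `sigma_px`, so that bright curvilinear ridges on a dark
#' background -- vessels on an OCTA angiogram -- give a positive response.
#' The kernel is sampled at integer offsets out to four standard deviations,
#' the Gaussian factor normalized to unit sum and the second-derivative
#' factor mean-corrected to exact zero sum, so a constant image maps to an
#' exactly zero response. Borders use replicate padding.
#'
#' @param image an [en_face_angiogram()].
#' @param sigma_px Gaussian standard deviation in pixels (default 2, matching
#'   the 2-3 px calibre of typical capillary-scale ridges at ~12 um/px).
#' @return A real-valued response matrix of the same shape.
#' @export
log_filter <- function(image, sigma_px = 2) {
  stopifnot(inherits(image, "en_face_angiogram"))
  if (!is_scalar_number(sigma_px) || sigma_px <= 0)
    stopf("`sigma_px` must be a positive number")
  r <- ceiling(4 * sigma_px)
  px <- image$pixels
  if (2 * r + 1 > min(dim(px)))
    stopf("sigma_px = %g needs a %d-px kernel, larger than the image",
          sigma_px, 2 * r + 1)
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma_px^2))
  g <- g / sum(g)
  g2 <- (x^2 - sigma_px^2) / sigma_px^4 * exp(-x^2 / (2 * sigma_px^2))
  g2 <- g2 - mean(g2)                     # exact zero-sum second derivative
  # LoG = d2/dy2 + d2/dx2 of the Gaussian-smoothed image; negate for ridges
  -(conv1d(conv1d(px, g2, 1L), g, 2L) + conv1d(conv1d(px, g, 1L), g2, 2L))
}

#' Binarize by Mexican-hat filtering
#'
#' The Mexican-hat branch of the workflow: the ridge-positive Laplacian of
#' Gaussian response is thresholded at `cutoff` (default 0, the canonical
#' parameter-free zero-crossing criterion for ridges).
#'
#' @inheritParams log_filter
#' @param cutoff response cutoff; pixels with response strictly greater are
#'   vessel. Increasing the cutoff never adds vessel pixels. The comparison
#'   carries a guard band of `1e-8 * max(1, max intensity)` so that flat
#'   image regions, whose response is zero up to rounding residue, never
#'   binarize as vessel.
#' @return A [binary_vessel_map()] with `method = "MHF"`.
#' @export
binarize_mhf <- function(image, sigma_px = 2, cutoff = 0) {
  resp <- log_filter(image, sigma_px)
  tol <- 1e-8 * max(1, max(image$pixels))
  binary_vessel_map(resp > cutoff + tol, method = "MHF",
                    threshold_used = cutoff)
}

#' Grey-level histogram over 256 bins
#'
#' Histogram used by the Shanbhag threshold. Regardless of bit depth the
#' intensities are mapped to 256 equal-width bins spanning the observed
#' `0..max` range: bin of intensity `v` is `min(255, floor(v * 256 / (max+1)))`,
#' which is the identity for an 8-bit image with full range.
#'
#' @param image an [en_face_angiogram()] (or a non-negative integer matrix).
#' @return A list with `counts` (256 integers), `total`, and `bin_of`, a
#'   function mapping intensity values to bin indices (0-based).
#' @export
grey_histogram <- function(image) {
  px <- if (inherits(image, "en_face_angiogram")) image$pixels else image
  m <- max(px)
  bin_of <- function(v) pmin((v * 256) %/% (m + 1), 255)
  b <- bin_of(px)
  counts <- tabulate(b + 1L, nbins = 256L)
  list(counts = counts, total = sum(counts), bin_of = bin_of)
}

#' Shanbhag information-measure threshold
#'
#' Global histogram threshold of Shanbhag (1994). Each candidate grey level
#' splits the normalized histogram into background and object classes; fuzzy
#' membership of a level in its class is taken proportional to the cumulative
#' mass on its own side, and each class contributes an information measure
#' built from `-p * log(1 - 0.5 * cumulative/classmass)` terms. The chosen
#' threshold minimizes the absolute difference between the background and
#' object information measures; ties resolve to the lowest qualifying level.
#' Candidates run from the first bin with positive mass to the last bin with
#' positive mass strictly above it. The measure depends only on normalized
#' masses, so scaling all counts leaves the threshold unchanged.
#'
#' @param hist a histogram as returned by [grey_histogram()], or a bare
#'   vector of 256 non-negative counts.
#' @return Integer threshold in `0..255` (a bin index). Binarization rules
#'   treat pixels with bin strictly greater than the threshold as foreground.
#' @export
shanbhag_threshold <- function(hist) {
  counts <- if (is.list(hist)) hist$counts else hist
  if (length(counts) != 256L || any(counts < 0))
    stopf("`hist` must hold 256 non-negative counts")
  nz <- which(counts > 0)
  if (length(nz) < 2L)
    stopf("threshold undefined: histogram has fewer than two grey levels")
  p <- counts / sum(counts)
  P1 <- cumsum(p)                     # mass at or below each bin
  P2 <- 1 - P1                        # mass strictly above each bin
  P1lag <- c(0, P1[-256L])            # mass strictly below each bin
  cand <- nz[1L]:(nz[length(nz)] - 1L)   # 1-based candidate indices

  # fuzzy information measures, vectorized over (bin i, candidate t);
  # entries outside each class (and their out-of-domain log arguments) are
  # neutralized to log(1) = 0 before summation
  cb <- 0.5 / P1[cand]                # background membership slope per candidate
  co <- 0.5 / P2[cand]
  lower <- outer(seq_len(256L), cand, "<=")
  ab <- 1 - outer(P1lag, cb)          # 256 x n_cand
  ab[!lower | ab <= 0] <- 1
  ao <- 1 - outer(P2, co)
  ao[lower | ao <= 0] <- 1
  ent_back <- colSums(p * -log(ab)) * cb
  ent_obj  <- colSums(p * -log(ao)) * co
  as.integer(cand[which.min(abs(ent_back - ent_obj))] - 1L)
}

#' Binarize by Shanbhag thresholding
#'
#' The alternative branch of the workflow: a 256-bin grey-level histogram is
#' built (see [grey_histogram()]), the Shanbhag threshold computed, and
#' pixels whose bin lies strictly above the threshold become vessel. Because
#' the foveal avascular zone sits at background intensity it falls below any
#' valid threshold, so no manual FAZ removal is needed.
#'
#' @param image an [en_face_angiogram()], already minimum-filtered.
#' @return A [binary_vessel_map()] with `method = "ST"` and the chosen bin
#'   recorded in `threshold_used`.
#' @export
binarize_st <- function(image) {
  stopifnot(inherits(image, "en_face_angiogram"))
  h <- grey_histogram(image)
  t <- shanbhag_threshold(h)
  mask <- h$bin_of(image$pixels) > t
  binary_vessel_map(mask, method = "ST", threshold_used = t)
}
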