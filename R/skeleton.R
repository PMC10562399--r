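#' Skeleton (centerline) map
#'
#' One-pixel-wide centerline representation of a binary vessel map, used for
#' length-type measurements (skeleton density). The skeleton is always a
#' subset of the source mask and contains no fully-true 2 x 2 block.
#'
#' @param mask logical matrix.
#' @param source_method `"MHF"` or `"ST"`, inherited from the binarization.
#' @return An object of class `skeleton_map`.
#' @export
skeleton_map <- function(mask, source_method = c("MHF", "ST")) {
  source_method <- match.arg(source_method)
  structure(list(mask = as_mask(mask), source_method = source_method),
            class = "skeleton_map")
}

#' Skeletonize a binary vessel map
#'
#' Iterative thinning to unit-width centerlines, the final processing stage
#' of both pipelines. The implementation is a sequential directional
#' border-peeling scheme of the Zhang-Suen family: boundary pixels whose
#' foreground neighbours form a single connected arc (crossing number 1) and
#' that are not endpoints are deleted, one sweep direction at a time, until a
#' fixed point. By construction the skeleton is a subset of the input, every
#' 8-connected component of the input survives as exactly one component, the
#' result has unit thickness, and the operation is idempotent. The image
#' border is treated as background; short spurs are not pruned.
#'
#' @param binary a [binary_vessel_map()] or a logical matrix (an empty mask
#'   yields an empty skeleton).
#' @return A `skeleton_map` (tagged with the source method when available).
#' @export
skeletonize <- function(binary) {
  method <- if (inherits(binary, "binary_vessel_map")) binary$method else "MHF"
  mask <- as_mask(binary, "binary")
  skeleton_map(thin_mask_cpp(mask), source_method = method)
}
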