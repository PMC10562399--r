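#' ETDRS sector labels and the conventional sector numbering
#'
#' The nine macular sectors: central disc `C`, inner ring `S1, N1, I1, T1`
#' and outer ring `S2, N2, I2, T2` (S = superior, N = nasal, I = inferior,
#' T = temporal). `etdrs_sector_numbers` gives the conventional 1..9
#' numbering used in tabulated results (1 = C, 2 = I1, 3 = T1, 4 = S1,
#' 5 = N1, 6 = I2, 7 = T2, 8 = S2, 9 = N2).
#'
#' @export
etdrs_sector_labels <- c("C", "S1", "N1", "I1", "T1", "S2", "N2", "I2", "T2")

#' @rdname etdrs_sector_labels
#' @export
etdrs_sector_numbers <- c(C = 1L, I1 = 2L, T1 = 3L, S1 = 4L, N1 = 5L,
                          I2 = 6L, T2 = 7L, S2 = 8L, N2 = 9L)

#' Build the 9-sector ETDRS macular grid
#'
#' Concentric circles of 1, 3 and 6 mm diameter centered on the fovea define
#' a central disc, an inner and an outer ring; the rings are split into four
#' quadrants along the +-45 degree diagonals. Membership is by Euclidean
#' distance in millimetres from the center (central disc `d < 0.5`, inner
#' ring `0.5 <= d < 1.5`, outer ring `1.5 <= d < 3.0`) and by angle, with
#' half-open angular intervals so every pixel belongs to exactly one
#' quadrant. Temporal/nasal labels depend on laterality: on a right-eye (OD)
#' image the temporal quadrant is on the left; OS mirrors T and N. Pixels
#' outside the 6 mm circle belong to no sector, and the grid is clipped to
#' the image.
#'
#' @param shape `(rows, cols)` of the target image.
#' @param center `(row, col)` grid center (the fovea), inside the image.
#' @param scale_mm_per_px positive pixel scale.
#' @param laterality `"OD"` or `"OS"`.
#' @return An object of class `etdrs_grid`: a list with `sector_masks` (nine
#'   named logical matrices, pairwise disjoint, union = the discretized 3 mm
#'   disc), `center`, `scale_mm_per_px`, `laterality`.
#' @export
build_etdrs_grid <- function(shape, center, scale_mm_per_px,
                             laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  if (!is_scalar_number(scale_mm_per_px) || scale_mm_per_px <= 0)
    stopf("`scale_mm_per_px` must be a positive number")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (length(center) != 2L || center[1] < 1 || center[1] > nr ||
      center[2] < 1 || center[2] > nc)
    stopf("`center` must lie inside the image")
  dr <- seq_len(nr) - center[1]
  dc <- seq_len(nc) - center[2]
  DR <- matrix(dr, nr, nc)
  DC <- matrix(dc, nr, nc, byrow = TRUE)
  d_mm <- scale_mm_per_px * sqrt(DR^2 + DC^2)
  # angle from the upward vertical (rows grow downward), degrees in (-180,180]
  ang <- atan2(DC, -DR) * 180 / pi
  up    <- ang >= -45 & ang < 45
  right <- ang >= 45 & ang < 135
  left  <- ang >= -135 & ang < -45
  down  <- !(up | right | left)
  # OD: temporal on the image left; OS mirrored
  temporal <- if (laterality == "OD") left else right
  nasal    <- if (laterality == "OD") right else left
  ring1 <- d_mm >= 0.5 & d_mm < 1.5
  ring2 <- d_mm >= 1.5 & d_mm < 3.0
  sector_masks <- list(
    C  = d_mm < 0.5,
    S1 = ring1 & up,   N1 = ring1 & nasal,
    I1 = ring1 & down, T1 = ring1 & temporal,
    S2 = ring2 & up,   N2 = ring2 & nasal,
    I2 = ring2 & down, T2 = ring2 & temporal)
  structure(list(sector_masks = sector_masks, center = as.numeric(center),
                 scale_mm_per_px = scale_mm_per_px, laterality = laterality,
                 shape = c(nr, nc)),
            class = "etdrs_grid")
}

#' @export
print.etdrs_grid <- function(x, ...) {
  cat(sprintf("<etdrs_grid> %d x %d px, center (%.1f, %.1f), %.4f mm/px, %s\n",
              x$shape[1], x$shape[2], x$center[1], x$center[2],
              x$scale_mm_per_px, x$laterality))
  invisible(x)
}

#' Raw per-sector pixel counts
#'
#' Counts, for every ETDRS sector, the white (vessel) pixels `W` of the
#' binary map, the skeleton pixels `S`, and the sector area `T` in pixels.
#'
#' @param binary a [binary_vessel_map()] or logical matrix.
#' @param skeleton a [skeleton_map()] or logical matrix.
#' @param grid an [build_etdrs_grid()] result; all shapes must agree.
#' @return A data frame with columns `sector`, `W`, `S`, `T` (one row per
#'   sector, in `etdrs_sector_labels` order).
#' @export
sector_counts <- function(binary, skeleton, grid) {
  stopifnot(inherits(grid, "etdrs_grid"))
  bin <- as_mask(binary, "binary")
  sk <- as_mask(skeleton, "skeleton")
  if (!identical(dim(bin), dim(sk)) ||
      !identical(dim(bin), as.integer(grid$shape)))
    stopf("binary, skeleton and grid shapes must all match")
  out <- lapply(etdrs_sector_labels, function(lbl) {
    m <- grid$sector_masks[[lbl]]
    data.frame(sector = lbl, W = sum(bin & m), S = sum(sk & m), T = sum(m))
  })
  do.call(rbind, out)
}

#' Vessel density metrics from raw counts
#'
#' The three densitometric parameters, as ratios of pixel counts:
#' vessel density `VD = W / T` (fraction of sector area occupied by binarized
#' vessel signal), skeleton density `SkD = S / T` (centerline pixels per
#' sector area, a vessel-length proxy) and the vessel diameter index
#' `VDI = W / S = VD / SkD` (mean vessel calibre in pixels). When a sector
#' has no skeleton pixels the VDI is undefined and reported as `NA` (not 0).
#'
#' @param W,S,T numeric vectors of white, skeleton and total pixel counts,
#'   recycled to a common length; requires `T > 0` and `0 <= S <= W <= T`.
#' @return A data frame with columns `VD`, `SkD`, `VDI`.
#' @export
vessel_metrics <- function(W, S, T) {
  n <- max(length(W), length(S), length(T))
  W <- rep_len(W, n); S <- rep_len(S, n); T <- rep_len(T, n)
  if (any(T <= 0)) stopf("sector area T must be positive")
  if (any(S < 0 | S > W | W > T))
    stopf("counts must satisfy 0 <= S <= W <= T")
  data.frame(VD = W / T, SkD = S / T,
             VDI = ifelse(S > 0, W / S, NA_real_))
}

#' Per-sector metrics for one processed image
#'
#' Convenience wrapper combining [sector_counts()] and [vessel_metrics()]
#' into the per-subject, per-method record used by cohort summaries and the
#' agreement analysis.
#'
#' @inheritParams sector_counts
#' @param subject_id identifier carried through to the output.
#' @param method overrides the method tag (defaults to the binary map's).
#' @return A data frame with columns `subject_id`, `method`, `sector`,
#'   `sector_number`, `W`, `S`, `T`, `VD`, `SkD`, `VDI`.
#' @export
sector_metrics <- function(binary, skeleton, grid, subject_id = NA,
                           method = NULL) {
  if (is.null(method))
    method <- if (inherits(binary, "binary_vessel_map")) binary$method
              else "MHF"
  counts <- sector_counts(binary, skeleton, grid)
  cbind(subject_id = subject_id, method = method,
        counts["sector"],
        sector_number = etdrs_sector_numbers[counts$sector],
        counts[c("W", "S", "T")],
        vessel_metrics(counts$W, counts$S, counts$T),
        row.names = NULL)
}

#' Cohort summary of sector metrics
#'
#' Aggregates per-subject sector metrics of one method into the per-sector
#' mean, sample standard deviation (n-1 denominator; reported as 0 when
#' n = 1), median and quartiles (linear-interpolation definition,
#' `stats::quantile` type 7) for each of VD, SkD and VDI. Sectors whose VDI
#' is undefined for a subject are excluded from the VDI aggregation, with
#' the number of exclusions reported in `n_undefined`.
#'
#' @param metrics a data frame as returned by [sector_metrics()] (possibly
#'   row-bound over subjects), or a list of such data frames. All rows must
#'   share one method.
#' @return A data frame with one row per (metric, sector):
#'   `method`, `metric`, `sector`, `sector_number`, `n`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `n_undefined`.
#' @export
cohort_summary <- function(metrics) {
  if (is.list(metrics) && !is.data.frame(metrics))
    metrics <- do.call(rbind, metrics)
  if (!is.data.frame(metrics) || nrow(metrics) == 0L)
    stopf("`metrics` must contain at least one subject")
  if (length(unique(metrics$method)) != 1L)
    stopf("all rows must come from a single method; summarize methods separately")
  rows <- list()
  for (metric in c("VD", "SkD", "VDI")) {
    for (lbl in etdrs_sector_labels) {
      v <- metrics[[metric]][metrics$sector == lbl]
      n_undef <- sum(is.na(v))
      v <- v[!is.na(v)]
      n <- length(v)
      rows[[length(rows) + 1L]] <- data.frame(
        method = metrics$method[1], metric = metric, sector = lbl,
        sector_number = unname(etdrs_sector_numbers[lbl]), n = n,
        mean = if (n) mean(v) else NA_real_,
        sd = if (n > 1L) stats::sd(v) else if (n == 1L) 0 else NA_real_,
        median = if (n) stats::median(v) else NA_real_,
        q1 = if (n) unname(stats::quantile(v, 0.25, type = 7)) else NA_real_,
        q3 = if (n) unname(stats::quantile(v, 0.75, type = 7)) else NA_real_,
        n_undefined = n_undef)
    }
  }
  do.call(rbind, rows)
}
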