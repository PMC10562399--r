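#' Noise reduction of a binarized image
#'
#' Fraction of the processed image that is background (non-vessel):
#' `1 - white / total`. On healthy superficial-plexus masks this is the
#' "noise level" figure of merit, typically around 65%, and it complements
#' the white-pixel fraction to exactly 1.
#'
#' @param binary a [binary_vessel_map()] or logical matrix.
#' @return A number in `[0, 1]`.
#' @export
noise_reduction <- function(binary) {
  mask <- as_mask(binary, "binary")
  if (length(mask) == 0L) stopf("`binary` must be non-empty")
  1 - sum(mask) / length(mask)
}

#' Count connected vascular segments
#'
#' Number of connected components of the vessel mask -- the fragmentation
#' measure. In a healthy eye the vasculature should form one contiguous
#' segment; processing noise breaks it apart, and the two binarization
#' methods fragment to different degrees. Default 8-connectivity (diagonally
#' touching vessel pixels connect); 4-connectivity is available for
#' sensitivity analysis.
#'
#' @param binary a [binary_vessel_map()] or logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Non-negative integer component count (0 for an empty mask).
#' @export
count_components <- function(binary, connectivity = 8L) {
  mask <- as_mask(binary, "binary")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stopf("`connectivity` must be 4 or 8")
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(0L)
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (off in offs) {
    dr <- off[1]; dc <- off[2]
    rows <- if (dr >= 0) seq_len(nr - dr) else seq.int(1L - dr, nr)
    cols <- seq_len(nc - dc)
    both <- mask[rows, cols, drop = FALSE] &
      mask[rows + dr, cols + dc, drop = FALSE]
    if (!any(both)) next
    sub <- which(both)
    r0 <- rows[1L] + (sub - 1L) %% length(rows)
    c0 <- cols[1L] + (sub - 1L) %/% length(rows)
    a <- (c0 - 1L) * nr + r0
    b <- (c0 + dc - 1L) * nr + (r0 + dr)
    edges <- c(edges, rbind(match(a, idx), match(b, idx)))
  }
  g <- igraph::make_graph(edges = edges, n = n, directed = FALSE)
  as.integer(igraph::components(g)$no)
}

#' Repeatability error of manual ETDRS grid placement
#'
#' The ETDRS grid must be centered on the fovea by hand, so in the original
#' workflow it was placed several consecutive times and the white-pixel
#' counts of the four inner sectors (S1, N1, I1, T1) compared across
#' placements. For each inner sector the coefficient of variation
#' (sample SD / mean) of the white count across placements is computed;
#' the returned error is the mean sector CV as a percentage. Sectors with
#' zero mean white count are excluded with a warning.
#'
#' @param binary a [binary_vessel_map()] or logical matrix.
#' @param grids a list of two or more [build_etdrs_grid()] placements on the
#'   same image.
#' @return Percentage error (0 for identical placements).
#' @export
grid_placement_error <- function(binary, grids) {
  mask <- as_mask(binary, "binary")
  if (!is.list(grids) || length(grids) < 2L)
    stopf("`grids` must list at least two grid placements")
  inner <- c("S1", "N1", "I1", "T1")
  counts <- sapply(grids, function(g) {
    stopifnot(inherits(g, "etdrs_grid"))
    vapply(inner, function(lbl) sum(mask & g$sector_masks[[lbl]]), 0)
  })                                        # 4 sectors x n placements
  cv <- apply(counts, 1L, function(w) {
    if (mean(w) == 0) return(NA_real_)
    stats::sd(w) / mean(w)
  })
  if (anyNA(cv)) {
    warning("sector(s) with zero mean white count excluded: ",
            paste(inner[is.na(cv)], collapse = ", "))
    cv <- cv[!is.na(cv)]
    if (!length(cv)) stopf("no inner sector has white pixels")
  }
  100 * mean(cv)
}

#' Repeatability error of manual FAZ selection
#'
#' The freehand FAZ outline of the Mexican-hat pipeline is drawn several
#' times; for each repetition the white pixels falling inside the selection
#' are counted, and the error is the mean absolute deviation of those counts
#' from their mean, divided by the mean, as a percentage. The metric is
#' count-based, not overlap-based: disjoint selections capturing equal white
#' counts give 0%.
#'
#' @param binary a [binary_vessel_map()] or logical matrix.
#' @param faz_masks a list of two or more [faz_selection()]s (or logical
#'   masks).
#' @return Percentage error.
#' @export
faz_selection_error <- function(binary, faz_masks) {
  mask <- as_mask(binary, "binary")
  if (!is.list(faz_masks) || length(faz_masks) < 2L)
    stopf("`faz_masks` must list at least two selections")
  w <- vapply(faz_masks, function(f) sum(mask & as_mask(f, "faz")), 0)
  if (all(w == 0)) stopf("no white pixels in any selection")
  100 * mean(abs(w - mean(w))) / mean(w)
}

#' Bland-Altman agreement between the two methods
#'
#' Paired-difference agreement analysis for one metric in one sector across
#' subjects. Differences are formed as MHF minus ST. Reports the mean
#' difference, its sample SD, the limits of agreement (mean +/- 1.96 SD) and
#' the 95% confidence interval of the mean difference
#' (mean +/- 1.96 SD / sqrt(n) by default, consistent with the 1.96
#' convention of the limits; a t-quantile CI is available via `ci_method`).
#' The difference is called significant when the CI excludes zero.
#'
#' @param mhf,st paired numeric vectors (same subjects, same order), n >= 3.
#'   Alternatively `mhf` may be a two-column matrix/data frame of
#'   (MHF, ST) pairs.
#' @param ci_method `"normal"` (1.96) or `"t"` (t-quantile with n-1 df).
#' @return An object of class `bland_altman_stats`: `n`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `ci_low`, `ci_high`, `significant`,
#'   plus `points`, a data frame of per-pair `(mean, diff)` for plotting.
#' @export
bland_altman <- function(mhf, st = NULL, ci_method = c("normal", "t")) {
  ci_method <- match.arg(ci_method)
  if (is.null(st)) {
    mhf <- as.matrix(mhf)
    if (ncol(mhf) != 2L) stopf("paired input must have two columns")
    st <- mhf[, 2L]; mhf <- mhf[, 1L]
  }
  if (length(mhf) != length(st)) stopf("`mhf` and `st` must be paired")
  keep <- stats::complete.cases(mhf, st)
  mhf <- mhf[keep]; st <- st[keep]
  n <- length(mhf)
  if (n < 3L) stopf("Bland-Altman analysis needs at least 3 complete pairs")
  d <- mhf - st
  m <- mean(d)
  s <- stats::sd(d)
  z <- if (ci_method == "normal") 1.96 else stats::qt(0.975, n - 1L)
  half <- z * s / sqrt(n)
  out <- list(n = n, mean_diff = m, sd_diff = s,
              loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
              ci_low = m - half, ci_high = m + half,
              significant = (m - half) > 0 || (m + half) < 0,
              ci_method = ci_method,
              points = data.frame(mean = (mhf + st) / 2, diff = d))
  class(out) <- "bland_altman_stats"
  out
}

#' @export
print.bland_altman_stats <- function(x, ...) {
  cat(sprintf(paste0("<bland_altman_stats> n = %d\n",
                     "  mean diff %.4f (SD %.4f), LoA [%.4f, %.4f]\n",
                     "  95%% CI of mean diff [%.4f, %.4f] -> %s\n"),
              x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high,
              x$ci_low, x$ci_high,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Correlation between per-pair means and differences
#'
#' Pearson correlation of the Bland-Altman point cloud (per-pair means vs
#' differences), used to characterize proportional bias: a negative value
#' means the between-method difference shrinks as the measured quantity
#' grows. Undefined (NA) when either coordinate has zero variance.
#'
#' @param points a `bland_altman_stats` object or a data frame with columns
#'   `mean` and `diff` (n >= 3).
#' @return Signed correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
diff_mean_correlation <- function(points) {
  if (inherits(points, "bland_altman_stats")) points <- points$points
  if (!is.data.frame(points) || nrow(points) < 3L)
    stopf("need at least 3 (mean, diff) points")
  if (stats::sd(points$mean) == 0 || stats::sd(points$diff) == 0)
    return(NA_real_)
  stats::cor(points$mean, points$diff)
}

#' Fragmentation percent difference
#'
#' Reporting formula for how much more fragmented one mask is than another:
#' `(n_mhf - n_st) / n_mhf * 100`, the percentage by which the ST segment
#' count falls below the MHF count.
#'
#' @param n_mhf,n_st mean segment counts of the two methods.
#' @return Percentage difference.
#' @export
fragmentation_pct_diff <- function(n_mhf, n_st) {
  if (any(n_mhf <= 0)) stopf("`n_mhf` must be positive")
  (n_mhf - n_st) / n_mhf * 100
}

#' Per-image quality report
#'
#' Bundles the scalar quality metrics for one processed image; repeatability
#' errors are included when the corresponding repeated placements/selections
#' are supplied.
#'
#' @param binary a [binary_vessel_map()].
#' @param grids optional list of repeated grid placements
#'   (see [grid_placement_error()]).
#' @param faz_masks optional list of repeated FAZ selections
#'   (see [faz_selection_error()]).
#' @param connectivity component connectivity, 4 or 8.
#' @return A list of class `quality_report` with `noise_reduction`,
#'   `n_components` and optionally `grid_error_pct`, `faz_error_pct`.
#' @export
quality_report <- function(binary, grids = NULL, faz_masks = NULL,
                           connectivity = 8L) {
  out <- list(noise_reduction = noise_reduction(binary),
              n_components = count_components(binary, connectivity))
  if (!is.null(grids))
    out$grid_error_pct <- grid_placement_error(binary, grids)
  if (!is.null(faz_masks))
    out$faz_error_pct <- faz_selection_error(binary, faz_masks)
  class(out) <- "quality_report"
  out
}

#' Bland-Altman plot
#'
#' Scatter of per-pair means vs differences with the mean-difference line,
#' dashed limits of agreement, shaded 95% CI of the mean difference and a
#' dotted zero line.
#'
#' @param x a `bland_altman_stats` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman_stats <- function(x, ...) {
  pts <- x$points
  ylim <- range(pts$diff, x$loa_low, x$loa_high, 0)
  graphics::plot(pts$mean, pts$diff, xlab = "Mean of methods",
                 ylab = "Difference (MHF - ST)", ylim = ylim, ...)
  graphics::rect(graphics::par("usr")[1], x$ci_low,
                 graphics::par("usr")[2], x$ci_high,
                 col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
  graphics::abline(h = x$mean_diff, lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
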