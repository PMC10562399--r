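#' Parameters of a synthetic vascular phantom
#'
#' Describes a fovea-centered retinal-vasculature phantom: a dark noisy
#' background, an avascular central disc (the FAZ), and a bright branching
#' vascular network of varying calibre grown from the image border toward the
#' fovea, optionally overlaid with a mesh of short dim capillary segments.
#' Defaults emulate a 6 x 6 mm superficial-plexus scan sampled on a 512 px
#' grid (~11.7 um/px): a normal-sized FAZ of 0.3 mm radius, a dozen trunk
#' vessels of 4-10 px (47-117 um) calibre rendered near signal saturation,
#' a dimmer sub-resolution capillary mesh with a length share comparable to
#' the trunk tree, and moderate additive noise.
#'
#' @param seed integer RNG seed; all phantom randomness derives from it.
#' @param height_px,width_px image size in pixels (>= 64).
#' @param scale_mm_per_px physical pixel size (default `6 / width_px`).
#' @param faz_radius_mm radius of the avascular disc, `< 3` mm.
#' @param n_root_vessels number of trunk vessels entering from the border.
#' @param branch_probability per-step probability that a walker spawns a
#'   side branch, in `[0, 1]`.
#' @param width_range_px `(min, max)` trunk-vessel calibre in pixels.
#'   Trunks taper along their course and branches thin at each generation;
#'   a branch terminates once its calibre would fall below the minimum
#'   (finer vessels belong to the capillary mesh, modeled separately). The
#'   default 3-8 px corresponds to 35-95 um arterioles/venules at the
#'   default sampling.
#' @param capillary_density in `[0, 1]`; scales the number of short, thin
#'   (1-2 px) capillary segments overlaid on the trunk network.
#' @param background_level background intensity in `0..255`.
#' @param vessel_level rendered intensity of a full-calibre trunk vessel in
#'   `0..255`.
#' @param capillary_level rendered capillary intensity (dimmer than trunks,
#'   the physical basis of the differing capillary sensitivity of the two
#'   binarization methods).
#' @param width_gain intensity drop per pixel of calibre below the maximum:
#'   a vessel of local width `w` renders at
#'   `vessel_level - width_gain * (max_width - w)`, emulating the weaker
#'   flow signal of narrow vessels. With a constant `width_range_px` the
#'   vessels still render at a single level whatever the gain.
#' @param noise_sigma additive noise standard deviation (grey levels).
#' @param noise_type `"gaussian"` (additive, default) or `"speckle"`
#'   (multiplicative).
#' @param laterality `"OD"` or `"OS"`.
#' @return A validated list of class `phantom_params`.
#' @export
phantom_params <- function(seed = 1L, height_px = 512L, width_px = 512L,
                           scale_mm_per_px = 6 / width_px,
                           faz_radius_mm = 0.3, n_root_vessels = 12L,
                           branch_probability = 0.02,
                           width_range_px = c(4, 10),
                           capillary_density = 0.5,
                           background_level = 40L, vessel_level = 245L,
                           capillary_level = 110L, width_gain = 2,
                           noise_sigma = 12,
                           noise_type = c("gaussian", "speckle"),
                           laterality = c("OD", "OS")) {
  noise_type <- match.arg(noise_type)
  laterality <- match.arg(laterality)
  height_px <- as.integer(height_px); width_px <- as.integer(width_px)
  if (height_px < 64L || width_px < 64L)
    stopf("phantom must be at least 64 x 64 px")
  if (!is_scalar_number(scale_mm_per_px) || scale_mm_per_px <= 0)
    stopf("`scale_mm_per_px` must be positive")
  if (faz_radius_mm < 0 || faz_radius_mm >= 3)
    stopf("`faz_radius_mm` must be in [0, 3)")
  faz_px <- faz_radius_mm / scale_mm_per_px
  if (faz_px >= min(height_px, width_px) / 2)
    stopf("degenerate field: the FAZ disc covers the image")
  if (n_root_vessels < 1L) stopf("`n_root_vessels` must be positive")
  if (branch_probability < 0 || branch_probability > 1)
    stopf("`branch_probability` must be in [0, 1]")
  if (length(width_range_px) != 2L || any(width_range_px <= 0) ||
      width_range_px[1] > width_range_px[2])
    stopf("`width_range_px` must be positive (min, max) with min <= max")
  if (capillary_density < 0 || capillary_density > 1)
    stopf("`capillary_density` must be in [0, 1]")
  if (background_level < 0 || background_level > 255 ||
      vessel_level < 0 || vessel_level > 255)
    stopf("intensity levels must be in 0..255")
  if (noise_sigma < 0) stopf("`noise_sigma` must be non-negative")
  structure(list(seed = as.integer(seed), height_px = height_px,
                 width_px = width_px, scale_mm_per_px = scale_mm_per_px,
                 faz_radius_mm = faz_radius_mm,
                 n_root_vessels = as.integer(n_root_vessels),
                 branch_probability = branch_probability,
                 width_range_px = as.numeric(width_range_px),
                 capillary_density = capillary_density,
                 background_level = as.integer(background_level),
                 vessel_level = as.integer(vessel_level),
                 capillary_level = as.integer(capillary_level),
                 width_gain = width_gain, noise_sigma = noise_sigma,
                 noise_type = noise_type, laterality = laterality),
            class = "phantom_params")
}

#' Generate a ground-truth vascular network
#'
#' Grows a branching vascular tree per root vessel by a biased random walk:
#' each walker enters from the image border aimed at the fovea, advances in
#' sub-pixel steps with angular jitter, tapers along its length, spawns side
#' branches with probability `branch_probability` per step, and terminates on
#' leaving the image or on reaching the FAZ disc (which no vessel ever
#' enters). Short thin capillary segments are then scattered over the field
#' according to `capillary_density`. The result carries the exact boolean
#' vessel and centerline masks plus per-sector ground-truth pixel counts, so
#' densitometric metrics have a known truth. Deterministic for a fixed seed.
#'
#' @param params a [phantom_params()].
#' @return An object of class `octa_ground_truth`: `vessel_mask`,
#'   `centerline_mask`, `capillary_mask` (subset of `vessel_mask`),
#'   `width_map` (local calibre at vessel pixels, 0 elsewhere),
#'   `fovea_center`, `per_sector_true_counts` (data frame: `sector`,
#'   `vessel_px`, `centerline_px`, `total_px`) and the originating `params`.
#' @export
generate_network <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  nr <- params$height_px; nc <- params$width_px
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  faz_px <- params$faz_radius_mm / params$scale_mm_per_px
  wmin <- params$width_range_px[1]; wmax <- params$width_range_px[2]

  with_seed(params$seed, {
    pts_r <- integer(0); pts_c <- integer(0)
    pts_w <- numeric(0); pts_cap <- logical(0)
    add_chain <- function(r, c, w, capillary = FALSE) {
      pts_r <<- c(pts_r, r); pts_c <<- c(pts_c, c)
      pts_w <<- c(pts_w, rep_len(w, length(r)))
      pts_cap <<- c(pts_cap, rep_len(capillary, length(r)))
    }

    # walker state: position, heading, width, branch depth. Each walker's
    # step budget is ~1.5x its straight-line distance to the fovea, so trunks
    # span the field without wandering until they tile it.
    step_len <- 0.75
    walk <- function(pos, ang, w, depth) {
      w <- min(max(w, wmin), wmax)
      ch_r <- numeric(0); ch_c <- numeric(0); ch_w <- numeric(0)
      children <- list()
      max_steps <- ceiling(1.5 * sqrt(sum((pos - ctr)^2)) / step_len)
      for (i in seq_len(max_steps)) {
        nxt <- pos + step_len * c(-cos(ang), sin(ang))
        if (nxt[1] < 1 || nxt[1] > nr || nxt[2] < 1 || nxt[2] > nc) break
        if (sqrt(sum((nxt - ctr)^2)) <= faz_px + w / 2 + 1) break
        pos <- nxt
        ch_r <- c(ch_r, round(pos[1])); ch_c <- c(ch_c, round(pos[2]))
        ch_w <- c(ch_w, w)
        ang <- ang + stats::rnorm(1L, 0, 0.08)
        w <- w * 0.9985
        if (w < wmin) break             # below trunk calibre: mesh territory
        if (depth < 4L && stats::runif(1L) < params$branch_probability) {
          wc <- w * stats::runif(1L, 0.6, 0.8)
          if (wc >= wmin)
            children[[length(children) + 1L]] <-
              list(pos = pos,
                   ang = ang + sample(c(-1, 1), 1L) * stats::runif(1L, 0.5, 1.1),
                   w = wc, depth = depth + 1L)
        }
      }
      if (length(ch_r)) add_chain(ch_r, ch_c, ch_w)
      children
    }

    # roots: evenly spread entry angles around the border, jittered
    base_ang <- seq(0, 2 * pi, length.out = params$n_root_vessels + 1L)[
      seq_len(params$n_root_vessels)]
    queue <- lapply(base_ang, function(a) {
      a <- a + stats::runif(1L, -0.2, 0.2)
      # border entry point along direction a from the center
      dir <- c(-cos(a), sin(a))
      tmax <- min(ifelse(dir[1] > 0, (nr - ctr[1]) / dir[1],
                         ifelse(dir[1] < 0, (1 - ctr[1]) / dir[1], Inf)),
                  ifelse(dir[2] > 0, (nc - ctr[2]) / dir[2],
                         ifelse(dir[2] < 0, (1 - ctr[2]) / dir[2], Inf)))
      pos <- ctr + (tmax - 0.5) * dir
      # head back toward the center, jittered
      list(pos = pos, ang = a + pi + stats::rnorm(1L, 0, 0.15),
           w = stats::runif(1L, 0.7, 1) * wmax, depth = 0L)
    })
    # branch cascade capped so the tree stays at a retina-like areal density
    max_segments <- 12L * params$n_root_vessels
    n_segments <- 0L
    while (length(queue) && n_segments < max_segments) {
      st <- queue[[1L]]; queue <- queue[-1L]
      n_segments <- n_segments + 1L
      queue <- c(queue, walk(st$pos, st$ang, st$w, st$depth))
    }

    # capillary mesh: short, thin, dim segments scattered outside the FAZ;
    # at the default density the mesh carries a length share comparable to
    # the trunk tree, as in the real superficial plexus
    n_cap <- round(params$capillary_density * nr * nc / 40)
    for (i in seq_len(n_cap)) {
      repeat {
        p0 <- c(stats::runif(1L, 2, nr - 1), stats::runif(1L, 2, nc - 1))
        if (sqrt(sum((p0 - ctr)^2)) > faz_px + 2) break
      }
      a <- stats::runif(1L, 0, 2 * pi)
      len <- sample(4:12, 1L)
      t <- seq(0, len, by = 0.7)
      rr <- round(p0[1] - t * cos(a)); cc <- round(p0[2] + t * sin(a))
      keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc &
        sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2) > faz_px + 1
      if (any(keep))
        add_chain(rr[keep], cc[keep], stats::runif(1L, 0.8, 1.6),
                  capillary = TRUE)
    }

    centerline <- matrix(FALSE, nr, nc)
    vessel <- matrix(FALSE, nr, nc)
    capillary <- matrix(FALSE, nr, nc)
    width_map <- matrix(0, nr, nc)
    if (length(pts_r)) {
      lin <- (pts_c - 1L) * nr + pts_r
      centerline[lin] <- TRUE
      # stamp each centerline pixel with a disc of its local width
      radii <- pmax(0L, round((pts_w - 1) / 2))
      for (rad in sort(unique(radii))) {
        sel <- radii == rad
        d <- -rad:rad
        offs <- expand.grid(dr = d, dc = d)
        offs <- offs[offs$dr^2 + offs$dc^2 <= (rad + 0.5)^2, ]
        for (k in seq_len(nrow(offs))) {
          rr <- pts_r[sel] + offs$dr[k]; cc <- pts_c[sel] + offs$dc[k]
          ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
          li <- (cc[ok] - 1L) * nr + rr[ok]
          vessel[li] <- TRUE
          width_map[li] <- pmax(width_map[li], pts_w[sel][ok])
          capillary[li] <- capillary[li] | pts_cap[sel][ok]
        }
      }
      capillary <- capillary & vessel
    }

    # enforce FAZ exclusion exactly (dilation may graze the disc boundary)
    DR <- matrix(seq_len(nr) - ctr[1], nr, nc)
    DC <- matrix(seq_len(nc) - ctr[2], nr, nc, byrow = TRUE)
    in_faz <- sqrt(DR^2 + DC^2) < faz_px
    vessel[in_faz] <- FALSE
    centerline[in_faz] <- FALSE
    capillary[in_faz] <- FALSE
    width_map[!vessel] <- 0
    centerline <- centerline & vessel

    grid <- build_etdrs_grid(c(nr, nc), ctr, params$scale_mm_per_px,
                             params$laterality)
    cnt <- sector_counts(vessel, centerline, grid)
    truth <- list(vessel_mask = vessel, centerline_mask = centerline,
                  capillary_mask = capillary, width_map = width_map,
                  fovea_center = ctr,
                  per_sector_true_counts = data.frame(
                    sector = cnt$sector, vessel_px = cnt$W,
                    centerline_px = cnt$S, total_px = cnt$T),
                  params = params)
    class(truth) <- "octa_ground_truth"
    truth
  })
}

#' @export
print.octa_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<octa_ground_truth> %d x %d px, %.2f%% vessel, %.2f%% centerline\n",
    nrow(x$vessel_mask), ncol(x$vessel_mask),
    100 * mean(x$vessel_mask), 100 * mean(x$centerline_mask)))
  invisible(x)
}

#' Render a ground-truth network as an angiogram
#'
#' Paints the phantom as an 8-bit grayscale en-face angiogram: background at
#' `background_level`, vessel pixels at `vessel_level` minus `width_gain`
#' per pixel of calibre below the maximum (brightness increases with local
#' width), capillary pixels at the dimmer `capillary_level`, then seeded
#' noise (additive Gaussian or multiplicative speckle of scale
#' `noise_sigma`) and clipping to `0..255`. With `noise_sigma = 0`,
#' `capillary_density = 0` and a constant `width_range_px` the rendering has
#' exactly two intensity levels and midpoint thresholding recovers the truth
#' mask exactly.
#'
#' @param truth an [generate_network()] result.
#' @param params the matching [phantom_params()] (defaults to the ones
#'   stored in `truth`).
#' @return An [en_face_angiogram()] with the phantom's scale, laterality and
#'   fovea center.
#' @export
render_angiogram <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "octa_ground_truth"),
            inherits(params, "phantom_params"))
  if (!identical(dim(truth$vessel_mask),
                 c(params$height_px, params$width_px)))
    stopf("truth shape does not match params")
  img <- matrix(as.numeric(params$background_level),
                params$height_px, params$width_px)
  lvl <- params$vessel_level -
    params$width_gain * pmax(0, params$width_range_px[2] - truth$width_map)
  img[truth$vessel_mask] <- lvl[truth$vessel_mask]
  img[truth$capillary_mask] <- params$capillary_level
  if (params$noise_sigma > 0) {
    img <- with_seed(params$seed + 1000003L, {
      eps <- stats::rnorm(length(img), 0, params$noise_sigma)
      if (params$noise_type == "gaussian") img + eps
      else img * (1 + eps / 128)
    })
  }
  img <- matrix(as.integer(pmin(255, pmax(0, round(img)))),
                params$height_px, params$width_px)
  en_face_angiogram(img, bit_depth = 8L,
                    scale_mm_per_px = params$scale_mm_per_px,
                    laterality = params$laterality,
                    fovea_center = truth$fovea_center)
}

#' Write a phantom to disk
#'
#' Writes the rendered angiogram (PNG or PGM by extension) together with a
#' sidecar JSON holding the generating parameters and the ground-truth
#' per-sector counts.
#'
#' @param truth an [generate_network()] result.
#' @param path image path; the JSON sidecar gets the same stem plus
#'   `.json`.
#' @return Invisibly, the two paths written.
#' @export
write_phantom <- function(truth, path) {
  stopifnot(inherits(truth, "octa_ground_truth"))
  img <- render_angiogram(truth)
  write_angiogram(img, path)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  p <- truth$params
  p$noise_type <- as.character(p$noise_type)
  jsonlite::write_json(
    list(params = unclass(p),
         per_sector_true_counts = truth$per_sector_true_counts),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}
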