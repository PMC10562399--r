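# Independent oracles used to cross-check package implementations.

# Literal per-candidate evaluation of the Shanbhag information-measure
# objective: cumulative masses, fuzzy entropies of the two classes for every
# admissible threshold, arg-min with lowest-index ties. Kept structurally
# independent of the package's vectorized outer-product formulation.
oracle_shanbhag <- function(counts) {
  norm <- counts / sum(counts)
  P1 <- cumsum(norm)
  P2 <- 1 - P1
  P1prev <- c(0, P1[-256])
  first_bin <- which(P1 >= .Machine$double.eps)[1]
  last_bin <- max(which(P2 >= .Machine$double.eps))
  threshold <- -1L
  min_ent <- Inf
  for (it in first_bin:last_bin) {
    term <- 0.5 / P1[it]
    ent_back <- -sum(norm[1:it] * log(1 - term * P1prev[1:it])) * term
    term <- 0.5 / P2[it]
    ent_obj <- -sum(norm[(it + 1):256] * log(1 - term * P2[(it + 1):256])) *
      term
    tot <- abs(ent_back - ent_obj)
    if (tot < min_ent) {
      min_ent <- tot
      threshold <- it
    }
  }
  threshold - 1L
}

# Exhaustive BFS flood fill for connected-component counting.
oracle_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  seen <- matrix(FALSE, nr, nc)
  ncomp <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      r <- (i - 1L) %% nr + 1L
      c <- (i - 1L) %/% nr + 1L
      for (o in offs) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          j <- (cc - 1L) * nr + rr
          if (mask[j] && !seen[j]) {
            seen[j] <- TRUE
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  ncomp
}

# Brute-force windowed minimum with replicate padding, per pixel.
oracle_min_filter <- function(px, window) {
  nr <- nrow(px); nc <- ncol(px)
  out <- px
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      rows <- pmin(r:(r + window - 1L), nr)
      cols <- pmin(c:(c + window - 1L), nc)
      out[r, c] <- min(px[rows, cols])
    }
  }
  out
}

# Brute-force spatial convolution of an image with an explicitly sampled
# (negated, zero-sum) Laplacian-of-Gaussian kernel, replicate padding.
oracle_log_response <- function(px, sigma) {
  r <- ceiling(4 * sigma)
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  g2 <- (x^2 - sigma^2) / sigma^4 * exp(-x^2 / (2 * sigma^2))
  g2 <- g2 - mean(g2)
  K <- -(outer(g2, g) + outer(g, g2))
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(0, nr, nc)
  for (rr in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      acc <- 0
      for (i in seq_along(x)) {
        ri <- min(max(rr + x[i], 1L), nr)
        for (j in seq_along(x)) {
          cj <- min(max(cc + x[j], 1L), nc)
          acc <- acc + K[i, j] * px[ri, cj]
        }
      }
      out[rr, cc] <- acc
    }
  }
  out
}

# Small phantoms for fast unit tests (60 um/px-scale world, same structure).
small_params <- function(seed, ...) {
  phantom_params(seed = seed, height_px = 128L, width_px = 128L,
                 scale_mm_per_px = 6 / 128, ...)
}

# Random blobby masks: thresholded noise plus a few discs, seeded.
random_mask <- function(seed, nr = 40L, nc = 40L, p = 0.35) {
  set.seed(seed)
  m <- matrix(stats::runif(nr * nc) < p, nr, nc)
  for (i in seq_len(3L)) {
    r0 <- stats::runif(1, 5, nr - 5); c0 <- stats::runif(1, 5, nc - 5)
    rad <- stats::runif(1, 2, 6)
    D <- outer((seq_len(nr) - r0)^2, (seq_len(nc) - c0)^2, "+")
    m <- m | (D <= rad^2)
  }
  m
}

# Minimal hand-built ETDRS grid stand-in for repeatability-error tests.
fake_grid <- function(shape, inner_masks) {
  masks <- stats::setNames(
    rep(list(matrix(FALSE, shape[1], shape[2])), 9L), etdrs_sector_labels)
  for (lbl in names(inner_masks)) masks[[lbl]] <- inner_masks[[lbl]]
  structure(list(sector_masks = masks, center = shape / 2,
                 scale_mm_per_px = 1, laterality = "OD", shape = shape),
            class = "etdrs_grid")
}
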