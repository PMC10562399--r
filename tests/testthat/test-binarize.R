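img8 <- function(px) en_face_angiogram(px, bit_depth = 8L,
                                       scale_mm_per_px = 6 / ncol(px))

rand_hist <- function(seed) {
  set.seed(seed)
  counts <- rpois(256L, lambda = runif(1, 0.5, 30))
  if (sum(counts > 0) < 2L) counts[c(40L, 200L)] <- counts[c(40L, 200L)] + 1L
  counts
}

test_that("shanbhag_threshold equals the exhaustive arg-min oracle", {
  for (s in 1:50)
    expect_identical(shanbhag_threshold(rand_hist(s)),
                     oracle_shanbhag(rand_hist(s)))
})

test_that("shanbhag_threshold separates a two-spike histogram", {
  counts <- integer(256L)
  counts[41L] <- 700L; counts[201L] <- 300L   # grey levels 40 and 200
  t <- shanbhag_threshold(counts)
  expect_identical(t, oracle_shanbhag(counts))
  expect_true(t >= 40L && t < 200L)           # binarization splits the spikes
})

test_that("shanbhag_threshold is invariant to count scaling", {
  for (s in c(3, 11)) {
    counts <- rand_hist(s)
    expect_identical(shanbhag_threshold(counts),
                     shanbhag_threshold(2L * counts))
  }
})

test_that("shanbhag_threshold rejects degenerate histograms", {
  counts <- integer(256L); counts[100L] <- 50L
  expect_error(shanbhag_threshold(counts), "fewer than two")
  expect_error(shanbhag_threshold(integer(10L)), "256")
})

test_that("log_filter annihilates constants and is ridge-positive", {
  flat <- img8(matrix(123L, 32, 32))
  expect_lt(max(abs(log_filter(flat, 2))), 1e-9 * 123)
  px <- matrix(10L, 32, 32); px[15:17, ] <- 200L  # bright 3-px line
  resp <- log_filter(img8(px), 2)
  expect_true(all(resp[16, 5:28] > 0))
  expect_error(log_filter(img8(matrix(0L, 10, 10)), 4), "larger")
  expect_error(log_filter(flat, -1), "positive")
})

test_that("log_filter agrees with the brute-force convolution oracle", {
  set.seed(7)
  px <- matrix(0L, 18, 18)
  px[, 10:18] <- 150L                         # bright step profile
  px <- px + matrix(sample.int(20L, 324L, replace = TRUE), 18, 18)
  resp <- log_filter(img8(px), 1.5)
  expect_equal(resp, oracle_log_response(px, 1.5), tolerance = 1e-10)
})

test_that("MHF binarization is monotone in the cutoff and quiet on flats", {
  expect_false(any(binarize_mhf(img8(matrix(55L, 32, 32)), 2)$mask))
  px <- matrix(10L, 48, 48); px[20:24, 5:44] <- 220L
  a <- img8(px)
  n_prev <- Inf
  for (cut in c(0, 1, 5, 20)) {
    n <- sum(binarize_mhf(a, 2, cutoff = cut)$mask)
    expect_lte(n, n_prev)
    n_prev <- n
  }
  b <- binarize_mhf(a, 2)
  expect_identical(b$method, "MHF")
  expect_identical(b$threshold_used, 0)
})

test_that("MHF detects ridge interiors of a noise-free phantom", {
  # ridge-scale calibre (~sigma): the regime where a zero-cutoff response
  # is positive across the whole vessel interior
  p <- small_params(5, noise_sigma = 0, capillary_density = 0,
                    width_range_px = c(3, 4))
  gt <- generate_network(p)
  b <- binarize_mhf(render_angiogram(gt), sigma_px = 2)
  # erode the truth by 1 px (8-neighborhood) and require full detection there
  v <- gt$vessel_mask
  nr <- nrow(v); nc <- ncol(v)
  er <- v
  for (dr in -1:1) for (dc in -1:1) {
    sh <- v[pmin(pmax(seq_len(nr) + dr, 1), nr),
            pmin(pmax(seq_len(nc) + dc, 1), nc)]
    er <- er & sh
  }
  expect_gt(sum(er), 200)                     # the check is non-vacuous
  expect_true(all(b$mask[er]))
})

test_that("ST binarization matches the oracle threshold pixel by pixel", {
  set.seed(9)
  px <- matrix(sample.int(251L, 64L, replace = TRUE) - 1L, 8, 8)
  px[1] <- 250L                               # pin the observed maximum
  a <- img8(px)
  b <- binarize_st(a)
  h <- grey_histogram(a)
  t <- oracle_shanbhag(h$counts)
  expect_identical(b$threshold_used, t)
  for (i in seq_len(64L)) {                   # enumerate all 64 pixels
    bin <- min(255L, (px[i] * 256L) %/% 251L)
    expect_identical(unname(b$mask[i]), bin > t)
  }
  expect_identical(b$method, "ST")
})

test_that("ST removes the FAZ automatically on phantoms", {
  p <- small_params(4)
  gt <- generate_network(p)
  b <- binarize_st(render_angiogram(gt))
  n <- p$height_px
  ctr <- gt$fovea_center
  D <- sqrt(outer((seq_len(n) - ctr[1])^2, (seq_len(n) - ctr[2])^2, "+"))
  in_faz <- D < p$faz_radius_mm / p$scale_mm_per_px
  expect_true(any(in_faz))
  expect_false(any(b$mask[in_faz]))
  expect_error(binarize_st(img8(matrix(9L, 16, 16))), "fewer than two")
})

test_that("noise-free ST mask never exceeds the above-background set", {
  p <- small_params(8, noise_sigma = 0)
  gt <- generate_network(p)
  img <- render_angiogram(gt)
  b <- binarize_st(img)
  expect_lte(sum(b$mask), sum(img$pixels > p$background_level))
})
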