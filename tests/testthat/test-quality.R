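test_that("noise_reduction is the black fraction", {
  expect_equal(noise_reduction(matrix(TRUE, 5, 5)), 0)
  expect_equal(noise_reduction(matrix(FALSE, 5, 5)), 1)
  m <- matrix(FALSE, 10, 10); m[seq_len(34)] <- TRUE
  expect_equal(noise_reduction(m), 0.66)
  expect_equal(noise_reduction(m) + mean(m), 1)
})

test_that("count_components matches the flood-fill oracle", {
  expect_identical(count_components(matrix(FALSE, 4, 4)), 0L)
  two <- matrix(FALSE, 12, 12)
  two[2:4, 2:4] <- TRUE; two[8:10, 8:10] <- TRUE
  expect_identical(count_components(two), 2L)
  diagonal <- matrix(FALSE, 4, 4)
  diagonal[1, 1] <- TRUE; diagonal[2, 2] <- TRUE
  expect_identical(count_components(diagonal, 8L), 1L)
  expect_identical(count_components(diagonal, 4L), 2L)
  for (s in 1:30) {
    m <- random_mask(s, nr = 25L, nc = 25L)
    expect_identical(count_components(m, 8L), oracle_components(m, 8L))
    expect_identical(count_components(m, 4L), oracle_components(m, 4L))
  }
  expect_error(count_components(two, 6L), "4 or 8")
})

test_that("grid placement error is zero for identical placements", {
  m <- random_mask(1, 30L, 30L)
  inner <- list(S1 = matrix(FALSE, 30, 30), N1 = matrix(FALSE, 30, 30),
                I1 = matrix(FALSE, 30, 30), T1 = matrix(FALSE, 30, 30))
  inner$S1[1:10, 1:10] <- TRUE; inner$N1[1:10, 21:30] <- TRUE
  inner$I1[21:30, 1:10] <- TRUE; inner$T1[21:30, 21:30] <- TRUE
  g <- fake_grid(c(30L, 30L), inner)
  expect_equal(grid_placement_error(m, list(g, g, g, g)), 0)
})

test_that("grid placement error averages per-sector CVs of white counts", {
  n <- 40L
  m <- matrix(TRUE, n, n)                     # counts = placement mask areas
  mk <- function(s1_px) {
    inner <- list(S1 = matrix(FALSE, n, n), N1 = matrix(FALSE, n, n),
                  I1 = matrix(FALSE, n, n), T1 = matrix(FALSE, n, n))
    inner$S1[seq_len(s1_px)] <- TRUE
    inner$N1[801:850] <- TRUE; inner$I1[901:950] <- TRUE
    inner$T1[1001:1050] <- TRUE
    fake_grid(c(n, n), inner)
  }
  grids <- lapply(c(100L, 100L, 100L, 102L), mk)
  expected <- 100 * mean(c(stats::sd(c(100, 100, 100, 102)) / 100.5, 0, 0, 0))
  expect_equal(grid_placement_error(m, grids), expected)
  expect_error(grid_placement_error(m, grids[1]), "at least two")
  # zero-mean sectors are excluded with a warning
  empty_inner <- mk(0L)
  expect_warning(
    grid_placement_error(matrix(c(TRUE, rep(FALSE, n * n - 1)), n, n),
                         lapply(c(1L, 1L), function(i) mk(100L))),
    "zero mean")
})

test_that("FAZ selection error follows the stated count formula", {
  n <- 30L
  m <- matrix(TRUE, n, n)
  mk <- function(px) {
    x <- matrix(FALSE, n, n); x[seq_len(px)] <- TRUE
    faz_selection(mask = x)
  }
  expect_equal(faz_selection_error(m, list(mk(100L), mk(100L))), 0)
  expect_equal(faz_selection_error(m, list(mk(98L), mk(100L), mk(102L))),
               100 * (4 / 3) / 100)
  # disjoint selections with equal counts: still zero (count-based metric)
  a <- matrix(FALSE, n, n); a[1:50] <- TRUE
  b <- matrix(FALSE, n, n); b[101:150] <- TRUE
  expect_equal(faz_selection_error(m, list(faz_selection(mask = a),
                                           faz_selection(mask = b))), 0)
  expect_error(faz_selection_error(matrix(FALSE, n, n),
                                   list(mk(10L), mk(20L))), "no white")
})

test_that("bland_altman reproduces hand-computed agreement statistics", {
  mhf <- c(11, 22, 33, 44, 55)
  st <- mhf - 1:5                             # diffs 1..5
  ba <- bland_altman(mhf, st)
  expect_identical(ba$n, 5L)
  expect_equal(ba$mean_diff, 3)
  expect_equal(ba$sd_diff, 1.5811388, tolerance = 1e-6)
  expect_equal(ba$loa_low, 3 - 1.96 * sd(1:5))
  expect_equal(ba$loa_high, 3 + 1.96 * sd(1:5))
  expect_equal(ba$ci_low, 3 - 1.96 * sd(1:5) / sqrt(5))
  expect_equal(ba$ci_high, 3 + 1.96 * sd(1:5) / sqrt(5))
  expect_equal(round(c(ba$loa_low, ba$loa_high), 4), c(-0.0990, 6.0990))
  expect_equal(round(c(ba$ci_low, ba$ci_high), 4), c(1.6141, 4.3859))
  expect_true(ba$significant)
})

test_that("bland_altman degenerate and shifted cases behave", {
  x <- c(1, 2, 3, 4)
  zero <- bland_altman(x, x)
  expect_equal(zero$mean_diff, 0)
  expect_equal(zero$sd_diff, 0)
  expect_equal(c(zero$loa_low, zero$loa_high), c(0, 0))
  expect_false(zero$significant)
  off <- bland_altman(x + 2, x)
  expect_equal(off$mean_diff, 2)
  expect_equal(off$sd_diff, 0)
  expect_true(off$significant)
  # equivariance: adding a constant to MHF shifts the mean, not the SD
  set.seed(5)
  a <- rnorm(10); b <- rnorm(10)
  ba0 <- bland_altman(a, b)
  ba1 <- bland_altman(a + 7, b)
  expect_equal(ba1$mean_diff, ba0$mean_diff + 7)
  expect_equal(ba1$sd_diff, ba0$sd_diff)
  expect_error(bland_altman(c(1, 2), c(1, 2)), "at least 3")
})

test_that("t-quantile confidence intervals are available", {
  ba <- bland_altman(c(11, 22, 33, 44, 55), c(10, 20, 30, 40, 50),
                     ci_method = "t")
  half <- qt(0.975, 4) * ba$sd_diff / sqrt(5)
  expect_equal(ba$ci_high - ba$mean_diff, half)
})

test_that("diff_mean_correlation signs trends and flags degeneracy", {
  pts <- data.frame(mean = 1:10, diff = 10:1)  # shrinking differences
  expect_lt(diff_mean_correlation(pts), 0)
  expect_true(is.na(diff_mean_correlation(data.frame(mean = 1:5,
                                                     diff = rep(2, 5)))))
  set.seed(8)
  x <- rnorm(50); y <- 0.3 * x + rnorm(50, sd = 0.5)
  pts <- data.frame(mean = x, diff = y)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(diff_mean_correlation(pts), direct, tolerance = 1e-12)
})

test_that("fragmentation percent difference uses the reporting formula", {
  expect_equal(fragmentation_pct_diff(4000, 3000), 25)
  expect_error(fragmentation_pct_diff(0, 1), "positive")
})
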