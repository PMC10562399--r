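test_that("central-disc pixel count matches the exhaustive distance test", {
  n <- 1024L; scale <- 6 / n
  g <- build_etdrs_grid(c(n, n), c((n + 1) / 2, (n + 1) / 2), scale, "OD")
  D <- scale * sqrt(outer((seq_len(n) - (n + 1) / 2)^2,
                          (seq_len(n) - (n + 1) / 2)^2, "+"))
  expect_identical(sum(g$sector_masks$C), sum(D < 0.5))
  expect_lt(abs(sum(g$sector_masks$C) - pi * (0.5 / scale)^2),
            0.01 * pi * (0.5 / scale)^2)
  # inner-ring quadrants: equal to each other and to the analytic area
  areas <- vapply(c("S1", "N1", "I1", "T1"),
                  function(l) sum(g$sector_masks[[l]]), 0L)
  analytic <- pi * (1.5^2 - 0.5^2) / 4 / scale^2
  expect_true(all(abs(areas - analytic) < 0.01 * analytic))
  expect_lt(diff(range(areas)), 0.01 * mean(areas))
})

test_that("the nine sectors partition the 3 mm disc exactly", {
  configs <- list(
    list(n = 160L, ctr = c(80.5, 80.5), lat = "OD"),
    list(n = 160L, ctr = c(80.5, 80.5), lat = "OS"),
    list(n = 160L, ctr = c(60.2, 95.7), lat = "OD"),   # off-center
    list(n = 128L, ctr = c(30.0, 90.0), lat = "OS"),   # heavily clipped
    list(n = 200L, ctr = c(100.5, 100.5), lat = "OD"))
  for (cf in configs) {
    n <- cf$n
    g <- build_etdrs_grid(c(n, n), cf$ctr, 6 / n, cf$lat)
    D <- (6 / n) * sqrt(outer((seq_len(n) - cf$ctr[1])^2,
                              (seq_len(n) - cf$ctr[2])^2, "+"))
    stack <- Reduce(`+`, lapply(g$sector_masks, function(m) m * 1L))
    expect_true(all(stack <= 1L))                       # pairwise disjoint
    expect_identical(stack == 1L, D < 3.0)              # union = 3 mm disc
  }
})

test_that("laterality swaps exactly the temporal and nasal masks", {
  n <- 96L
  od <- build_etdrs_grid(c(n, n), c(48.5, 48.5), 6 / n, "OD")
  os <- build_etdrs_grid(c(n, n), c(48.5, 48.5), 6 / n, "OS")
  for (lbl in c("C", "S1", "I1", "S2", "I2"))
    expect_identical(od$sector_masks[[lbl]], os$sector_masks[[lbl]])
  expect_identical(od$sector_masks$T1, os$sector_masks$N1)
  expect_identical(od$sector_masks$N1, os$sector_masks$T1)
  expect_identical(od$sector_masks$T2, os$sector_masks$N2)
  # on a right-eye image the temporal quadrant lies on the left
  cols_t <- which(od$sector_masks$T2, arr.ind = TRUE)[, "col"]
  expect_lt(mean(cols_t), 48.5)
  expect_error(build_etdrs_grid(c(n, n), c(48.5, 48.5), 0, "OD"), "positive")
  expect_error(build_etdrs_grid(c(n, n), c(200, 48.5), 6 / n, "OD"), "inside")
})

test_that("sector_counts counts white, skeleton and area pixels", {
  n <- 96L
  g <- build_etdrs_grid(c(n, n), c(48.5, 48.5), 6 / n, "OD")
  none <- matrix(FALSE, n, n)
  all_px <- matrix(TRUE, n, n)
  z <- sector_counts(none, none, g)
  expect_true(all(z$W == 0L) && all(z$S == 0L))
  full <- sector_counts(all_px, skeletonize(all_px), g)
  expect_identical(full$W, full$T)
  expect_true(all(full$S <= full$W))
  expect_error(sector_counts(matrix(FALSE, 5, 5), none, g), "shape")
})

test_that("vessel_metrics implements the ratio forms and flags VDI", {
  m <- vessel_metrics(W = c(1000, 0, 362), S = c(1000, 0, 134), T = 1000)
  expect_equal(m$VD, c(1, 0, 0.362))
  expect_equal(m$SkD, c(1, 0, 0.134))
  expect_equal(m$VDI, c(1, NA, 362 / 134))
  expect_equal(m$VDI[3], 2.7015, tolerance = 1e-4)
  expect_error(vessel_metrics(1, 1, 0), "positive")
  expect_error(vessel_metrics(W = 5, S = 7, T = 10), "S <= W")
})

test_that("VDI times SkD returns VD wherever defined", {
  for (s in 1:20) {
    set.seed(s)
    T <- sample(50:5000, 9)
    W <- vapply(T, function(t) sample.int(t, 1L), 0L)
    S <- vapply(W, function(w) sample.int(w + 1L, 1L) - 1L, 0L)
    m <- vessel_metrics(W, S, T)
    def <- !is.na(m$VDI)
    expect_true(all(abs(m$VDI[def] * m$SkD[def] - m$VD[def]) < 1e-12))
    expect_true(all(m$SkD <= m$VD))
  }
})

test_that("adding vessel pixels never decreases a sector's VD", {
  n <- 96L
  g <- build_etdrs_grid(c(n, n), c(48.5, 48.5), 6 / n, "OD")
  set.seed(1)
  m1 <- matrix(runif(n * n) < 0.2, n, n)
  m2 <- m1 | (matrix(runif(n * n) < 0.1, n, n))
  sk <- matrix(FALSE, n, n)
  vd1 <- sector_metrics(m1, sk, g)$VD
  vd2 <- sector_metrics(m2, sk, g)$VD
  expect_true(all(vd2 >= vd1))
})

test_that("cohort_summary aggregates with n-1 SD and quartiles", {
  base <- sector_metrics(matrix(FALSE, 96, 96), matrix(FALSE, 96, 96),
                         build_etdrs_grid(c(96, 96), c(48.5, 48.5), 6 / 96,
                                          "OD"),
                         subject_id = 1)
  mk <- function(id, vd) {
    x <- base; x$subject_id <- id
    x$VD <- vd; x$SkD <- vd / 2; x$VDI <- 2
    x
  }
  cs <- cohort_summary(list(mk(1, 2), mk(2, 4), mk(3, 6)))
  row <- cs[cs$metric == "VD" & cs$sector == "C", ]
  expect_equal(row$mean, 4)
  expect_equal(row$sd, 2)                     # sample SD of {2,4,6}
  expect_equal(row$median, 4)
  expect_equal(row$q1, 3)                     # type-7 linear interpolation
  expect_identical(row$n, 3L)
  one <- cohort_summary(mk(1, 2))
  expect_equal(one$sd[one$metric == "VD" & one$sector == "C"], 0)
  expect_identical(one$n[1], 1L)
  expect_error(cohort_summary(list()), "at least one")
  # undefined VDI entries are excluded and counted
  a <- mk(1, 2); a$VDI <- NA_real_
  cs2 <- cohort_summary(list(a, mk(2, 4)))
  vdi_row <- cs2[cs2$metric == "VDI" & cs2$sector == "C", ]
  expect_identical(vdi_row$n, 1L)
  expect_identical(vdi_row$n_undefined, 1L)
})

test_that("phantom ground-truth counts equal sector_counts on its masks", {
  p <- small_params(12)
  gt <- generate_network(p)
  g <- build_etdrs_grid(dim(gt$vessel_mask), gt$fovea_center,
                        p$scale_mm_per_px, p$laterality)
  cnt <- sector_counts(gt$vessel_mask, gt$centerline_mask, g)
  expect_identical(cnt$W, gt$per_sector_true_counts$vessel_px)
  expect_identical(cnt$S, gt$per_sector_true_counts$centerline_px)
  expect_identical(cnt$T, gt$per_sector_true_counts$total_px)
})
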