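test_that("disk partition realizes the 20/30/50 fractions to rank-cut precision", {
  part <- partition_zones(disk_mask(200))
  expect_lt(abs(part$realized_fractions[1] - 0.2), 0.001)
  expect_lt(abs(part$realized_fractions[2] - 0.3), 0.001)
  expect_lt(abs(part$realized_fractions[3] - 0.5), 0.001)
})

test_that("the outer zone of a disk is the closed-form annulus", {
  # annulus holding 20% of a radius-200 disk has inner radius 200*sqrt(0.8)
  part <- partition_zones(disk_mask(200))
  side <- nrow(part$labels)
  ctr <- (side + 1) / 2
  idx <- which(part$labels == 1L, arr.ind = TRUE)
  r_from_center <- sqrt((idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2)
  expect_lt(abs(min(r_from_center) - 200 * sqrt(0.8)), 2)
  idx_in <- which(part$labels == 3L, arr.ind = TRUE)
  r_inner <- sqrt((idx_in[, 1] - ctr)^2 + (idx_in[, 2] - ctr)^2)
  expect_lt(abs(max(r_inner) - 200 * sqrt(0.5)), 2)
})

test_that("degenerate fractions give zero-area zones, not errors", {
  part <- partition_zones(disk_mask(40), fractions = c(1, 0, 0))
  expect_equal(part$realized_fractions, c(1, 0, 0))
  expect_equal(sum(part$labels == 1L), mask_area(disk_mask(40)))
})

test_that("zones conserve the tumor pixel count exactly on random blobs", {
  for (s in 1:10) {
    m <- random_blob_mask(radius = 30 + 3 * s, seed = s)
    part <- partition_zones(m)
    expect_identical(sum(part$labels > 0L), mask_area(m))
    A <- mask_area(m)
    expect_lt(max(abs(part$realized_fractions - c(0.2, 0.3, 0.5))), 2 / A)
    # distance ordering: outer pixels never deeper than inner pixels
    d <- part$distance
    expect_lte(max(d[part$labels == 1L]), min(d[part$labels == 3L]) + 1e-9)
  }
})

test_that("partition tie-breaks are bit-reproducible", {
  m <- random_blob_mask(radius = 35, seed = 3)
  expect_identical(partition_zones(m)$labels, partition_zones(m)$labels)
})

test_that("partition validates fractions and mask size", {
  expect_error(partition_zones(disk_mask(40), fractions = c(0.2, 0.3, 0.4)),
               "sum to 1")
  expect_error(partition_zones(binary_mask(matrix(FALSE, 10, 10))), "empty")
  small <- binary_mask(matrix(TRUE, 10, 10))
  expect_error(partition_zones(small), "1024")
})

test_that("detect_nuclei recovers the generated field almost perfectly", {
  tm <- disk_mask(96, margin = 8)
  f <- gen_ki67_field(c(0.45, 0.30, 0.15), 5, tm, seed = 3)
  det <- detect_nuclei(f)
  truth <- f$nuclei_truth
  pairs <- match_nuclei(det, truth, tol = 3)
  expect_gte(nrow(pairs) / nrow(det), 0.95)    # precision
  expect_gte(nrow(pairs) / nrow(truth), 0.95)  # recall
  agree <- det$positive[pairs$det] ==
    (truth$label[pairs$tru] == "positive")
  expect_gte(mean(agree), 0.98)
})

test_that("an all-negative field yields zero positive calls", {
  f <- gen_ki67_field(c(0, 0, 0), 4, disk_mask(64, margin = 8), seed = 6)
  det <- detect_nuclei(f)
  expect_gt(nrow(det), 0)
  expect_equal(sum(det$positive), 0L)
})

test_that("score_ki67 computes zone percentages and flags empty zones", {
  part <- partition_zones(disk_mask(60))
  side <- nrow(part$labels)
  outer_px <- which(part$labels == 1L, arr.ind = TRUE)[1:20, ]
  nuclei <- data.frame(x = outer_px[, 2] - 1L, y = outer_px[, 1] - 1L,
                       positive = rep(c(TRUE, FALSE), 10))
  sc <- score_ki67(nuclei, part)
  expect_equal(sc$zones$percent[sc$zones$zone == "outer"], 50)
  expect_true(is.na(sc$zones$percent[sc$zones$zone == "inner"]))
  expect_equal(sc$zones$total[sc$zones$zone == "inner"], 0L)
  expect_equal(sc$n_rejected, 0L)

  # a centroid outside the tumor goes to the reject bin
  nuclei2 <- rbind(nuclei, data.frame(x = 0, y = 0, positive = TRUE))
  expect_equal(score_ki67(nuclei2, part)$n_rejected, 1L)
})

test_that("scored zone percents recover the generator's triple on average", {
  targets <- c(0.45, 0.30, 0.15)
  tm <- disk_mask(192, margin = 8)
  part <- partition_zones(tm)
  acc <- matrix(0, nrow = 30, ncol = 3)
  for (s in 1:30) {
    f <- gen_ki67_field(targets, 5, tm, seed = s)
    sc <- score_ki67(f$nuclei_truth, part)
    acc[s, ] <- sc$zones$percent
  }
  means <- colMeans(acc, na.rm = TRUE)
  expect_true(all(abs(means - 100 * targets) < 2))
})
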