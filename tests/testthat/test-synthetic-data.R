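test_that("percolation generator honors trivial and precondition cases", {
  full <- gen_percolation_mask(2, 1.0, 3, seed = 1)
  expect_identical(dim(full$grid), c(8L, 8L))
  expect_equal(mask_area(full), 64L)

  expect_error(gen_percolation_mask(3, 0.10, 2, seed = 1), "subcritical")
  expect_error(gen_percolation_mask(2, 0, 2, seed = 1), "retain_prob")
  expect_error(gen_percolation_mask(2, 0.9, 13, seed = 1), "size cap")
})

test_that("percolation is deterministic given the spec and seed", {
  a <- gen_percolation_mask(5, 0.702, 3, seed = 42)
  b <- gen_percolation_mask(5, 0.702, 3, seed = 42)
  c <- gen_percolation_mask(5, 0.702, 3, seed = 43)
  expect_identical(a$grid, b$grid)
  expect_false(identical(a$grid, c$grid))
})

test_that("retained-cell counts match the branching expectation at depth L", {
  # mean log5(N_L)/L over non-extinct realizations approaches log5(25 p);
  # N_L is the foreground count, i.e. the level-L box count at box size 1
  p <- 0.702
  masks <- nonextinct_percolation(5, p, 5, n_masks = 100)
  lvl <- vapply(masks, function(m) log(mask_area(m), 5) / 5, numeric(1))
  expect_lt(abs(mean(lvl) - log(25 * p, 5)), 0.05)
})

test_that("section generator hits the target necrotic fraction exactly", {
  for (case in list(list(f = 0, p = "compact_interior", s = 1),
                    list(f = 0.374, p = "compact_interior", s = 7),
                    list(f = 0.374, p = "dispersed_peripheral", s = 7),
                    list(f = 0.8, p = "dispersed_peripheral", s = 2))) {
    sec <- gen_section(64, case$f, case$p, seed = case$s)
    realized <- mask_area(sec$necrosis_truth) / mask_area(sec$tumor_mask)
    expect_lt(abs(realized - case$f), 0.01)
    expect_false(any(sec$necrosis_truth$grid & !sec$tumor_mask$grid))
  }
  sec0 <- gen_section(64, 0, "compact_interior", seed = 1)
  expect_equal(mask_area(sec0$necrosis_truth), 0L)
})

test_that("section generator rejects invalid specs and is deterministic", {
  expect_error(gen_section(64, 1.2, "compact_interior"), "necrotic_fraction")
  expect_error(gen_section(16, 0.3, "compact_interior"), "radius_px")
  a <- gen_section(48, 0.3, "dispersed_peripheral", seed = 9)
  b <- gen_section(48, 0.3, "dispersed_peripheral", seed = 9)
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$necrosis_truth$grid, b$necrosis_truth$grid)
})

test_that("compact necrosis sits deeper than dispersed necrosis", {
  mean_depth <- function(pattern) {
    sec <- gen_section(96, 0.3, pattern, seed = 11)
    d <- xenometry:::boundary_distance(sec$tumor_mask)
    mean(d[sec$necrosis_truth$grid])
  }
  expect_gt(mean_depth("compact_interior"), mean_depth("dispersed_peripheral"))
})

test_that("ki67 field honors degenerate positivity fractions", {
  tm <- disk_mask(48, margin = 8)
  all_neg <- gen_ki67_field(c(0, 0, 0), 3, tm, seed = 2)
  expect_true(all(all_neg$nuclei_truth$label == "negative"))
  all_pos <- gen_ki67_field(c(1, 1, 1), 3, tm, seed = 2)
  expect_true(all(all_pos$nuclei_truth$label == "positive"))
})

test_that("ki67 nuclei stay inside the tumor and fractions track targets", {
  tm <- disk_mask(96, margin = 8)
  f <- gen_ki67_field(c(0.45, 0.30, 0.15), 5, tm, seed = 3)
  tr <- f$nuclei_truth
  expect_true(all(tm$grid[cbind(tr$y + 1L, tr$x + 1L)]))
  for (z in c("outer", "intermediate", "inner")) {
    sub <- tr[tr$zone == z, ]
    target <- c(outer = 0.45, intermediate = 0.30, inner = 0.15)[[z]]
    phat <- mean(sub$label == "positive")
    se <- sqrt(target * (1 - target) / nrow(sub))
    expect_lt(abs(phat - target), 3 * se + 1e-12)
  }
})

test_that("ki67 labels are Bernoulli draws at the specified zone rates", {
  # aggregate counts over 50 seeds, then a chi-square GOF per zone
  targets <- c(outer = 0.4, intermediate = 0.25, inner = 0.1)
  tm <- disk_mask(40, margin = 6)
  tot <- pos <- c(outer = 0, intermediate = 0, inner = 0)
  for (s in 1:50) {
    tr <- gen_ki67_field(unname(targets), 4, tm, seed = s)$nuclei_truth
    for (z in names(targets)) {
      tot[z] <- tot[z] + sum(tr$zone == z)
      pos[z] <- pos[z] + sum(tr$zone == z & tr$label == "positive")
    }
  }
  for (z in names(targets)) {
    pv <- stats::chisq.test(c(pos[z], tot[z] - pos[z]),
                            p = c(targets[z], 1 - targets[z]))$p.value
    expect_gt(pv, 0.001)
  }
})

test_that("ki67 placement errors out when the density is unplaceable", {
  expect_error(gen_ki67_field(c(0.5, 0.5, 0.5), 60, disk_mask(40, margin = 6),
                              seed = 1),
               "density too high")
})

test_that("cohort rows satisfy the caliper conventions", {
  ct <- gen_cohort(seed = 11)
  expect_true(all(ct$length_mm >= ct$width_mm))
  expect_true(all(ct$width_mm > 0))
  expect_identical(names(ct),
                   c("group", "animal_id", "day", "length_mm", "width_mm",
                     "weight_g"))
  # weights only on the final day
  expect_true(all(is.na(ct$weight_g[ct$day < max(ct$day)])))
  expect_true(all(is.finite(ct$weight_g[ct$day == max(ct$day)])))
})

test_that("cohort trajectories are linear in cube-root (radius) space", {
  ct <- gen_cohort(list(cohort_arm("control", 6, 519.4, 62.9)), seed = 4)
  vol <- suppressWarnings(tumor_volume(ct$length_mm, ct$width_mm))
  for (id in unique(ct$animal_id)) {
    sel <- ct$animal_id == id
    r <- vol[sel]^(1 / 3)
    fit <- lm(r ~ ct$day[sel])
    expect_lt(max(abs(residuals(fit))), 1e-9)
  }
})

test_that("cohort day-22 means land near their calibration targets", {
  ct <- gen_cohort(list(cohort_arm("control", 6, 519.4, 62.9)),
                   days = c(0, 22), seed = 11)
  vol <- tumor_volume(ct$length_mm, ct$width_mm)
  m22 <- mean(vol[ct$day == 22])
  expect_lt(abs(m22 - 519.4), 3 * 62.9)
})

test_that("arms ordered by final mean stay ordered in expectation", {
  mean22 <- c(rhGCSF = 0, control = 0)
  for (s in 1:30) {
    ct <- gen_cohort(list(cohort_arm("control", 6, 519.4, 62.9),
                          cohort_arm("rhGCSF", 7, 282.0, 30.7)),
                     seed = s)
    vol <- tumor_volume(ct$length_mm, ct$width_mm)
    for (g in names(mean22)) {
      mean22[g] <- mean22[g] + mean(vol[ct$group == g & ct$day == 22]) / 30
    }
  }
  expect_gt(mean22["control"], mean22["rhGCSF"])
})

test_that("cohort generator validates its spec", {
  expect_error(cohort_arm("a", 1, 100, 10), "n >= 2")
  expect_error(cohort_arm("a", 3, -5, 10), "positive")
  expect_error(gen_cohort(start_mean_mm3 = -1, seed = 1), "positive")
  a <- gen_cohort(seed = 5)
  b <- gen_cohort(seed = 5)
  expect_identical(a, b)
})
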