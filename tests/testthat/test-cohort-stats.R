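test_that("caliper volume formula and the swap rule work", {
  expect_equal(tumor_volume(2, 2), 4)
  expect_equal(tumor_volume(10, 5), 125)
  expect_warning(v <- tumor_volume(5, 10), "swap")
  expect_equal(v, 125)
  expect_error(tumor_volume(-1, 2), "positive")
  expect_error(tumor_volume(3, 0), "positive")
})

test_that("tumor volume is scale-cubic", {
  set.seed(12)
  for (i in 1:20) {
    a <- runif(1, 5, 15)
    b <- runif(1, 1, a)
    k <- runif(1, 0.5, 3)
    expect_equal(tumor_volume(k * a, k * b), k^3 * tumor_volume(a, b))
  }
})

test_that("group summaries match hand arithmetic and are order-invariant", {
  ct <- data.frame(group = "g", animal_id = c("m1", "m2", "m3"), day = 0,
                   length_mm = c(2, 2, 2),
                   width_mm = sqrt(2 * c(1, 2, 3) / 2),
                   weight_g = NA_real_)
  s <- summarize_cohort(ct)
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3))

  perm <- ct[c(3, 1, 2), ]
  expect_equal(summarize_cohort(perm), s)

  single <- summarize_cohort(ct[1, ])
  expect_true(is.na(single$sem))
  expect_equal(single$n, 1L)
})

test_that("exact Mann-Whitney matches its stated small cases", {
  r <- mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_two_sided, 2 / choose(6, 3))

  same <- mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_two_sided, 1)

  sep <- mann_whitney_exact(101:107, 1:6)
  expect_equal(sep$p_two_sided, 2 / choose(13, 6))
  expect_error(mann_whitney_exact(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney equals brute-force enumeration up to n = 12", {
  set.seed(21)
  cases <- list(
    list(x = rnorm(3), y = rnorm(4)),
    list(x = rnorm(5), y = rnorm(5)),
    list(x = rnorm(6), y = rnorm(6)),
    list(x = rnorm(2), y = rnorm(9)),
    list(x = sample(1:4, 6, TRUE), y = sample(1:4, 5, TRUE)),  # heavy ties
    list(x = rep(1, 4), y = rep(1, 4))                          # all tied
  )
  for (cs in cases) {
    got <- mann_whitney_exact(cs$x, cs$y)
    want <- brute_force_mw(cs$x, cs$y)
    expect_equal(got$statistic, want$U)
    expect_equal(got$p_two_sided, want$p)
  }
})

test_that("tie-free exact Mann-Whitney agrees with the distributional form", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(6)
    y <- rnorm(7)
    got <- mann_whitney_exact(x, y)$p_two_sided
    ref <- stats::wilcox.test(x, y, exact = TRUE,
                              alternative = "two.sided")$p.value
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney falls back to a sane approximation", {
  set.seed(30)
  x <- rnorm(15)
  y <- rnorm(15, 1)
  r <- mann_whitney_exact(x, y)
  expect_false(r$detail$exact)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(r$p_two_sided, ref, tolerance = 1e-6)
})

test_that("summary-based Welch t reproduces the printed necrosis contrast", {
  r <- welch_t_from_summary(37.4, 4.6, 7, 7.5, 3.0, 7)
  expect_equal(r$statistic, (37.4 - 7.5) / sqrt(4.6^2 + 3.0^2))
  expect_lt(abs(r$statistic - 5.44), 0.01)
  expect_lt(abs(r$df - 10.3), 0.1)
  expect_lt(r$p_two_sided, 0.001)
})

test_that("summary-based Welch equals the raw-data Welch to 12 digits", {
  set.seed(40)
  for (i in 1:10) {
    x <- rnorm(7, 10, 3)
    y <- rnorm(6, 8, 1)
    from_summary <- welch_t_from_summary(
      mean(x), sd(x) / sqrt(7), 7, mean(y), sd(y) / sqrt(6), 6)
    raw <- welch_t(x, y)
    ref <- stats::t.test(x, y)
    expect_equal(from_summary$statistic, raw$statistic, tolerance = 1e-12)
    expect_equal(from_summary$p_two_sided, raw$p_two_sided, tolerance = 1e-12)
    expect_equal(raw$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(raw$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the pooled flag reproduces the classical Student t", {
  set.seed(41)
  x <- rnorm(7)
  y <- rnorm(6)
  pooled <- welch_t(x, y, pooled = TRUE)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$df, 11)
  expect_equal(pooled$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(pooled$p_two_sided, ref$p.value, tolerance = 1e-12)
})

test_that("degenerate zero-SEM summaries are handled explicitly", {
  r <- welch_t_from_summary(5, 0, 3, 5, 0, 3)
  expect_equal(r$p_two_sided, 1)
  expect_error(welch_t_from_summary(5, 0, 3, 6, 0, 3), "degenerate")
})

test_that("one-way ANOVA matches hand computation and the trivial cases", {
  r <- anova_oneway(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 16)
  expect_equal(r$p_two_sided, 1 - pf(16, 2, 3))

  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_two_sided, 1)

  expect_error(anova_oneway(list(c(1, 1), c(2, 2))), "undefined")
  expect_error(anova_oneway(list(1, c(2, 3))), "n >= 2")
})

test_that("growth report flags nothing for identical arms", {
  set.seed(50)
  base <- data.frame(group = "control",
                     animal_id = sprintf("m%02d", 1:6),
                     day = rep(c(0, 11, 22), each = 6),
                     length_mm = rep(runif(6, 6, 8), 3),
                     width_mm = rep(runif(6, 4, 6), 3),
                     weight_g = NA_real_)
  mirror <- base
  mirror$group <- "arm2"
  mirror$animal_id <- sub("m", "x", mirror$animal_id)
  rep_ <- growth_report(rbind(base, mirror), control = "control")
  expect_true(is.na(rep_$first_signif$first_day_p_below_alpha))
  expect_true(all(rep_$per_day$p_vs_control == 1))
})

test_that("growth report has the expected structural shape", {
  ct <- gen_cohort(seed = 2)
  rep_ <- growth_report(ct, control = "control")
  n_days <- length(unique(ct$day))
  expect_equal(nrow(rep_$per_day), n_days * 2)  # two non-control arms
  # 3 arm pairs x (volume, weight)
  expect_equal(nrow(rep_$final), 6)
  expect_error(growth_report(ct, control = "nope"), "not present")
})

test_that("diverging arms are flagged at the simulated power of the design", {
  # With control N(519.4, (62.9*sqrt(6))^2), n = 6 vs treated
  # N(282.0, (30.7*sqrt(7))^2), n = 7, the exact Mann-Whitney at alpha
  # 0.05 detects the separation by the final day in about 84% of cohorts
  # (simulated rate 0.84 over 400 seeds); assert a 2.5-sigma lower bound.
  flagged <- 0
  for (s in 1:100) {
    ct <- gen_cohort(list(cohort_arm("control", 6, 519.4, 62.9),
                          cohort_arm("rhGCSF", 7, 282.0, 30.7)),
                     seed = s)
    rep_ <- growth_report(ct, control = "control")
    d <- rep_$first_signif$first_day_p_below_alpha
    flagged <- flagged + (!is.na(d) && d <= 22)
  }
  expect_gte(flagged / 100, 0.75)
})
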