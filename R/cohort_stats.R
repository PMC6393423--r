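#' Caliper tumor volume
#'
#' The ellipsoid approximation `V = (a * b^2) / 2` for subcutaneous tumors,
#' with `a` the longest and `b` the shortest diameter (mm). Rows with
#' `a < b` are treated as caliper orientation slips: the values are swapped
#' with a warning, not rejected.
#'
#' @param a,b Caliper diameters in mm (vectorized).
#' @return Volume(s) in mm^3.
#' @examples
#' tumor_volume(10, 5)  # 250 / 2 = 125
#' @export
tumor_volume <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0)) {
    stop("caliper diameters must be positive finite numbers")
  }
  swap <- a < b
  if (any(swap)) {
    warning(sprintf("%d measurement(s) with a < b: swapping (caliper orientation)",
                    sum(swap)))
    tmp <- a[swap]
    a[swap] <- b[swap]
    b[swap] <- tmp
  }
  a * b^2 / 2
}

#' Per-group per-day summaries of a cohort table
#'
#' Computes n, mean and SEM (sample SD with the n-1 denominator, divided by
#' sqrt(n)) of tumor volume — or of final tumor weight — for every
#' (group, day) cell. Single-animal cells report `NA` SEM (undefined), not 0.
#'
#' @param cohort A `cohort_table` data frame (see [gen_cohort()] /
#'   [read_cohort_csv()]).
#' @param measure `"volume"` (from the caliper pair) or `"weight"`.
#' @return Data frame with columns `group`, `day`, `n`, `mean`, `sem`,
#'   ordered by (group, day). Rows with no finite values are dropped (e.g.
#'   weight on non-final days).
#' @examples
#' summarize_cohort(gen_cohort(seed = 1))
#' @export
summarize_cohort <- function(cohort, measure = c("volume", "weight")) {
  measure <- match.arg(measure)
  stopifnot(is.data.frame(cohort),
            all(c("group", "day") %in% names(cohort)))
  value <- if (measure == "volume") {
    tumor_volume(cohort$length_mm, cohort$width_mm)
  } else {
    cohort$weight_g
  }
  keep <- is.finite(value)
  df <- data.frame(group = cohort$group[keep], day = cohort$day[keep],
                   value = value[keep], stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(data.frame(group = character(0), day = integer(0), n = integer(0),
                      mean = numeric(0), sem = numeric(0)))
  }
  key <- interaction(df$group, df$day, drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(df, key), function(d) {
    n <- nrow(d)
    data.frame(group = d$group[1], day = d$day[1], n = n,
               mean = mean(d$value),
               sem = if (n >= 2) stats::sd(d$value) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$group, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Shared result container for the test family.
test_result <- function(test_name, statistic, p, df = NA_real_,
                        detail = list()) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_two_sided = unname(min(1, p)), df = unname(df),
                 detail = detail),
            class = "xeno_test")
}

#' @export
print.xeno_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g, p = %.6g%s\n", x$test_name,
              x$statistic, x$p_two_sided,
              if (is.finite(x$df)) sprintf(", df = %.4g", x$df) else ""))
  invisible(x)
}

#' Exact Mann-Whitney U test
#'
#' Rank-sum test with the U statistic `min(U1, U2)` and midranks for ties.
#' For combined sample sizes up to `exact_limit` (default 20) the two-sided
#' p-value is exact: the number of group labelings — all
#' `choose(n1 + n2, n1)` equally likely assignments of the pooled values to
#' the groups — whose U is less than or equal to the observed U, divided by
#' the total count. Enumeration over subsets handles ties correctly
#' (distinguishable orderings). Above the limit, a normal approximation
#' with midrank tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact_limit Largest `n1 + n2` for which full enumeration is used.
#' @return A test result with `statistic` (U), `p_two_sided`, and in
#'   `detail` the sample sizes and whether the p-value is exact.
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))$p_two_sided  # 2/20 = 0.1
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 20L) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty")
  }
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)  # midranks
  u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- min(u1, n1 * n2 - u1)

  if (n1 + n2 <= exact_limit) {
    sets <- utils::combn(n1 + n2, n1)
    r1 <- colSums(matrix(rk[sets], nrow = n1))
    u1_all <- r1 - n1 * (n1 + 1) / 2
    u_all <- pmin(u1_all, n1 * n2 - u1_all)
    hits <- sum(u_all <= u + 1e-9)
    p <- hits / ncol(sets)
    exact <- TRUE
  } else {
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    sd_u <- sqrt(n1 * n2 / 12 * (n1 + n2 + 1 - tie_term))
    if (sd_u == 0) {
      p <- 1
    } else {
      z <- (abs(u1 - n1 * n2 / 2) - 0.5) / sd_u
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    exact <- FALSE
  }
  test_result("mann_whitney_exact", u, p,
              detail = list(n1 = n1, n2 = n2, U1 = u1, exact = exact))
}

#' Two-sample t test from printed summary statistics
#'
#' Welch's unequal-variance t test computed from group means, SEMs and
#' sizes alone: `t = (m1 - m2) / sqrt(sem1^2 + sem2^2)` with
#' Welch-Satterthwaite degrees of freedom. This is the form applicable when
#' only published summaries (mean +/- SEM, n) are available. Setting
#' `pooled = TRUE` gives the classical equal-variance Student variant with
#' `df = n1 + n2 - 2`.
#'
#' @param m1,sem1,n1 Mean, SEM and size of the first group.
#' @param m2,sem2,n2 Mean, SEM and size of the second group.
#' @param pooled Use the pooled-variance Student form instead of Welch.
#' @return A test result with `statistic` (t), `df` and `p_two_sided`.
#' @examples
#' # necrosis contrast from printed summaries: 37.4 +/- 4.6 vs 7.5 +/- 3.0
#' welch_t_from_summary(37.4, 4.6, 7, 7.5, 3.0, 7)
#' @export
welch_t_from_summary <- function(m1, sem1, n1, m2, sem2, n2,
                                 pooled = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sem1 >= 0, sem2 >= 0)
  if (sem1 == 0 && sem2 == 0) {
    if (m1 == m2) {
      return(test_result(
        if (pooled) "student_t" else "welch_t_from_summary",
        0, 1, df = if (pooled) n1 + n2 - 2 else Inf))
    }
    stop("both SEMs are 0 with unequal means: degenerate test")
  }
  if (pooled) {
    s2_1 <- sem1^2 * n1  # sample variances back from SEMs
    s2_2 <- sem2^2 * n2
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s2_1 + (n2 - 1) * s2_2) / df
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    name <- "student_t"
  } else {
    se2 <- sem1^2 + sem2^2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
    name <- "welch_t_from_summary"
  }
  p <- 2 * stats::pt(-abs(t), df)
  test_result(name, t, p, df = df,
              detail = list(m1 = m1, sem1 = sem1, n1 = n1,
                            m2 = m2, sem2 = sem2, n2 = n2))
}

#' @rdname welch_t_from_summary
#' @param x,y Raw samples (each n >= 2); the raw-data form simply summarises
#'   and delegates, so the two routes agree to machine precision.
#' @export
welch_t <- function(x, y, pooled = FALSE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  res <- welch_t_from_summary(
    mean(x), stats::sd(x) / sqrt(length(x)), length(x),
    mean(y), stats::sd(y) / sqrt(length(y)), length(y),
    pooled = pooled)
  res$test_name <- if (pooled) "student_t" else "welch_t"
  res
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA F test across two or more groups.
#'
#' @param groups List of numeric samples, each of size >= 2.
#' @return A test result with `statistic` (F), `df` (numerator,
#'   denominator) and `p_two_sided`.
#' @examples
#' anova_oneway(list(c(1, 2), c(3, 4), c(5, 6)))  # F = 16
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs n >= 2")
  }
  if (all(vapply(groups, stats::sd, numeric(1)) == 0)) {
    stop("zero within-group variance in every group: F undefined")
  }
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ft <- stats::oneway.test(value ~ grp, var.equal = TRUE)
  test_result("anova_oneway", ft$statistic, ft$p.value,
              df = unname(ft$parameter["num df"]),
              detail = list(df_within = unname(ft$parameter["denom df"])))
}

#' Growth-curve comparison report for a multi-arm cohort
#'
#' For every study day and non-control arm, summarizes the group volumes and
#' tests the arm against the control with the exact Mann-Whitney U test,
#' flagging the first day each arm separates from control at `alpha`. On the
#' final day, all arm pairs are additionally compared on volume and (where
#' present) tumor weight.
#'
#' @param cohort A `cohort_table`.
#' @param control Name of the control arm.
#' @param alpha Significance level for the first-separation flag.
#' @return An object of class `growth_report`: `per_day` (columns `day`,
#'   `group`, `n`, `mean_mm3`, `sem_mm3`, `p_vs_control`, `test`), `final`
#'   (columns `comparison`, `metric`, `p`, `test`), `first_signif` (one row
#'   per non-control arm; day `NA` if never significant) and `summaries`
#'   (all per-group-day volume summaries, control included).
#' @examples
#' rep <- growth_report(gen_cohort(seed = 3), control = "control")
#' rep$first_signif
#' @export
growth_report <- function(cohort, control = "control", alpha = 0.05) {
  stopifnot(is.data.frame(cohort))
  groups <- unique(cohort$group)
  if (!(control %in% groups)) {
    stop(sprintf("control group '%s' not present", control))
  }
  vol <- tumor_volume(cohort$length_mm, cohort$width_mm)
  days <- sort(unique(cohort$day))
  arms <- setdiff(groups, control)
  summ <- summarize_cohort(cohort)

  per_day <- list()
  for (d in days) {
    ctrl_v <- vol[cohort$group == control & cohort$day == d]
    for (g in arms) {
      gv <- vol[cohort$group == g & cohort$day == d]
      if (length(gv) == 0L) next
      p <- if (length(ctrl_v) == 0L) {
        NA_real_  # missing control rows: flagged, not fatal
      } else {
        mann_whitney_exact(gv, ctrl_v)$p_two_sided
      }
      per_day[[length(per_day) + 1L]] <- data.frame(
        day = d, group = g, n = length(gv), mean_mm3 = mean(gv),
        sem_mm3 = if (length(gv) >= 2) stats::sd(gv) / sqrt(length(gv)) else NA_real_,
        p_vs_control = p, test = "mann_whitney_exact",
        stringsAsFactors = FALSE)
    }
  }
  per_day <- if (length(per_day)) do.call(rbind, per_day) else
    data.frame(day = integer(0), group = character(0), n = integer(0),
               mean_mm3 = numeric(0), sem_mm3 = numeric(0),
               p_vs_control = numeric(0), test = character(0))

  first_signif <- data.frame(
    group = arms,
    first_day_p_below_alpha = vapply(arms, function(g) {
      rows <- per_day[per_day$group == g & !is.na(per_day$p_vs_control) &
                        per_day$p_vs_control < alpha, , drop = FALSE]
      if (nrow(rows) == 0L) NA_integer_ else as.integer(min(rows$day))
    }, integer(1)),
    stringsAsFactors = FALSE)

  final_day <- max(days)
  pairs <- utils::combn(sort(groups), 2)
  final <- list()
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1, j]
    g2 <- pairs[2, j]
    v1 <- vol[cohort$group == g1 & cohort$day == final_day]
    v2 <- vol[cohort$group == g2 & cohort$day == final_day]
    if (length(v1) && length(v2)) {
      final[[length(final) + 1L]] <- data.frame(
        comparison = paste(g1, "vs", g2), metric = "volume_mm3",
        p = mann_whitney_exact(v1, v2)$p_two_sided,
        test = "mann_whitney_exact", stringsAsFactors = FALSE)
    }
    w1 <- cohort$weight_g[cohort$group == g1 & cohort$day == final_day]
    w2 <- cohort$weight_g[cohort$group == g2 & cohort$day == final_day]
    w1 <- w1[is.finite(w1)]
    w2 <- w2[is.finite(w2)]
    if (length(w1) && length(w2)) {
      final[[length(final) + 1L]] <- data.frame(
        comparison = paste(g1, "vs", g2), metric = "weight_g",
        p = mann_whitney_exact(w1, w2)$p_two_sided,
        test = "mann_whitney_exact", stringsAsFactors = FALSE)
    }
  }
  final <- if (length(final)) do.call(rbind, final) else
    data.frame(comparison = character(0), metric = character(0),
               p = numeric(0), test = character(0))

  structure(
    list(per_day = per_day, final = final, first_signif = first_signif,
         summaries = summ, control = control, alpha = alpha),
    class = "growth_report"
  )
}

#' @export
print.growth_report <- function(x, ...) {
  cat(sprintf("<growth_report> control = %s, alpha = %.3g\n", x$control,
              x$alpha))
  cat("first day below alpha per arm:\n")
  print(x$first_signif, row.names = FALSE)
  cat("final-day comparisons:\n")
  print(x$final, row.names = FALSE)
  invisible(x)
}
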