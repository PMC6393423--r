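#' Define a cohort arm
#'
#' @param name Arm name (e.g. `"control"`).
#' @param n Number of animals (>= 2).
#' @param final_mean_mm3,final_sem_mm3 Target day-final group mean and SEM of
#'   tumor volume (mm^3). Between-animal SD is reconstructed from the SEM as
#'   `sem * sqrt(n)` (definitional).
#' @param weight_mean_g,weight_sem_g Optional final tumor-weight mean and SEM
#'   (g); if `NA`, no weights are emitted for the arm.
#' @return A list of class `cohort_arm`.
#' @export
cohort_arm <- function(name, n, final_mean_mm3, final_sem_mm3,
                       weight_mean_g = NA_real_, weight_sem_g = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, n >= 2)
  if (final_mean_mm3 <= 0 || final_sem_mm3 < 0) {
    stop("final mean must be positive and SEM non-negative")
  }
  structure(
    list(name = name, n = as.integer(n),
         final_mean_mm3 = final_mean_mm3, final_sem_mm3 = final_sem_mm3,
         weight_mean_g = weight_mean_g, weight_sem_g = weight_sem_g),
    class = "cohort_arm"
  )
}

# Normal draw truncated to (0, Inf) by resampling.
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x <= 0
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  if (any(x <= 0)) stop("could not draw positive volumes; check parameters")
  x
}

#' Simulate a longitudinal caliper cohort
#'
#' Generates per-animal tumor-volume trajectories for a multi-arm xenograft
#' cohort. Each animal draws a baseline volume (normal, common mean
#' `start_mean_mm3`, SD `start_sem_mm3 * sqrt(n)`) and a final volume
#' (normal, arm-specific mean, SD `final_sem_mm3 * sqrt(n)`), both truncated
#' positive, and interpolates linearly in cube-root (radius) space between
#' them — the constant boundary-growth picture in which the tumor radius,
#' not the volume, grows linearly. Each day's volume is converted to a
#' caliper pair `(a, b)` with aspect ratio `a/b` drawn uniformly from
#' `aspect_range` such that `(a * b^2) / 2` reproduces the volume exactly.
#' A final tumor weight is emitted per animal for arms that define weight
#' parameters.
#'
#' Defaults are calibrated to a three-arm pancreatic-cancer xenograft study
#' design: saline control (n = 6), rhG-CSF (n = 7) and gemcitabine (n = 7),
#' starting from a common 106.9 +/- 3.1 mm^3 baseline and diverging to final
#' means of 519.4 +/- 62.9, 282.0 +/- 30.7 and 202.6 +/- 18.1 mm^3
#' respectively, measured twice weekly from day 0 to day 22.
#'
#' @param arms List of [cohort_arm()] objects.
#' @param start_mean_mm3,start_sem_mm3 Common baseline mean and SEM (mm^3).
#' @param days Integer measurement schedule; must include the first and last
#'   day.
#' @param seed Integer RNG seed.
#' @param aspect_range Range of the caliper aspect ratio `a/b` (>= 1).
#' @param measurement_cv Optional multiplicative per-measurement caliper
#'   noise (coefficient of variation on volume); default 0 (noise-free).
#' @return A `data.frame` of class `cohort_table` with columns
#'   `group, animal_id, day, length_mm, width_mm, weight_g` (`weight_g` is
#'   `NA` except on the final day of arms with weight parameters).
#' @examples
#' ct <- gen_cohort(seed = 1)
#' head(ct)
#' @export
gen_cohort <- function(arms = default_study_arms(),
                       start_mean_mm3 = 106.9, start_sem_mm3 = 3.1,
                       days = c(0L, 4L, 8L, 11L, 15L, 18L, 22L),
                       seed = 1L, aspect_range = c(1.0, 1.6),
                       measurement_cv = 0) {
  if (inherits(arms, "cohort_arm")) arms <- list(arms)
  stopifnot(length(arms) >= 1L,
            all(vapply(arms, inherits, logical(1), "cohort_arm")))
  if (start_mean_mm3 <= 0) stop("`start_mean_mm3` must be positive")
  days <- sort(unique(as.integer(days)))
  stopifnot(length(days) >= 2L, all(days >= 0L))
  stopifnot(length(aspect_range) == 2L, aspect_range[1] >= 1,
            diff(aspect_range) >= 0)
  t0 <- days[1]
  t1 <- days[length(days)]

  rows <- with_seed(seed, {
    out <- vector("list", length(arms))
    for (ai in seq_along(arms)) {
      arm <- arms[[ai]]
      n <- arm$n
      v0 <- rnorm_pos(n, start_mean_mm3, start_sem_mm3 * sqrt(n))
      v1 <- rnorm_pos(n, arm$final_mean_mm3, arm$final_sem_mm3 * sqrt(n))
      wt <- if (!is.na(arm$weight_mean_g)) {
        rnorm_pos(n, arm$weight_mean_g, arm$weight_sem_g * sqrt(n))
      } else {
        rep(NA_real_, n)
      }
      arm_rows <- vector("list", n)
      for (k in seq_len(n)) {
        r0 <- v0[k]^(1 / 3)
        r1 <- v1[k]^(1 / 3)
        frac <- (days - t0) / (t1 - t0)
        vol <- (r0 + (r1 - r0) * frac)^3
        if (measurement_cv > 0) {
          vol <- vol * pmax(1e-6, 1 + stats::rnorm(length(vol), 0,
                                                   measurement_cv))
        }
        q <- stats::runif(length(days), aspect_range[1], aspect_range[2])
        b <- (2 * vol / q)^(1 / 3)
        a <- q * b
        arm_rows[[k]] <- data.frame(
          group = arm$name,
          animal_id = sprintf("%s_%02d", arm$name, k),
          day = days,
          length_mm = a, width_mm = b,
          weight_g = ifelse(days == t1, wt[k], NA_real_),
          stringsAsFactors = FALSE
        )
      }
      out[[ai]] <- do.call(rbind, arm_rows)
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  class(rows) <- c("cohort_table", "data.frame")
  rows
}

#' @rdname gen_cohort
#' @return `default_study_arms()`: the three-arm design described above.
#' @export
default_study_arms <- function() {
  list(
    cohort_arm("control", 6, 519.4, 62.9, 0.316, 0.017),
    cohort_arm("rhGCSF", 7, 282.0, 30.7, 0.143, 0.029),
    cohort_arm("gemcitabine", 7, 202.6, 18.1, 0.129, 0.018)
  )
}
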