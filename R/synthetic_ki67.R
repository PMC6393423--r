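#' Synthetic Ki67-stained nucleus field with zone-dependent positivity
#'
#' Places non-overlapping disk nuclei at a Poisson-like density inside a
#' tumor mask and labels each nucleus Ki67-positive with a probability that
#' depends on the concentric zone (outer/intermediate/inner, 20/30/50% of
#' tumor area by distance-to-boundary rank) containing its center. Positive
#' nuclei are rendered DAB-brown, negative nuclei hematoxylin-blue, on an
#' eosin background. This emulates the proliferation gradient of xenograft
#' sections, where positivity is highest in the outer rim.
#'
#' Placement is by dart throwing with a bounded number of retries; if the
#' requested density cannot be placed without overlap, an error is raised.
#'
#' @param zone_positive_fractions Numeric triple: Ki67-positive probability
#'   in the (outer, intermediate, inner) zone, each in [0, 1].
#' @param cell_density Nuclei per 1000 square pixels of tumor area.
#' @param tumor_mask A non-empty `binary_mask` (area >= 1024 px so that it
#'   can be zoned).
#' @param seed Integer RNG seed.
#' @param nucleus_radius Nucleus disk radius in pixels.
#' @param noise_sd Per-channel Gaussian stain jitter (8-bit units).
#' @param max_tries_factor Retry budget: `max_tries_factor * n` throws.
#' @return A `section_image` whose `nuclei_truth` is a data frame with
#'   columns `x`, `y` (0-based center coordinates), `zone`
#'   (`outer`/`intermediate`/`inner`) and `label` (`positive`/`negative`);
#'   the `zone_partition` used is attached in `meta`.
#' @examples
#' f <- gen_ki67_field(c(0.45, 0.30, 0.15), cell_density = 3,
#'                     tumor_mask = disk_mask(60, margin = 8), seed = 1)
#' table(f$nuclei_truth$zone, f$nuclei_truth$label)
#' @export
gen_ki67_field <- function(zone_positive_fractions, cell_density, tumor_mask,
                           seed = 1L, nucleus_radius = 3, noise_sd = 3,
                           max_tries_factor = 60L) {
  stopifnot(is_binary_mask(tumor_mask))
  if (mask_area(tumor_mask) == 0L) {
    stop("tumor mask is empty")
  }
  zp <- as.numeric(zone_positive_fractions)
  if (length(zp) != 3L || any(zp < 0 | zp > 1)) {
    stop("`zone_positive_fractions` must be three probabilities in [0, 1]")
  }
  part <- partition_zones(tumor_mask)
  side_r <- nrow(tumor_mask$grid)
  side_c <- ncol(tumor_mask$grid)

  # nuclei must lie wholly inside the tumor: centers where the boundary
  # distance exceeds the nucleus radius
  dist <- boundary_distance(tumor_mask)
  eligible <- which(dist > nucleus_radius)
  n_target <- round(cell_density / 1000 * mask_area(tumor_mask))

  with_seed(seed, {
    acc_r <- integer(0)
    acc_c <- integer(0)
    blocked <- matrix(FALSE, side_r, side_c)  # dilated occupancy
    block_off <- disk_offsets(2 * nucleus_radius + 1)
    tries <- 0L
    max_tries <- max_tries_factor * max(n_target, 1L)
    while (length(acc_r) < n_target && tries < max_tries) {
      tries <- tries + 1L
      cand <- eligible[sample.int(length(eligible), 1L)]
      r <- (cand - 1L) %% side_r + 1L
      c <- (cand - 1L) %/% side_r + 1L
      if (blocked[r, c]) next
      acc_r <- c(acc_r, r)
      acc_c <- c(acc_c, c)
      br <- r + block_off$dr
      bc <- c + block_off$dc
      ok <- br >= 1 & br <= side_r & bc >= 1 & bc <= side_c
      blocked[cbind(br[ok], bc[ok])] <- TRUE
    }
    if (length(acc_r) < n_target) {
      stop(sprintf(
        "could not place %d non-overlapping nuclei (placed %d in %d tries); density too high",
        n_target, length(acc_r), tries))
    }

    zone_id <- part$labels[cbind(acc_r, acc_c)]
    positive <- stats::rbinom(length(acc_r), 1L, zp[zone_id]) == 1L

    img <- array(255, dim = c(side_r, side_c, 3))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[tumor_mask$grid] <- STAIN_EOSIN[ch]
      if (noise_sd > 0) {
        j <- tumor_mask$grid
        plane[j] <- pmin(255, pmax(0, plane[j] +
                                     stats::rnorm(sum(j), 0, noise_sd)))
      }
      img[, , ch] <- plane
    }
    off <- disk_offsets(nucleus_radius)
    for (grp in list(list(sel = positive, color = STAIN_DAB),
                     list(sel = !positive, color = STAIN_NUCLEUS))) {
      if (!any(grp$sel)) next
      rr <- rep(acc_r[grp$sel], each = nrow(off)) + off$dr
      cc <- rep(acc_c[grp$sel], each = nrow(off)) + off$dc
      ok <- rr >= 1 & rr <= side_r & cc >= 1 & cc <= side_c
      rr <- rr[ok]
      cc <- cc[ok]
      ok <- tumor_mask$grid[cbind(rr, cc)]
      rr <- rr[ok]
      cc <- cc[ok]
      for (ch in 1:3) {
        img[cbind(rr, cc, ch)] <- pmin(255, pmax(0, grp$color[ch] +
          stats::rnorm(length(rr), 0, noise_sd)))
      }
    }

    truth <- data.frame(
      x = acc_c - 1L, y = acc_r - 1L,
      zone = c("outer", "intermediate", "inner")[zone_id],
      label = ifelse(positive, "positive", "negative"),
      stringsAsFactors = FALSE
    )
    section_image(
      img, tumor_mask, nuclei_truth = truth,
      meta = list(zone_positive_fractions = zp, cell_density = cell_density,
                  nucleus_radius = nucleus_radius, seed = seed,
                  zone_partition = part)
    )
  })
}
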