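# Stain palette: fixed, well-separated constants (configurable via args).
# viable nuclei ~ hematoxylin, background ~ eosin, necrosis pale, DAB brown.
STAIN_NUCLEUS  <- c(60, 40, 120)
STAIN_EOSIN    <- c(240, 180, 190)
STAIN_NECROSIS <- c(235, 220, 215)
STAIN_DAB      <- c(130, 80, 40)

#' Synthetic tumor cross-section with known necrotic fraction
#'
#' Renders an H&E-like RGB image of a disk-shaped tumor in which a specified
#' fraction of the tumor area is necrotic, laid out in one of two spatial
#' patterns: `compact_interior` grows a single irregular blob from the tumor
#' centroid (the pattern seen after treatments that kill from the inside
#' out), while `dispersed_peripheral` scatters irregular blobs whose centers
#' lie at >= 60% of the tumor radius. Viable tissue is rendered as
#' dense dark-stained nuclei on an eosin-pink background; necrotic tissue is
#' pale and nucleus-free. The realized ground-truth necrotic fraction is
#' exact to one pixel (the target pixel count is selected by rank), hence
#' always within 0.01 of the target.
#'
#' @param radius_px Tumor radius in pixels; must be >= 32 so the section can
#'   be zoned downstream.
#' @param necrotic_fraction Target necrotic fraction of tumor area in [0, 1].
#' @param pattern `"compact_interior"` or `"dispersed_peripheral"`.
#' @param seed Integer RNG seed.
#' @param nuclei_per_1000px2 Nucleus density in viable tissue, nuclei per
#'   1000 square pixels.
#' @param noise_sd Per-channel Gaussian stain jitter (8-bit units).
#' @return A `section_image` with `tumor_mask` (disk), `necrosis_truth`, and
#'   generator parameters in `meta`.
#' @examples
#' sec <- gen_section(64, 0.3, "compact_interior", seed = 1)
#' mask_area(sec$necrosis_truth) / mask_area(sec$tumor_mask)
#' @export
gen_section <- function(radius_px, necrotic_fraction,
                        pattern = c("compact_interior", "dispersed_peripheral"),
                        seed = 1L, nuclei_per_1000px2 = 12, noise_sd = 3) {
  pattern <- match.arg(pattern)
  if (!(necrotic_fraction >= 0 && necrotic_fraction <= 1)) {
    stop("`necrotic_fraction` must be in [0, 1]")
  }
  if (radius_px < 32) {
    stop("`radius_px` must be >= 32 (too small for zonal analysis)")
  }
  margin <- 32L  # background rim wider than downstream smoothing kernels
  tumor <- disk_mask(radius_px, margin = margin)
  side <- nrow(tumor$grid)
  ctr <- as.integer(radius_px) + margin + 1L

  with_seed(seed, {
    A <- mask_area(tumor)
    n_nec <- round(necrotic_fraction * A)
    idx <- which(tumor$grid, arr.ind = TRUE)

    # Potential field: necrosis = the n_nec tumor pixels of lowest potential.
    # A smoothed noise field makes blob boundaries irregular.
    rough <- matrix(stats::runif(side * side), side, side)
    rough <- EBImage::gblur(rough, sigma = radius_px / 16)
    rough <- (rough - mean(rough)) / max(stats::sd(rough), 1e-12)
    if (pattern == "compact_interior") {
      pot <- sqrt((idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2)
      pot <- pot + 0.12 * radius_px * rough[idx]
    } else {
      n_blob <- 8L
      ang <- stats::runif(n_blob, 0, 2 * pi)
      rad <- stats::runif(n_blob, 0.60 * radius_px, 0.92 * radius_px)
      cr <- ctr + rad * sin(ang)
      cc <- ctr + rad * cos(ang)
      pot <- rep(Inf, nrow(idx))
      for (k in seq_len(n_blob)) {
        pot <- pmin(pot, sqrt((idx[, 1] - cr[k])^2 + (idx[, 2] - cc[k])^2))
      }
      pot <- pot + 0.08 * radius_px * rough[idx]
    }
    nec_grid <- matrix(FALSE, side, side)
    if (n_nec > 0) {
      ord <- order(pot, idx[, 1], idx[, 2])
      nec_grid[idx[head(ord, n_nec), , drop = FALSE]] <- TRUE
    }
    viable <- tumor$grid & !nec_grid

    img <- array(255, dim = c(side, side, 3))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[viable] <- STAIN_EOSIN[ch]
      plane[nec_grid] <- STAIN_NECROSIS[ch]
      if (noise_sd > 0) {
        j <- tumor$grid
        plane[j] <- pmin(255, pmax(0, plane[j] +
                                     stats::rnorm(sum(j), 0, noise_sd)))
      }
      img[, , ch] <- plane
    }

    # Dense nuclei in viable tissue only; necrosis is nucleus-free.
    n_nuc <- round(nuclei_per_1000px2 / 1000 * sum(viable))
    if (n_nuc > 0) {
      vi <- which(viable)
      centers <- vi[sample.int(length(vi), min(n_nuc, length(vi)))]
      rows <- (centers - 1L) %% side + 1L
      cols <- (centers - 1L) %/% side + 1L
      radii <- sample(2:3, length(centers), replace = TRUE)
      # batch-stamp all nuclei of each radius in one vectorized pass
      for (rad in unique(radii)) {
        off <- disk_offsets(rad)
        sel <- which(radii == rad)
        rr <- rep(rows[sel], each = nrow(off)) + off$dr
        cc <- rep(cols[sel], each = nrow(off)) + off$dc
        ok <- rr >= 1 & rr <= side & cc >= 1 & cc <= side
        rr <- rr[ok]
        cc <- cc[ok]
        ok <- viable[cbind(rr, cc)]
        rr <- rr[ok]
        cc <- cc[ok]
        for (ch in 1:3) {
          img[cbind(rr, cc, ch)] <- pmin(255, pmax(0, STAIN_NUCLEUS[ch] +
            stats::rnorm(length(rr), 0, noise_sd)))
        }
      }
    }

    section_image(
      img, tumor,
      necrosis_truth = binary_mask(nec_grid),
      meta = list(radius_px = radius_px,
                  necrotic_fraction = necrotic_fraction,
                  realized_fraction = n_nec / A,
                  pattern = pattern, seed = seed)
    )
  })
}
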