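#' Percent intratumoral necrosis from masks
#'
#' The necrotic percentage of tumor cross-sectional area,
#' `100 * |necrosis| / |tumor|`. The ratio is formed from the exact integer
#' pixel counts before the final float conversion, so the result carries no
#' platform float drift.
#'
#' @param necrosis A `binary_mask` of necrotic pixels; must be a subset of
#'   `tumor`.
#' @param tumor A non-empty `binary_mask` of tumor pixels.
#' @return Percentage in [0, 100].
#' @examples
#' tum <- binary_mask(matrix(TRUE, 10, 100))
#' nec <- binary_mask(matrix(rep(c(TRUE, FALSE), each = 500), 10, 100))
#' percent_necrosis(nec, tum)  # 50
#' @export
percent_necrosis <- function(necrosis, tumor) {
  stopifnot(is_binary_mask(necrosis), is_binary_mask(tumor))
  if (!all(dim(necrosis$grid) == dim(tumor$grid))) {
    stop("necrosis and tumor masks have different raster sizes")
  }
  if (mask_area(tumor) == 0L) {
    stop("empty tumor mask")
  }
  if (any(necrosis$grid & !tumor$grid)) {
    stop("necrosis pixels found outside the tumor mask (misaligned masks?)")
  }
  (100 * mask_area(necrosis)) / mask_area(tumor)
}

#' Segment intratumoral necrosis on a stained section
#'
#' Classifies every tumor pixel as necrotic or viable from two smoothed
#' feature maps: a nuclear-density map (Gaussian-smoothed indicator of
#' nuclear-stain pixels, i.e. blue-over-red dominance) and a pallor map
#' (Gaussian-smoothed luminance), both computed by normalized convolution
#' restricted to the tumor mask so the slide background never bleeds in.
#' A pixel is necrotic when its nuclear density falls below an Otsu
#' threshold (capped at `dens_cap`) and its smoothed luminance rises above
#' an Otsu threshold (floored at `lum_floor`); the absolute guards keep a
#' fully viable section from being split by Otsu's always-split behaviour.
#' The raw call is then regularized by morphological opening and closing
#' with a disk brush and removal of small components.
#'
#' @param image A `section_image` whose tumor mask has >= 1024 pixels.
#' @param sigma Gaussian smoothing scale for both maps, in pixels.
#' @param brush_radius Disk radius (px) of the opening/closing brush.
#' @param min_component Minimum necrotic component area kept, in pixels.
#' @param nuclear_margin Blue-over-red margin (8-bit units) defining a
#'   nuclear-stain pixel.
#' @param dens_cap Upper cap on the nuclear-density threshold (fraction of
#'   nuclear-stain cover below which tissue can be called necrotic).
#' @param lum_floor Lower floor on the luminance threshold (0..1 scale).
#' @return An object of class `necrosis_result`: `necrosis_mask`,
#'   `tumor_mask`, `percent_necrosis`, the thresholds used, and a
#'   `degenerate` flag (TRUE when the section had no luminance contrast and
#'   0% is returned by convention).
#' @examples
#' sec <- gen_section(64, 0.3, "compact_interior", seed = 2)
#' segment_necrosis(sec)$percent_necrosis
#' @export
segment_necrosis <- function(image, sigma = 8, brush_radius = 3,
                             min_component = 64, nuclear_margin = 0,
                             dens_cap = 0.10, lum_floor = 0.75) {
  stopifnot(inherits(image, "section_image"))
  tumor <- image$tumor_mask$grid
  if (sum(tumor) < 1024L) {
    stop("tumor mask has < 1024 pixels; too small to quantify")
  }
  R <- image$rgb[, , 1]
  G <- image$rgb[, , 2]
  B <- image$rgb[, , 3]
  lum <- luminance(R, G, B) / 255

  if (stats::sd(lum[tumor]) < 1e-3) {
    warning("degenerate single-color section; returning 0% necrosis")
    empty <- binary_mask(matrix(FALSE, nrow(tumor), ncol(tumor)),
                         image$tumor_mask$pixel_size_um)
    return(structure(
      list(necrosis_mask = empty, tumor_mask = image$tumor_mask,
           percent_necrosis = 0, thresholds = NULL, degenerate = TRUE),
      class = "necrosis_result"))
  }

  nuclear <- (B > R + nuclear_margin) & tumor
  dens <- smooth_masked(nuclear * 1, tumor, sigma)
  pallor <- smooth_masked(lum, tumor, sigma)

  th_dens <- min(otsu_threshold(dens[tumor]), dens_cap)
  th_lum <- max(otsu_threshold(pallor[tumor]), lum_floor)
  raw <- tumor & (dens < th_dens) & (pallor > th_lum)

  brush <- EBImage::makeBrush(2L * as.integer(brush_radius) + 1L, "disc")
  reg <- EBImage::closing(EBImage::opening(raw * 1, brush), brush) > 0
  reg <- reg & tumor

  if (min_component > 0 && any(reg)) {
    lab <- EBImage::bwlabel(reg * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component)
    reg <- matrix(lab %in% keep, nrow(reg), ncol(reg))
  }

  nec <- binary_mask(reg, image$tumor_mask$pixel_size_um)
  structure(
    list(necrosis_mask = nec, tumor_mask = image$tumor_mask,
         percent_necrosis = percent_necrosis(nec, image$tumor_mask),
         thresholds = c(density = th_dens, luminance = th_lum),
         degenerate = FALSE),
    class = "necrosis_result"
  )
}

#' @export
print.necrosis_result <- function(x, ...) {
  cat(sprintf("<necrosis_result> %.2f%% of %d tumor px necrotic%s\n",
              x$percent_necrosis, mask_area(x$tumor_mask),
              if (x$degenerate) " (degenerate input)" else ""))
  invisible(x)
}

#' Dice overlap between two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param a,b `binary_mask` objects on the same raster.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(is_binary_mask(a), is_binary_mask(b),
            all(dim(a$grid) == dim(b$grid)))
  denom <- mask_area(a) + mask_area(b)
  if (denom == 0L) {
    return(1)
  }
  2 * sum(a$grid & b$grid) / denom
}
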