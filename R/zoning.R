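# Euclidean distance of every pixel to the nearest background pixel.
# The raster is padded with a one-pixel background ring first, so the image
# border always counts as tumor boundary (EBImage::distmap would otherwise
# return Inf for a mask with no background at all).
boundary_distance <- function(mask) {
  g <- mask$grid
  padded <- matrix(0, nrow(g) + 2L, ncol(g) + 2L)
  padded[2:(nrow(g) + 1L), 2:(ncol(g) + 1L)] <- g * 1
  d <- EBImage::distmap(padded, metric = "euclidean")
  as.matrix(d)[2:(nrow(g) + 1L), 2:(ncol(g) + 1L)]
}

#' Partition a tumor mask into concentric zones of fixed area fractions
#'
#' Splits the tumor cross-section into outer, intermediate and inner zones
#' holding fixed fractions of the tumor area (default 20/30/50%), ordered by
#' Euclidean distance to the tumor boundary: every tumor pixel is ranked by
#' `(distance, row, column)` and the first `round(f1 * A)` pixels become the
#' outer zone, the next `round(f2 * A)` the intermediate zone, the remainder
#' the inner zone. The rank cut makes realized fractions exact to one pixel,
#' and the lexicographic tie-break makes the partition bit-reproducible.
#' Zero-area zones (degenerate fractions) are allowed.
#'
#' @param tumor A `binary_mask` with >= 1024 foreground pixels.
#' @param fractions Positive-or-zero triple summing to 1 (tolerance 1e-9):
#'   target area fractions of (outer, intermediate, inner).
#' @return An object of class `zone_partition`: `labels` (integer matrix;
#'   0 background, 1 outer, 2 intermediate, 3 inner), `target_fractions`,
#'   `realized_fractions`, `distance` (the boundary-distance map) and
#'   `tumor_mask`.
#' @examples
#' p <- partition_zones(disk_mask(60))
#' p$realized_fractions
#' @export
partition_zones <- function(tumor, fractions = c(0.2, 0.3, 0.5)) {
  stopifnot(is_binary_mask(tumor))
  A <- mask_area(tumor)
  if (A == 0L) {
    stop("empty tumor mask")
  }
  if (A < 1024L) {
    stop("tumor mask has < 1024 pixels; too small to zone")
  }
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions < 0)) {
    stop("`fractions` must be three non-negative numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop(sprintf("`fractions` must sum to 1 (got %.12f)", sum(fractions)))
  }

  dist <- boundary_distance(tumor)
  idx <- which(tumor$grid, arr.ind = TRUE)
  ord <- order(dist[idx], idx[, 1], idx[, 2])

  n_outer <- round(fractions[1] * A)
  n_inter <- round(fractions[2] * A)
  labels <- matrix(0L, nrow(tumor$grid), ncol(tumor$grid))
  zone_of_rank <- rep(3L, A)
  if (n_outer > 0) zone_of_rank[seq_len(n_outer)] <- 1L
  if (n_inter > 0) zone_of_rank[n_outer + seq_len(min(n_inter, A - n_outer))] <- 2L
  labels[idx[ord, , drop = FALSE]] <- zone_of_rank

  realized <- tabulate(labels[labels > 0L], 3L) / A
  structure(
    list(labels = labels, target_fractions = fractions,
         realized_fractions = realized, distance = dist,
         tumor_mask = tumor),
    class = "zone_partition"
  )
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(sprintf(
    "<zone_partition> outer/intermediate/inner = %.1f/%.1f/%.1f%% of %d tumor px\n",
    100 * x$realized_fractions[1], 100 * x$realized_fractions[2],
    100 * x$realized_fractions[3], mask_area(x$tumor_mask)))
  invisible(x)
}

#' Detect stained nuclei on a section image
#'
#' Thresholds a nuclear-stain score per pixel — the union of blue-dominant
#' (hematoxylin) and brown-dominant (DAB) pixels, both far darker than the
#' eosin background — labels connected components within the tumor mask,
#' filters them by area, and calls each nucleus Ki67-positive when the red
#' channel exceeds the blue channel by `positive_margin` over at least half
#' of its pixels.
#'
#' @param image A `section_image`.
#' @param lum_threshold Luminance (0..255) below which a pixel counts as
#'   nuclear stain.
#' @param min_area,max_area Component area bounds in pixels.
#' @param positive_margin Red-minus-blue margin (8-bit units) for the
#'   brown-dominance call.
#' @return Data frame with one row per nucleus: 0-based centroid `x`, `y`,
#'   `area` (px), and logical `positive`.
#' @examples
#' f <- gen_ki67_field(c(1, 1, 1), 2, disk_mask(60, margin = 8), seed = 4)
#' nrow(detect_nuclei(f))
#' @export
detect_nuclei <- function(image, lum_threshold = 150, min_area = 20,
                          max_area = 400, positive_margin = 30) {
  stopifnot(inherits(image, "section_image"))
  R <- image$rgb[, , 1]
  B <- image$rgb[, , 3]
  lum <- luminance(R, image$rgb[, , 2], B)
  stained <- (lum < lum_threshold) & image$tumor_mask$grid
  if (!any(stained)) {
    return(data.frame(x = numeric(0), y = numeric(0), area = integer(0),
                      positive = logical(0)))
  }
  lab <- EBImage::bwlabel(stained * 1)
  ids <- lab[lab > 0]
  sizes <- tabulate(ids)
  keep <- which(sizes >= min_area & sizes <= max_area)
  if (length(keep) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), area = integer(0),
                      positive = logical(0)))
  }
  pix <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[pix]
  sel <- comp %in% keep
  pix <- pix[sel, , drop = FALSE]
  comp <- factor(comp[sel], levels = keep)
  brown <- (R[pix] > B[pix] + positive_margin)
  out <- data.frame(
    x = as.numeric(tapply(pix[, 2] - 1L, comp, mean)),
    y = as.numeric(tapply(pix[, 1] - 1L, comp, mean)),
    area = as.integer(sizes[keep]),
    positive = as.numeric(tapply(brown, comp, mean)) >= 0.5
  )
  rownames(out) <- NULL
  out
}

#' Score Ki67 positivity per concentric tumor zone
#'
#' Assigns each detected nucleus to the zone containing its centroid and
#' reports, per zone, the total and Ki67-positive counts and the percent
#' positive (the proliferation rate). Nuclei whose centroid falls outside
#' the partitioned tumor mask are counted in a reject bin, not discarded
#' silently. Zones containing zero nuclei report `NA` percent (flagged
#' undefined), never 0%, so empty zones cannot bias downstream means.
#'
#' @param nuclei Data frame from [detect_nuclei()] (columns `x`, `y`,
#'   `positive`) or a ground-truth table with `label` == "positive".
#' @param partition A `zone_partition` for the same raster.
#' @return An object of class `ki_score`: data frame `zones` with columns
#'   `zone`, `total`, `positive`, `percent` (NA when `total` is 0),
#'   `overall_percent`, and `n_rejected`.
#' @examples
#' part <- partition_zones(disk_mask(60))
#' f <- gen_ki67_field(c(0.5, 0.3, 0.1), 3, disk_mask(60), seed = 5)
#' score_ki67(detect_nuclei(f), partition_zones(disk_mask(60)))
#' @export
score_ki67 <- function(nuclei, partition) {
  stopifnot(inherits(partition, "zone_partition"))
  if (!all(c("x", "y") %in% names(nuclei))) {
    stop("`nuclei` must have columns x and y")
  }
  pos <- if ("positive" %in% names(nuclei)) {
    as.logical(nuclei$positive)
  } else if ("label" %in% names(nuclei)) {
    nuclei$label == "positive"
  } else {
    stop("`nuclei` must have a `positive` or `label` column")
  }
  labs <- partition$labels
  r <- round(nuclei$y) + 1L
  c <- round(nuclei$x) + 1L
  inside <- r >= 1 & r <= nrow(labs) & c >= 1 & c <= ncol(labs)
  zone <- rep(0L, nrow(nuclei))
  zone[inside] <- labs[cbind(r[inside], c[inside])]
  n_rejected <- sum(zone == 0L)

  zone_names <- c("outer", "intermediate", "inner")
  total <- vapply(1:3, function(z) sum(zone == z), integer(1))
  positive <- vapply(1:3, function(z) sum(zone == z & pos), integer(1))
  percent <- ifelse(total > 0, 100 * positive / total, NA_real_)
  in_tumor <- zone > 0L
  overall <- if (any(in_tumor)) {
    100 * sum(pos[in_tumor]) / sum(in_tumor)
  } else {
    NA_real_
  }
  structure(
    list(zones = data.frame(zone = zone_names, total = total,
                            positive = positive, percent = percent,
                            stringsAsFactors = FALSE),
         overall_percent = overall, n_rejected = n_rejected),
    class = "ki_score"
  )
}

#' @export
print.ki_score <- function(x, ...) {
  cat("<ki_score>\n")
  print(x$zones, row.names = FALSE)
  cat(sprintf("  overall: %s%%   rejected (outside tumor): %d\n",
              ifelse(is.na(x$overall_percent), "NA",
                     sprintf("%.1f", x$overall_percent)), x$n_rejected))
  invisible(x)
}
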