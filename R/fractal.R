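#' Box counts of a binary mask over a set of scales
#'
#' For each box edge length `eps`, partitions the foreground bounding box
#' into an axis-aligned grid of `eps x eps` cells anchored at the bounding
#' box's top-left corner (ragged cells at the right/bottom edges allowed)
#' and counts the cells containing at least one foreground pixel.
#'
#' @param mask A non-empty `binary_mask`.
#' @param scales Integer vector of box edge lengths, each >= 1 and <= the
#'   smaller raster side.
#' @return Integer vector of occupied-box counts, one per scale.
#' @seealso [fractal_dimension()]
#' @examples
#' box_count(binary_mask(matrix(TRUE, 8, 8)), c(1, 2, 4))
#' @export
box_count <- function(mask, scales) {
  stopifnot(is_binary_mask(mask))
  if (mask_area(mask) == 0L) {
    stop("empty mask: box counts (and their logs) are undefined")
  }
  scales <- as.integer(scales)
  min_side <- min(dim(mask$grid))
  if (any(scales < 1L) || any(scales > min_side)) {
    stop(sprintf("scales must be in [1, %d] (min raster side)", min_side))
  }
  fg <- which(mask$grid, arr.ind = TRUE)
  r <- fg[, 1] - min(fg[, 1])  # 0-based within the bounding box
  c <- fg[, 2] - min(fg[, 2])
  vapply(scales, function(eps) {
    qr <- r %/% eps
    qc <- c %/% eps
    length(unique(qr * (max(qc) + 1) + qc))
  }, integer(1))
}

#' Box-counting fractal dimension of a binary mask
#'
#' Estimates the box dimension as the negated slope of the ordinary
#' least-squares fit of `log N(eps)` on `log eps`, where `N(eps)` are the
#' occupied-box counts from [box_count()]. Default scales are powers of 2
#' from 2 up to `floor(min_side / 4)`; the upper bound keeps the fit out of
#' the saturated-count regime. For masks built on a non-dyadic lattice
#' (e.g. Mandelbrot percolation with subdivision factor `b`), set
#' `scale_base = b` to use powers of that base instead.
#'
#' @param mask A `binary_mask` with at least 2 foreground pixels.
#' @param scales Optional explicit integer scale vector (>= 4 values).
#' @param scale_base Integer base for the default geometric scale ladder.
#' @return An object of class `fractal_fit` with fields `scales`, `counts`,
#'   `d_f`, `stderr` (standard error of the slope; 0 for a perfect fit),
#'   `r_squared` and `intercept`.
#' @examples
#' fractal_dimension(binary_mask(matrix(TRUE, 256, 256)))$d_f  # ~2
#' @export
fractal_dimension <- function(mask, scales = NULL, scale_base = 2L) {
  stopifnot(is_binary_mask(mask))
  if (mask_area(mask) < 2L) {
    stop("need >= 2 foreground pixels to estimate a dimension")
  }
  scale_base <- as.integer(scale_base)
  stopifnot(scale_base >= 2L)
  if (is.null(scales)) {
    upper <- floor(min(dim(mask$grid)) / 4)
    kmax <- floor(log(upper) / log(scale_base) + 1e-9)
    if (kmax < 1) stop("mask too small for the default scale ladder")
    scales <- scale_base^seq_len(kmax)
  }
  scales <- sort(as.integer(scales))
  if (length(scales) < 4L) {
    stop("need >= 4 scales for a meaningful log-log fit")
  }
  counts <- box_count(mask, scales)

  x <- log(scales)
  y <- log(counts)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  d_f <- -slope
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  # slope SE computed directly so a perfect fit reports exactly 0
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  se <- if (ss_res < 1e-24) 0 else sqrt(ss_res / (n - 2) / sxx)
  r2 <- if (ss_tot < 1e-24) 1 else 1 - ss_res / ss_tot

  if (d_f < -0.05 || d_f > 2.05) {
    stop(sprintf("fitted dimension %.3f outside [0, 2] for a 2-D mask", d_f))
  }
  structure(
    list(scales = scales, counts = counts, d_f = d_f, stderr = se,
         r_squared = r2, intercept = unname(stats::coef(fit)[1])),
    class = "fractal_fit"
  )
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("<fractal_fit> d_f = %.4f (SE %.4f, R^2 %.4f) over %d scales [%d..%d]\n",
              x$d_f, x$stderr, x$r_squared, length(x$scales),
              min(x$scales), max(x$scales)))
  invisible(x)
}
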