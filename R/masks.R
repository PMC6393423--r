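#' Binary raster mask
#'
#' Container for a 2-D foreground/background raster, the substrate of all
#' area and fractal computations. The foreground pixel count is computed at
#' construction and retrievable in constant time via [mask_area()].
#'
#' @param grid A logical (or 0/1 numeric) matrix; `TRUE` is foreground.
#'   Indexed `[row, column]`, origin top-left.
#' @param pixel_size_um Physical edge length of one pixel in micrometers.
#'   Metadata only; all computation is in pixels. Default 1.3.
#'
#' @return An object of class `binary_mask` with fields `grid`,
#'   `pixel_size_um` and `n_foreground`.
#' @examples
#' m <- binary_mask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
#' mask_area(m)
#' @export
binary_mask <- function(grid, pixel_size_um = 1.3) {
  if (!is.matrix(grid)) {
    stop("`grid` must be a matrix")
  }
  if (is.numeric(grid)) {
    grid <- grid != 0
  }
  if (!is.logical(grid)) {
    stop("`grid` must be logical or numeric")
  }
  if (nrow(grid) < 1L || ncol(grid) < 1L) {
    stop("`grid` must be at least 1x1")
  }
  grid[is.na(grid)] <- FALSE
  structure(
    list(grid = grid, pixel_size_um = pixel_size_um,
         n_foreground = sum(grid)),
    class = "binary_mask"
  )
}

#' @rdname binary_mask
#' @param x An object.
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

#' @rdname binary_mask
#' @param mask A `binary_mask`.
#' @return `mask_area()`: the foreground pixel count (integer).
#' @export
mask_area <- function(mask) {
  stopifnot(is_binary_mask(mask))
  mask$n_foreground
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground (%.1f%%), %.3g um/px\n",
              nrow(x$grid), ncol(x$grid), x$n_foreground,
              100 * x$n_foreground / length(x$grid), x$pixel_size_um))
  invisible(x)
}

#' Rasterize a filled disk mask
#'
#' @param radius Disk radius in pixels.
#' @param margin Background margin around the disk, in pixels. The raster
#'   side is `2 * (radius + margin) + 1`.
#' @param pixel_size_um Passed to [binary_mask()].
#' @return A `binary_mask` containing a centered filled disk.
#' @examples
#' mask_area(disk_mask(20))
#' @export
disk_mask <- function(radius, margin = 0, pixel_size_um = 1.3) {
  stopifnot(radius >= 1)
  side <- 2L * (as.integer(radius) + as.integer(margin)) + 1L
  ctr <- as.integer(radius) + as.integer(margin) + 1L
  d2 <- outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, `+`)
  binary_mask(d2 <= radius^2, pixel_size_um = pixel_size_um)
}

#' Histology-like section image
#'
#' Bundle of an 8-bit RGB raster, its tumor mask, and (for synthetic images)
#' ground-truth annotations.
#'
#' @param rgb Numeric array `[rows, cols, 3]` with values in 0..255.
#' @param tumor_mask A `binary_mask` of the same raster size marking tumor
#'   tissue.
#' @param necrosis_truth Optional `binary_mask`: ground-truth necrosis.
#' @param nuclei_truth Optional data frame of ground-truth nuclei with
#'   0-based `x` (column) and `y` (row) coordinates.
#' @param meta Optional list of generator parameters.
#' @return An object of class `section_image`.
#' @export
section_image <- function(rgb, tumor_mask, necrosis_truth = NULL,
                          nuclei_truth = NULL, meta = list()) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  stopifnot(is_binary_mask(tumor_mask))
  if (!all(dim(rgb)[1:2] == dim(tumor_mask$grid))) {
    stop("rgb raster and tumor mask dimensions differ")
  }
  if (!is.null(necrosis_truth)) {
    stopifnot(is_binary_mask(necrosis_truth))
    if (any(necrosis_truth$grid & !tumor_mask$grid)) {
      stop("ground-truth necrosis extends outside the tumor mask")
    }
  }
  structure(
    list(rgb = rgb, tumor_mask = tumor_mask,
         necrosis_truth = necrosis_truth, nuclei_truth = nuclei_truth,
         meta = meta),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px RGB, tumor area %d px\n",
              dim(x$rgb)[1], dim(x$rgb)[2], mask_area(x$tumor_mask)))
  if (!is.null(x$necrosis_truth)) {
    cat(sprintf("  ground-truth necrosis: %.1f%% of tumor\n",
                100 * mask_area(x$necrosis_truth) / mask_area(x$tumor_mask)))
  }
  if (!is.null(x$nuclei_truth)) {
    cat(sprintf("  ground-truth nuclei: %d\n", nrow(x$nuclei_truth)))
  }
  invisible(x)
}
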