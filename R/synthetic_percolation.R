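#' Mandelbrot percolation fractal mask of known box dimension
#'
#' Generates a random fractal by recursive curdling: starting from one
#' retained cell, each level subdivides every retained cell into
#' `base x base` children and independently retains each child with
#' probability `retain_prob`. In the supercritical regime
#' (`base^2 * retain_prob > 1`) the limit set has box dimension
#' `log(base^2 * retain_prob) / log(base)`, which makes these masks a
#' validation substrate of known ground truth for box-counting estimators.
#'
#' The process may go extinct (no retained cell at the final level); an
#' all-background mask is then returned rather than silently re-sampling,
#' so identical specs give bit-identical output. Callers needing a
#' non-extinct mask should re-seed.
#'
#' @param base Integer subdivision factor `b >= 2`.
#' @param retain_prob Retention probability `p` in (0, 1].
#' @param levels Integer number of subdivision levels `L >= 1`; the raster
#'   side is `base^levels`.
#' @param seed Integer RNG seed; the generator is deterministic given the
#'   full spec.
#' @param max_side Size cap on the raster side; larger requests error.
#' @return A `binary_mask` of side `base^levels`.
#' @seealso [percolation_dimension()], [fractal_dimension()]
#' @examples
#' m <- gen_percolation_mask(base = 2, retain_prob = 0.9, levels = 6, seed = 1)
#' percolation_dimension(2, 0.9)
#' @export
gen_percolation_mask <- function(base, retain_prob, levels, seed,
                                 max_side = 4096L) {
  base <- as.integer(base)
  levels <- as.integer(levels)
  stopifnot(base >= 2L, levels >= 1L)
  if (!(retain_prob > 0 && retain_prob <= 1)) {
    stop("`retain_prob` must be in (0, 1]")
  }
  if (base^2 * retain_prob <= 1) {
    stop(sprintf(
      "subcritical spec: base^2 * retain_prob = %.3f <= 1, box dimension undefined",
      base^2 * retain_prob))
  }
  side <- base^levels
  if (side > max_side) {
    stop(sprintf("raster side %d exceeds the size cap %d", side, max_side))
  }
  grid <- with_seed(seed, {
    m <- matrix(TRUE, 1L, 1L)
    for (l in seq_len(levels)) {
      s <- nrow(m) * base
      parent <- m[rep(seq_len(nrow(m)), each = base),
                  rep(seq_len(ncol(m)), each = base), drop = FALSE]
      # draws are consumed for every cell, retained parent or not, so the
      # stream layout does not depend on earlier outcomes
      m <- parent & (stats::runif(s * s) < retain_prob)
      dim(m) <- c(s, s)
    }
    m
  })
  binary_mask(grid)
}

#' Theoretical box dimension of supercritical Mandelbrot percolation
#'
#' @inheritParams gen_percolation_mask
#' @return `log(base^2 * retain_prob) / log(base)`, equivalently
#'   `2 + log(retain_prob) / log(base)`.
#' @export
percolation_dimension <- function(base, retain_prob) {
  if (base^2 * retain_prob <= 1) {
    stop("subcritical: dimension undefined")
  }
  2 + log(retain_prob) / log(base)
}
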