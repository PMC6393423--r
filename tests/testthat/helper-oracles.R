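# Independent oracles and fixture builders used across the suite.
# These deliberately use different code paths from the package.

# Naive box counter: explicit double loop over grid cells.
naive_box_count <- function(grid, eps) {
  fg <- which(grid, arr.ind = TRUE)
  r0 <- min(fg[, 1])
  c0 <- min(fg[, 2])
  r1 <- max(fg[, 1])
  c1 <- max(fg[, 2])
  count <- 0L
  for (top in seq(r0, r1, by = eps)) {
    for (left in seq(c0, c1, by = eps)) {
      cell <- grid[top:min(top + eps - 1L, r1),
                   left:min(left + eps - 1L, c1), drop = FALSE]
      if (any(cell)) count <- count + 1L
    }
  }
  count
}

# Brute-force exact Mann-Whitney two-sided p over all C(n1+n2, n1)
# labelings, via bitmask enumeration and direct pairwise U counting.
brute_force_mw <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  pooled <- c(x, y)
  u_of <- function(xx, yy) {
    u1 <- sum(vapply(xx, function(v) sum(v > yy) + 0.5 * sum(v == yy),
                     numeric(1)))
    min(u1, length(xx) * length(yy) - u1)
  }
  u_obs <- u_of(x, y)
  hits <- 0L
  total <- 0L
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    if (sum(bits) != n1) next
    total <- total + 1L
    if (u_of(pooled[bits == 1L], pooled[bits == 0L]) <= u_obs + 1e-9) {
      hits <- hits + 1L
    }
  }
  list(U = u_obs, p = hits / total)
}

# Sierpinski triangle mask of the given dyadic side (256 = level 8).
sierpinski_mask <- function(side) {
  g <- outer(0:(side - 1), 0:(side - 1),
             function(i, j) bitwAnd(i, j) == 0L)
  binary_mask(g)
}

# Irregular blob mask: thresholded smooth noise added to a disk potential.
# Always >= 1024 foreground pixels.
random_blob_mask <- function(radius = 40, seed = 1) {
  set.seed(seed)
  side <- 2L * radius + 21L
  ctr <- radius + 11L
  noise <- EBImage::gblur(matrix(runif(side^2), side, side),
                          sigma = radius / 5)
  noise <- (noise - mean(noise)) / sd(noise)
  d <- sqrt(outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, `+`))
  g <- (d + 0.2 * radius * noise) <= radius
  stopifnot(sum(g) >= 1024)
  binary_mask(g)
}

# Greedy centroid matching of detections to ground truth within `tol` px.
match_nuclei <- function(detected, truth, tol = 3) {
  if (nrow(detected) == 0L || nrow(truth) == 0L) {
    return(data.frame(det = integer(0), tru = integer(0)))
  }
  d2 <- outer(detected$x, truth$x, `-`)^2 + outer(detected$y, truth$y, `-`)^2
  pairs <- data.frame(det = integer(0), tru = integer(0))
  repeat {
    m <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    if (d2[m[1], m[2]] > tol^2) break
    pairs <- rbind(pairs, data.frame(det = m[1], tru = m[2]))
    d2[m[1], ] <- Inf
    d2[, m[2]] <- Inf
    if (all(!is.finite(d2))) break
  }
  pairs
}

# Collect >= n_masks non-extinct percolation masks, re-seeding past extinct
# realizations from a fixed stream of seeds.
nonextinct_percolation <- function(base, p, levels, n_masks, seed_start = 1) {
  masks <- list()
  s <- seed_start - 1L
  while (length(masks) < n_masks) {
    s <- s + 1L
    m <- gen_percolation_mask(base, p, levels, seed = s)
    if (mask_area(m) > 0L) masks[[length(masks) + 1L]] <- m
  }
  masks
}
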