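# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Rec. 601 luma; inputs on the 0..255 scale.
luminance <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b

# Otsu's threshold by exhaustive between-class variance maximization over a
# fixed histogram. Returns a value on the scale of `x` (a bin midpoint).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (length(x) == 0L || diff(rng) <= 0) {
    return(rng[1])
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(x, breaks, all.inside = TRUE),
                           n_bins))
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  s1 <- cumsum(h * mids)
  m1 <- s1 / w1
  m2 <- (sum(h * mids) - s1) / w2
  between <- w1 * w2 * (m1 - m2)^2
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Gaussian smoothing restricted to a mask via normalized convolution, so
# values outside the mask (e.g. the white slide background) never bleed in.
smooth_masked <- function(values, mask, sigma) {
  m <- mask * 1
  num <- EBImage::gblur(values * m, sigma = sigma)
  den <- EBImage::gblur(m, sigma = sigma)
  out <- num / pmax(den, 1e-8)
  out[!mask] <- 0
  out
}

# Integer (dr, dc) offsets of a filled disk of the given radius.
disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

# Format numbers for byte-stable CSV output: 6 significant digits.
fmt_num <- function(x) {
  ifelse(is.na(x), "", formatC(signif(x, 6), format = "g", digits = 6))
}

# Write a data frame as CSV with 6-significant-digit numeric formatting and
# fixed column order; byte-stable across platforms.
write_csv_stable <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- fmt_num(out[[j]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
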