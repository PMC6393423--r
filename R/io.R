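COHORT_COLUMNS <- c("group", "animal_id", "day", "length_mm", "width_mm",
                    "weight_g")

#' Read and write cohort caliper tables
#'
#' The cohort CSV schema is fixed: header exactly
#' `group,animal_id,day,length_mm,width_mm,weight_g`, comma-separated,
#' decimal point, UTF-8; `weight_g` may be empty. Rows with `length_mm <
#' width_mm` are kept but flagged with a swap warning (caliper orientation
#' slips); duplicate `(group, animal_id, day)` keys are an error naming the
#' offending row.
#'
#' @param path File path.
#' @return `read_cohort_csv()`: a `cohort_table` data frame.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_cohort_csv(gen_cohort(seed = 1), p)
#' nrow(read_cohort_csv(p))
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path))
  }
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), COHORT_COLUMNS)) {
    stop(sprintf("bad cohort header: expected '%s', got '%s'",
                 paste(COHORT_COLUMNS, collapse = ","),
                 paste(header, collapse = ",")))
  }
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "character", "character",
                                             "character", "character"),
                        na.strings = c("", "NA"), encoding = "UTF-8")
  for (col in c("day", "length_mm", "width_mm", "weight_g")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column %s, data row %d",
                   df[[col]][bad[1]], col, bad[1]))
    }
    df[[col]] <- v
  }
  if (any(is.na(df$day)) || any(is.na(df$length_mm)) ||
      any(is.na(df$width_mm))) {
    stop("day, length_mm and width_mm must not be missing")
  }
  if (any(df$length_mm <= 0) || any(df$width_mm <= 0)) {
    bad <- which(df$length_mm <= 0 | df$width_mm <= 0)[1]
    stop(sprintf("non-positive caliper value in data row %d", bad))
  }
  df$day <- as.integer(df$day)
  key <- paste(df$group, df$animal_id, df$day, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate (group, animal_id, day) = (%s, %s, %d) at data row %d",
                 df$group[dup[1]], df$animal_id[dup[1]], df$day[dup[1]],
                 dup[1]))
  }
  swap <- which(df$length_mm < df$width_mm)
  if (length(swap)) {
    warning(sprintf("%d row(s) with length < width (data rows %s): treated as caliper orientation slips",
                    length(swap),
                    paste(utils::head(swap, 5), collapse = ", ")))
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @rdname read_cohort_csv
#' @param cohort A `cohort_table`.
#' @return `write_cohort_csv()`: the path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort), all(COHORT_COLUMNS %in% names(cohort)))
  write_csv_stable(cohort[COHORT_COLUMNS], path)
}

#' Read and write binary masks as single-channel PNG
#'
#' Masks travel as 8-bit single-channel PNG with values {0, 255}. On read,
#' any other value is an error unless `binarize_at` is given, in which case
#' values `>= binarize_at` become foreground. Multi-channel files are an
#' error unless `channel` selects one. A write-then-read round trip is the
#' identity.
#'
#' @param path File path.
#' @param binarize_at Optional threshold in 0..255.
#' @param channel Optional channel index for multi-channel input.
#' @param pixel_size_um Passed to [binary_mask()].
#' @return `read_mask_png()`: a `binary_mask`.
#' @examples
#' p <- tempfile(fileext = ".png")
#' write_mask_png(disk_mask(20), p)
#' mask_area(read_mask_png(p))
#' @export
read_mask_png <- function(path, binarize_at = NULL, channel = NULL,
                          pixel_size_um = 1.3) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) {
    if (is.null(channel)) {
      stop(sprintf("multi-channel PNG (%d channels): pass `channel`",
                   dim(arr)[3]))
    }
    arr <- arr[, , channel]
  }
  v <- round(arr * 255)
  if (is.null(binarize_at)) {
    if (!all(v %in% c(0, 255))) {
      bad <- sort(unique(v[!(v %in% c(0, 255))]))
      stop(sprintf("mask PNG contains values other than {0, 255} (e.g. %d); pass `binarize_at` to threshold",
                   bad[1]))
    }
    grid <- v == 255
  } else {
    grid <- v >= binarize_at
  }
  binary_mask(grid, pixel_size_um = pixel_size_um)
}

#' @rdname read_mask_png
#' @param mask A `binary_mask`.
#' @return `write_mask_png()`: the path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is_binary_mask(mask))
  png::writePNG(mask$grid * 1.0, path)
  invisible(path)
}

#' Write an RGB section image (or zone label raster) as PNG
#'
#' @param image A `section_image`, or a numeric array `[rows, cols, 3]` on
#'   the 0..255 scale.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_rgb_png <- function(image, path) {
  arr <- if (inherits(image, "section_image")) image$rgb else image
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  scaled <- arr / 255
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  png::writePNG(scaled, path)
  invisible(path)
}

#' Write a zone partition as a label PNG (values 1/2/3 on 0..255 scale)
#'
#' Background is 0; outer/intermediate/inner zones are written as pixel
#' values 1, 2 and 3 (read back with `round(value * 255)`).
#'
#' @param partition A `zone_partition`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_zones_png <- function(partition, path) {
  stopifnot(inherits(partition, "zone_partition"))
  png::writePNG(partition$labels / 255, path)
  invisible(path)
}
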