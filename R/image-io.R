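#' Read a micrograph from disk
#'
#' Reads a raster image and returns it in the 8-bit integer domain the
#' transformation pipeline operates in: a gray image is returned as an
#' integer matrix with values in `[0, 255]`; a colour image as an
#' `height x width x 3` integer array. Higher bit depths (e.g. 16-bit TIFF)
#' are rescaled linearly onto `[0, 255]`; the applied scale is recorded in
#' the `"rescaled_from"` attribute. An alpha channel, if present, is dropped.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @return An integer matrix (grayscale) or a 3-slice integer array (colour),
#'   values in `[0, 255]`.
#' @seealso [to_grayscale()], [write_image()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(
    ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      }
      jpeg::readJPEG(path)
    },
    stop(sprintf("unsupported image format: '.%s'", ext), call. = FALSE)
  )
  # png/tiff readers normalise to [0, 1] whatever the stored depth
  if (length(dim(raw)) == 3L && dim(raw)[3] >= 3L) {
    out <- round_half_up(raw[, , 1:3, drop = FALSE] * 255)
    storage.mode(out) <- "double"
    return(out)
  }
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L] # single-channel stored 3-D
  out <- round_half_up(raw * 255)
  attr(out, "rescaled_from") <- "[0,1] reader-normalised"
  assert_gray_image(out)
  out
}

#' Write a gray image or mask to disk
#'
#' @param img Integer matrix in `[0, 255]`, or a logical mask (written as
#'   0/255).
#' @param path Output path; format chosen by extension (`.png` or `.tif`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (is.logical(img)) img <- ifelse(img, 255, 0)
  assert_gray_image(img)
  ext <- tolower(tools::file_ext(path))
  norm <- img / 255
  switch(
    ext,
    png  = png::writePNG(norm, path),
    tif  = ,
    tiff = tiff::writeTIFF(norm, path, bits.per.sample = 8L),
    stop(sprintf("unsupported output format: '.%s'", ext), call. = FALSE)
  )
  invisible(path)
}

#' Convert a colour micrograph to 8-bit grayscale
#'
#' Per-pixel luminance `L = round(0.299 R + 0.587 G + 0.114 B)` (the
#' convention of common image-analysis tools), rounded half-up and clipped to
#' `[0, 255]`. A matrix input is assumed already gray and returned unchanged.
#'
#' @param img Colour array (`h x w x 3`, channels in `[0, 255]`) or gray
#'   matrix.
#' @param weights Length-3 RGB luma weights; must sum to 1.
#' @return Integer gray matrix in `[0, 255]`.
#' @export
to_grayscale <- function(img, weights = c(0.299, 0.587, 0.114)) {
  if (is.matrix(img)) {
    assert_gray_image(img)
    return(img)
  }
  if (length(dim(img)) != 3L || dim(img)[3] < 3L) {
    stop("`img` must be a gray matrix or an h x w x 3 colour array",
         call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must sum to 1", call. = FALSE)
  }
  lum <- matrix(weights[1] * img[, , 1] + weights[2] * img[, , 2] +
                  weights[3] * img[, , 3],
                dim(img)[1], dim(img)[2])
  clip255(round_half_up(lum))
}

#' Read a calibration sample table
#'
#' Parses a CSV with header columns `sample_id, mii, dcw, dilution_factor,
#' time_h` (only `sample_id` plus one of `mii`/`dcw` are required; unknown
#' columns are preserved). Validates that sample ids are unique, MII values
#' lie in `[0, 255]` and DCW values are non-negative, reporting offending
#' rows by number.
#'
#' @param path CSV path (comma-separated, UTF-8, header row; empty cells are
#'   missing values).
#' @return A tibble, one row per sample.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("sample table not found: '%s'", path), call. = FALSE)
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         na = c("", "NA"), progress = FALSE)
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed cells in '%s' at rows: %s", path,
                 paste(unique(probs$row), collapse = ", ")), call. = FALSE)
  }
  validate_sample_table(tbl)
}

#' Validate a calibration sample table
#'
#' @param tbl Data frame with at least `sample_id` and one of `mii`, `dcw`.
#' @return The table as a tibble, invisibly checked.
#' @export
validate_sample_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  if (!"sample_id" %in% names(tbl) ||
      !any(c("mii", "dcw") %in% names(tbl))) {
    stop("sample table needs a `sample_id` column and `mii` and/or `dcw`",
         call. = FALSE)
  }
  dup <- tbl$sample_id[duplicated(tbl$sample_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicated sample_id: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  if ("mii" %in% names(tbl)) {
    bad <- which(!is.na(tbl$mii) & (tbl$mii < 0 | tbl$mii > 255))
    if (length(bad) > 0) {
      stop(sprintf("mii outside [0, 255] at rows: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if ("dcw" %in% names(tbl)) {
    bad <- which(!is.na(tbl$dcw) & tbl$dcw < 0)
    if (length(bad) > 0) {
      stop(sprintf("negative dcw at rows: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if ("dilution_factor" %in% names(tbl) &&
      any(!is.na(tbl$dilution_factor) & tbl$dilution_factor <= 0)) {
    stop("dilution_factor must be positive", call. = FALSE)
  }
  tbl
}
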