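#' Pipeline configuration for the MII transformation chain
#'
#' Bundles every tunable of the transformation chain. The defaults are the
#' published workflow: primary threshold at gray level 154 on the raw
#' grayscale image, secondary threshold at 180 after background subtraction
#' and contrast enhancement, dark mycelium on a bright field.
#'
#' @param threshold_primary Primary gray-level cutoff in `[0, 255]`
#'   (default 154), applied to the raw grayscale image.
#' @param threshold_secondary Secondary cutoff in `[0, 255]` (default 180),
#'   applied after background subtraction inverts the signal to bright on
#'   dark.
#' @param foreground_polarity Polarity of the input micrograph:
#'   `"dark_on_bright"` (bright-field, default) or `"bright_on_dark"`.
#' @param background_radius Rolling-ball disc radius in pixels (default 50).
#' @param contrast_saturation Saturated tail fraction of the contrast
#'   stretch, in `[0, 0.5)` (default 0.0035).
#' @param dilation_selem Structuring element for dilating the primary mask:
#'   `"square3"` or `"cross3"`.
#' @param median_radius Median-filter window radius in pixels (default 1).
#' @param maxima_prominence Prominence threshold annotating speck-like
#'   removals (default 10 gray levels).
#' @param min_object_area Minimum connected-component area kept, in pixels
#'   (default 20).
#' @param mii_mode `"whole_image"` (mean over the full zeroed frame,
#'   default) or `"mask_only"`.
#' @return A list of class `mii_config`.
#' @export
mii_config <- function(threshold_primary = 154,
                       threshold_secondary = 180,
                       foreground_polarity = "dark_on_bright",
                       background_radius = 50,
                       contrast_saturation = 0.0035,
                       dilation_selem = "square3",
                       median_radius = 1,
                       maxima_prominence = 10,
                       min_object_area = 20,
                       mii_mode = "whole_image") {
  cfg <- list(
    threshold_primary = threshold_primary,
    threshold_secondary = threshold_secondary,
    foreground_polarity = match_polarity(foreground_polarity),
    background_radius = background_radius,
    contrast_saturation = contrast_saturation,
    dilation_selem = match.arg(dilation_selem, c("square3", "cross3")),
    median_radius = median_radius,
    maxima_prominence = maxima_prominence,
    min_object_area = min_object_area,
    mii_mode = match.arg(mii_mode, c("whole_image", "mask_only"))
  )
  assert_level(cfg$threshold_primary)
  assert_level(cfg$threshold_secondary)
  if (cfg$background_radius < 1 || cfg$median_radius < 1) {
    stop("background_radius and median_radius must be >= 1", call. = FALSE)
  }
  if (cfg$maxima_prominence < 0 || cfg$min_object_area < 0) {
    stop("maxima_prominence and min_object_area must be non-negative",
         call. = FALSE)
  }
  structure(cfg, class = "mii_config")
}

#' Read a pipeline configuration from a flat key = value file
#'
#' One `key = value` pair per line, keys matching [mii_config()] arguments;
#' blank lines and `#` comments ignored; unknown keys rejected.
#'
#' @param path Config file path.
#' @return An `mii_config` object.
#' @export
read_mii_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lines[lengths(kv) != 2L]
  if (length(bad) > 0) {
    stop(sprintf("malformed config line(s): %s", paste(bad, collapse = "; ")),
         call. = FALSE)
  }
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  known <- names(formals(mii_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  args <- stats::setNames(as.list(vals), keys)
  numeric_keys <- setdiff(known, c("foreground_polarity", "dilation_selem",
                                   "mii_mode"))
  args[names(args) %in% numeric_keys] <-
    lapply(args[names(args) %in% numeric_keys], as.numeric)
  do.call(mii_config, args)
}

#' @export
print.mii_config <- function(x, ...) {
  cat("<mii_config>\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, x[[k]]))
  invisible(x)
}

#' Transform a micrograph and measure its MII
#'
#' Runs the full transformation chain that virtually separates mycelium
#' from medium and summarises the frame as one intensity value:
#'
#' 1. grayscale conversion (colour input only);
#' 2. primary threshold (level 154) on the raw grayscale image, giving a
#'    provisional colony mask;
#' 3. rolling-ball background subtraction — the uneven bright field is
#'    estimated and removed, leaving mycelium signal bright on dark;
#' 4. linear contrast enhancement;
#' 5. secondary threshold (level 180, bright-on-dark) gated by the *dilated*
#'    provisional mask (logical AND), so enhancement artifacts outside the
#'    colony cannot enter;
#' 6. median filtering of the enhanced image;
#' 7. removal of connected components too small to be mycelium;
#' 8. zeroing of all non-mask pixels;
#' 9. MII measurement ([measure_mii()]).
#'
#' @param img Gray matrix or colour array (see [read_image()]).
#' @param cfg An [mii_config()].
#' @return An object of class `mii_transform`: list with `transformed` (gray
#'   matrix, background zeroed), `mask` (logical), `mii` (numeric scalar),
#'   `mask_area_px`, and `provenance` (character vector of applied stages
#'   with parameters).
#' @export
transform_image <- function(img, cfg = mii_config()) {
  stopifnot(inherits(cfg, "mii_config"))
  prov <- character()
  step <- function(fun, label, ...) {
    res <- tryCatch(fun(...),
                    error = function(e) {
                      stop(sprintf("stage '%s' failed: %s", label,
                                   conditionMessage(e)), call. = FALSE)
                    })
    prov <<- c(prov, label)
    res
  }

  g <- step(to_grayscale, "to_grayscale", img)
  m1 <- step(img_threshold,
             sprintf("threshold(level=%s, polarity=%s)",
                     cfg$threshold_primary, cfg$foreground_polarity),
             g, cfg$threshold_primary, cfg$foreground_polarity)
  bs <- step(subtract_background,
             sprintf("subtract_background(radius=%s)", cfg$background_radius),
             g, cfg$background_radius, cfg$foreground_polarity)
  ce <- step(enhance_contrast,
             sprintf("enhance_contrast(saturation=%s)",
                     cfg$contrast_saturation),
             bs, cfg$contrast_saturation)
  m1d <- step(dilate_mask, sprintf("dilate(selem=%s)", cfg$dilation_selem),
              m1, cfg$dilation_selem)
  m2 <- step(img_threshold,
             sprintf("threshold(level=%s, polarity=bright_on_dark)",
                     cfg$threshold_secondary),
             ce, cfg$threshold_secondary, "bright_on_dark") & m1d
  prov <- c(prov, "and(dilated_primary_mask)")
  mf <- step(median_filter, sprintf("median_filter(radius=%s)",
                                    cfg$median_radius),
             ce, cfg$median_radius)
  m3 <- step(remove_noise_objects,
             sprintf("remove_noise_objects(prominence=%s, min_area=%s)",
                     cfg$maxima_prominence, cfg$min_object_area),
             m2, mf, cfg$maxima_prominence, cfg$min_object_area)
  removed <- attr(m3, "removed")
  attr(m3, "removed") <- NULL
  transformed <- mf
  transformed[!m3] <- 0
  prov <- c(prov, "zero_background")
  mii <- measure_mii(transformed, m3, cfg$mii_mode)
  prov <- c(prov, sprintf("measure_mii(mode=%s)", cfg$mii_mode))

  structure(
    list(transformed = transformed, mask = m3, mii = mii,
         mask_area_px = sum(m3), removed = removed,
         provenance = prov, config = cfg),
    class = "mii_transform"
  )
}

#' @export
print.mii_transform <- function(x, ...) {
  cat(sprintf("<mii_transform> %dx%d px | MII = %.3f | mask area = %d px (%.2f%%)\n",
              nrow(x$transformed), ncol(x$transformed), x$mii,
              x$mask_area_px,
              100 * x$mask_area_px / length(x$transformed)))
  cat("stages:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Measure MII for a batch of micrographs
#'
#' Maps [transform_image()] over files or in-memory images and returns one
#' tidy row per micrograph, ready to join with DCW measurements for
#' calibration.
#'
#' @param images Character vector of image paths, or a (named) list of
#'   image matrices/arrays.
#' @param cfg An [mii_config()].
#' @return A tibble with columns `sample_id, mii, mask_area_px,
#'   provenance_hash`.
#' @export
mii_batch <- function(images, cfg = mii_config()) {
  if (is.character(images)) {
    ids <- tools::file_path_sans_ext(basename(images))
    images <- purrr::map(images, read_image)
  } else {
    ids <- names(images)
    if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(images))
  }
  purrr::map2_dfr(images, ids, function(im, id) {
    tr <- transform_image(im, cfg)
    tibble::tibble(
      sample_id = id,
      mii = tr$mii,
      mask_area_px = tr$mask_area_px,
      provenance_hash = rlang::hash(tr$provenance)
    )
  })
}
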