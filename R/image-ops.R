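# Elementary image operators of the MII transformation chain. All operators
# take and return integer matrices in [0, 255] (gray images) or logical
# matrices (masks); dimensions are preserved throughout.

#' Gray-level thresholding
#'
#' Classifies every pixel as mycelium (foreground) or medium (background) by
#' comparison with a gray-level cutoff. In bright-field micrographs mycelium
#' is darker than the medium, so with the default `dark_on_bright` polarity a
#' pixel is foreground iff its value is `<= level`; with `bright_on_dark`
#' (used after background subtraction inverts the signal) iff `>= level`.
#'
#' @param img Gray image matrix.
#' @param level Cutoff in `[0, 255]`.
#' @param polarity `"dark_on_bright"` or `"bright_on_dark"`.
#' @return Logical mask with the image's dimensions.
#' @export
img_threshold <- function(img, level, polarity = "dark_on_bright") {
  assert_gray_image(img)
  assert_level(level)
  polarity <- match_polarity(polarity)
  if (polarity == "dark_on_bright") img <= level else img >= level
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth illumination background by grayscale morphology with
#' a disc structuring element of the given radius and removes it. For
#' `dark_on_bright` input the bright background is estimated by grayscale
#' closing (which fills dark features narrower than the disc) and the result
#' is `background - image`, so mycelium signal comes back *bright on dark*;
#' for `bright_on_dark` the background is the grayscale opening and the
#' result is `image - background`. Output is clipped to `[0, 255]` and has
#' the input's dimensions.
#'
#' @param img Gray image matrix.
#' @param radius Disc radius in pixels (`>= 1`).
#' @param polarity Polarity of the *input* image.
#' @return Gray image matrix, signal bright on dark.
#' @export
subtract_background <- function(img, radius = 50, polarity = "dark_on_bright") {
  assert_gray_image(img)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1) {
    stop("`radius` must be a single value >= 1", call. = FALSE)
  }
  polarity <- match_polarity(polarity)
  r <- as.integer(radius)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  brush <- matrix(as.numeric(off$dr^2 + off$dc^2 <= r^2), 2L * r + 1L)
  x <- EBImage::Image(img / 255)
  if (polarity == "dark_on_bright") {
    # closing fills dark features narrower than the disc -> background
    bg <- round(EBImage::imageData(EBImage::closing(x, brush)) * 255)
    out <- bg - img
  } else {
    bg <- round(EBImage::imageData(EBImage::opening(x, brush)) * 255)
    out <- img - bg
  }
  clip255(round_half_up(out))
}

#' Quantile-based linear contrast stretch
#'
#' Maps the `saturation` and `1 - saturation` quantiles of the pixel
#' distribution to 0 and 255 and scales intermediate values linearly
#' (rounding half-up, clipping the saturated tails). A constant image is
#' returned unchanged.
#'
#' @param img Gray image matrix.
#' @param saturation Fraction of pixels saturated at each end, in
#'   `[0, 0.5)`; 0.0035 mirrors the 0.35% default of common ImageJ-style
#'   enhancement.
#' @return Gray image matrix spanning `[0, 255]` (unless degenerate).
#' @export
enhance_contrast <- function(img, saturation = 0.0035) {
  assert_gray_image(img)
  if (!is.numeric(saturation) || saturation < 0 || saturation >= 0.5) {
    stop("`saturation` must be in [0, 0.5)", call. = FALSE)
  }
  q <- stats::quantile(img, c(saturation, 1 - saturation), names = FALSE)
  lo <- q[1]; hi <- q[2]
  if (hi <= lo) return(img)
  clip255(round_half_up((img - lo) * 255 / (hi - lo)))
}

#' Morphological dilation of a binary mask
#'
#' Expands the mask by a 3x3 structuring element (full square or cross);
#' out-of-bounds neighbours are treated as background. The result is always
#' a superset of the input.
#'
#' @param mask Logical mask.
#' @param selem `"square3"` (8-neighbourhood) or `"cross3"`
#'   (4-neighbourhood).
#' @return Logical mask.
#' @export
dilate_mask <- function(mask, selem = "square3") {
  assert_mask(mask)
  selem <- match.arg(selem, c("square3", "cross3"))
  offs <- if (selem == "square3") {
    expand.grid(dr = -1:1, dc = -1:1)
  } else {
    data.frame(dr = c(0, -1, 1, 0, 0), dc = c(0, 0, 0, -1, 1))
  }
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out | shift_matrix(mask, offs$dr[k], offs$dc[k], FALSE)
  }
  out
}

#' Median filter
#'
#' Replaces each pixel by the median of its `(2r+1) x (2r+1)` neighbourhood;
#' windows at the border are truncated to in-bounds pixels. Removes impulse
#' (speck) noise while preserving hyphal edges.
#'
#' @param img Gray image matrix.
#' @param radius Window radius in pixels (`>= 1`).
#' @return Gray image matrix.
#' @export
median_filter <- function(img, radius = 1) {
  assert_gray_image(img)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1) {
    stop("`radius` must be a single value >= 1", call. = FALSE)
  }
  r <- as.integer(radius)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  stack <- vapply(
    seq_len(nrow(offs)),
    function(k) as.vector(shift_matrix(img, offs$dr[k], offs$dc[k],
                                       NA_real_)),
    numeric(length(img))
  )
  med <- apply(stack, 1L, stats::median, na.rm = TRUE)
  out <- matrix(round_half_up(med), nrow(img), ncol(img))
  clip255(out)
}

#' Label connected components of a mask
#'
#' 8-connected component labelling by iterative minimum-label propagation.
#'
#' @param mask Logical mask.
#' @return Integer matrix; 0 for background, components numbered from 1 in
#'   order of their smallest linear index.
#' @export
label_components <- function(mask) {
  assert_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(Inf, h, w)
  lab[mask] <- which(mask)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  repeat {
    new <- lab
    for (k in seq_len(nrow(offs))) {
      new <- pmin(new, shift_matrix(lab, offs$dr[k], offs$dc[k], Inf))
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, h, w)
  roots <- sort(unique(lab[mask]))
  out[mask] <- match(lab[mask], roots)
  out
}

#' Remove noise objects from a mycelium mask
#'
#' Discards connected components (8-connectivity) whose pixel area is below
#' `min_area` — the specks that survive thresholding but cannot be mycelium.
#' For each discarded component the intensity prominence (component extremum
#' minus the median gray level of its one-pixel surround) is computed and
#' returned in the `"removed"` attribute, flagging which removals were
#' isolated bright/dark maxima (`prominence > prominence` threshold) rather
#' than mere dust. The result is always a subset of the input mask; a
#' component of exactly `min_area` pixels is retained.
#'
#' @param mask Logical mask.
#' @param img Gray image the mask was derived from (same dimensions).
#' @param prominence Prominence threshold used to annotate speck-like
#'   removals.
#' @param min_area Minimum component area in pixels.
#' @return Logical mask with attribute `"removed"`: a tibble of
#'   `component, area, prominence, speck_like`.
#' @export
remove_noise_objects <- function(mask, img, prominence = 10, min_area = 20) {
  assert_mask(mask)
  assert_gray_image(img)
  assert_same_dim(mask, img)
  lab <- label_components(mask)
  if (max(lab) == 0L) {
    out <- mask
    attr(out, "removed") <- tibble::tibble(component = integer(),
                                           area = integer(),
                                           prominence = numeric(),
                                           speck_like = logical())
    return(out)
  }
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  drop_ids <- which(areas < min_area)
  out <- mask
  prom <- numeric(length(drop_ids))
  for (i in seq_along(drop_ids)) {
    id <- drop_ids[i]
    comp <- lab == id
    ring <- dilate_mask(comp, "square3") & !comp
    surround <- if (any(ring)) stats::median(img[ring]) else 0
    prom[i] <- max(abs(range(img[comp]) - surround))
    out[comp] <- FALSE
  }
  attr(out, "removed") <- tibble::tibble(
    component = drop_ids,
    area = areas[drop_ids],
    prominence = prom,
    speck_like = prom > prominence
  )
  out
}

#' Microscopic image intensity of a transformed micrograph
#'
#' The MII statistic: the arithmetic mean gray level of the transformed
#' image. In `whole_image` mode (the default; assumes background pixels have
#' been zeroed) the mean is over the full frame, so MII grows with mycelial
#' coverage; in `mask_only` mode it is the mean over mask pixels only (0 for
#' an empty mask).
#'
#' @param transformed Gray image matrix (background suppressed to 0).
#' @param mask Logical mycelium mask, same dimensions.
#' @param mode `"whole_image"` or `"mask_only"`.
#' @return A single number in `[0, 255]`.
#' @export
measure_mii <- function(transformed, mask, mode = "whole_image") {
  assert_gray_image(transformed)
  assert_mask(mask)
  assert_same_dim(transformed, mask)
  mode <- match.arg(mode, c("whole_image", "mask_only"))
  if (mode == "whole_image") {
    mean(transformed)
  } else if (any(mask)) {
    mean(transformed[mask])
  } else {
    0
  }
}
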