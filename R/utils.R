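# Internal helpers shared across the image operators.

# Round half away from zero (ImageJ-style), so masks are bit-stable across
# platforms; base round() is round-half-even.
round_half_up <- function(x) floor(x + 0.5)

clip255 <- function(x) pmin(pmax(x, 0), 255)

is_gray_image <- function(x) {
  is.matrix(x) && is.numeric(x) && !anyNA(x) &&
    all(x >= 0 & x <= 255) && all(x == floor(x))
}

assert_gray_image <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix of 8-bit gray levels", arg),
         call. = FALSE)
  }
  if (anyNA(x) || any(x < 0 | x > 255)) {
    stop(sprintf("`%s` has pixel values outside [0, 255]", arg), call. = FALSE)
  }
  invisible(x)
}

assert_mask <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.logical(x) || anyNA(x)) {
    stop(sprintf("`%s` must be a logical matrix with no missing values", arg),
         call. = FALSE)
  }
  invisible(x)
}

assert_same_dim <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop("image and mask dimensions differ", call. = FALSE)
  }
  invisible(NULL)
}

assert_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level < 0 || level > 255) {
    stop("threshold level must be a single value in [0, 255]", call. = FALSE)
  }
  invisible(level)
}

match_polarity <- function(polarity) {
  match.arg(polarity, c("dark_on_bright", "bright_on_dark"))
}

# Shift a matrix by (dr, dc), padding vacated cells with `fill`.
shift_matrix <- function(m, dr, dc, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dr
  src_c <- seq_len(w) - dc
  ok_r <- src_r >= 1L & src_r <= h
  ok_c <- src_c >= 1L & src_c <= w
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# Deterministic sub-seed derivation: keeps every generator phase on its own
# stream so adding an object type does not perturb earlier draws.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000000L) * 2L + as.integer(offset)
}
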