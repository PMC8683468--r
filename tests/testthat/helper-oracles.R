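# Brute-force reference implementations, deliberately naive (per-pixel
# loops, textbook formulas) and independent of the package's code paths.

random_gray <- function(h = 16, w = 16, seed = 1) {
  withr::with_seed(seed,
                   matrix(as.numeric(sample(0:255, h * w, replace = TRUE)),
                          h, w))
}

random_mask <- function(h = 16, w = 16, seed = 1, p = 0.4) {
  withr::with_seed(seed, matrix(runif(h * w) < p, h, w))
}

oracle_threshold <- function(img, level, polarity) {
  out <- matrix(NA, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      out[i, j] <- if (polarity == "dark_on_bright") img[i, j] <= level
      else img[i, j] >= level
    }
  }
  out
}

oracle_dilate <- function(mask, selem) {
  h <- nrow(mask); w <- ncol(mask)
  offs <- if (selem == "square3") expand.grid(dr = -1:1, dc = -1:1)
  else data.frame(dr = c(0, -1, 1, 0, 0), dc = c(0, 0, 0, -1, 1))
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      for (k in seq_len(nrow(offs))) {
        ii <- i + offs$dr[k]; jj <- j + offs$dc[k]
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && mask[ii, jj]) {
          out[i, j] <- TRUE
        }
      }
    }
  }
  out
}

oracle_median <- function(img, radius) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      rs <- max(1, i - radius):min(h, i + radius)
      cs <- max(1, j - radius):min(w, j + radius)
      out[i, j] <- floor(median(img[rs, cs]) + 0.5)
    }
  }
  out
}

oracle_mii <- function(transformed, mask, mode) {
  s <- 0; k <- 0
  for (i in seq_len(nrow(transformed))) {
    for (j in seq_len(ncol(transformed))) {
      if (mode == "whole_image" || mask[i, j]) {
        s <- s + transformed[i, j]
        k <- k + 1
      }
    }
  }
  if (k == 0) 0 else s / k
}

# grayscale dilation/erosion with a disc, looped over offsets
disc_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[g$dr^2 + g$dc^2 <= radius^2, ]
}

oracle_gray_dilate <- function(img, radius) {
  h <- nrow(img); w <- ncol(img)
  offs <- disc_offsets(radius)
  out <- matrix(-Inf, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      for (k in seq_len(nrow(offs))) {
        ii <- i + offs$dr[k]; jj <- j + offs$dc[k]
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
          out[i, j] <- max(out[i, j], img[ii, jj])
        }
      }
    }
  }
  out
}

oracle_gray_erode <- function(img, radius) {
  -oracle_gray_dilate(-img, radius)
}

# rolling-ball equivalent for a dark-on-bright image: the bright background
# is the grayscale closing; equivalently the opening of the inverted image,
# inverted back. Returns background - image, clipped.
oracle_subtract_background <- function(img, radius) {
  bg <- oracle_gray_erode(oracle_gray_dilate(img, radius), radius)
  pmin(pmax(bg - img, 0), 255)
}

oracle_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (i0 in seq_len(h)) {
    for (j0 in seq_len(w)) {
      if (mask[i0, j0] && lab[i0, j0] == 0L) {
        nxt <- nxt + 1L
        queue <- list(c(i0, j0))
        lab[i0, j0] <- nxt
        while (length(queue) > 0) {
          p <- queue[[1]]; queue <- queue[-1]
          for (di in -1:1) for (dj in -1:1) {
            ii <- p[1] + di; jj <- p[2] + dj
            if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
                mask[ii, jj] && lab[ii, jj] == 0L) {
              lab[ii, jj] <- nxt
              queue[[length(queue) + 1L]] <- c(ii, jj)
            }
          }
        }
      }
    }
  }
  lab
}

# simple-regression fit from the normal equations and textbook formulas
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b1 <- sxy / sxx
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  df <- n - 2
  mse <- sum(res^2) / df
  se1 <- sqrt(mse / sxx)
  se0 <- sqrt(mse * (1 / n + mean(x)^2 / sxx))
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / sst
  t0 <- b0 / se0; t1 <- b1 / se1
  f <- (sst - sum(res^2)) / 1 / mse
  tq <- qt(0.975, df)
  list(beta0 = b0, beta1 = b1, beta0_se = se0, beta1_se = se1,
       beta_std = b1 * sd(x) / sd(y),
       t_intercept = t0, t_slope = t1,
       p_intercept = 2 * pt(abs(t0), df, lower.tail = FALSE),
       p_slope = 2 * pt(abs(t1), df, lower.tail = FALSE),
       f_stat = f, p_f = pf(f, 1, df, lower.tail = FALSE),
       r_squared = r2, df_residual = df, residuals = res,
       ci95_beta0 = c(b0 - tq * se0, b0 + tq * se0),
       ci95_beta1 = c(b1 - tq * se1, b1 + tq * se1), n = n)
}

mask_f1 <- function(pred, truth) {
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

rel_err <- function(a, b) {
  abs(a - b) / pmax(abs(b), 1e-12)
}

default_dilution_groups <- c("2" = "2-5", "5" = "2-5", "10" = "10",
                             "100" = "10^2", "1000" = "10^3")
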