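# Seeded generators for synthetic bright-field micrographs of submerged
# fungal culture: dark branching hyphae, spores and pellets on a bright,
# unevenly illuminated background, with per-pixel ground truth. These stand
# in for real micrographs when exercising the transformation pipeline and
# the calibration statistics.

#' Specification of a synthetic micrograph scene
#'
#' Describes one simulated bright-field frame. Objects are dark on a bright
#' field (`foreground_level < background_level`), the background carries a
#' linear illumination gradient, and the rendered image receives additive
#' Gaussian noise plus dark impulse specks (non-mycelium debris) so the
#' median-filter and small-object-removal stages have something to do.
#'
#' @param width,height Frame size in pixels.
#' @param n_spores Number of spores (small ellipses, the early-culture
#'   morphology).
#' @param n_hyphae Number of hyphal trees (correlated random walks with
#'   per-step branching, the mid-culture morphology).
#' @param hypha_mean_length Mean walk length in steps (pixels).
#' @param branch_prob Per-step branching probability in `[0, 1]`.
#' @param hypha_width Filament thickness in pixels.
#' @param n_pellets Number of pellets (dense disk aggregates, the
#'   late-culture morphology).
#' @param pellet_radius Pellet radius in pixels.
#' @param background_level Medium gray level in `[0, 255]`.
#' @param illumination_gradient Gray-level span of the linear illumination
#'   ramp across the frame.
#' @param gaussian_noise_sd SD of additive Gaussian pixel noise.
#' @param salt_speck_count Number of dark impulse specks (area 1-4 px,
#'   *not* part of the ground truth).
#' @param foreground_level Mycelium gray level; must be below
#'   `background_level`.
#' @param seed Integer seed; identical specs render bit-identical scenes.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width = 128, height = 128,
                       n_spores = 8, n_hyphae = 12,
                       hypha_mean_length = 40, branch_prob = 0.08,
                       hypha_width = 2,
                       n_pellets = 0, pellet_radius = 8,
                       background_level = 200, illumination_gradient = 20,
                       gaussian_noise_sd = 3, salt_speck_count = 30,
                       foreground_level = 80, seed = 1) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_spores = as.integer(n_spores),
               n_hyphae = as.integer(n_hyphae),
               hypha_mean_length = hypha_mean_length,
               branch_prob = branch_prob, hypha_width = hypha_width,
               n_pellets = as.integer(n_pellets),
               pellet_radius = pellet_radius,
               background_level = background_level,
               illumination_gradient = illumination_gradient,
               gaussian_noise_sd = gaussian_noise_sd,
               salt_speck_count = as.integer(salt_speck_count),
               foreground_level = foreground_level,
               seed = as.integer(seed))
  if (spec$width < 1 || spec$height < 1) {
    stop("frame must be at least 1x1", call. = FALSE)
  }
  if (spec$foreground_level >= spec$background_level) {
    stop("foreground_level must be below background_level (dark-on-bright)",
         call. = FALSE)
  }
  counts <- c(spec$n_spores, spec$n_hyphae, spec$n_pellets,
              spec$salt_speck_count)
  if (any(counts < 0)) stop("object counts must be non-negative",
                            call. = FALSE)
  if (spec$branch_prob < 0 || spec$branch_prob > 1) {
    stop("branch_prob must be in [0, 1]", call. = FALSE)
  }
  structure(spec, class = "scene_spec")
}

# --- object rasterisers --------------------------------------------------
# All draw into `state`, an environment with `labels` (integer matrix, 0 =
# background) and `next_id`. Out-of-frame pixels are clipped silently.

stamp_pixels <- function(state, rows, cols, id) {
  ok <- rows >= 1L & rows <= nrow(state$labels) &
    cols >= 1L & cols <= ncol(state$labels)
  idx <- cbind(rows[ok], cols[ok])
  if (nrow(idx) > 0) state$labels[idx] <- id
  invisible(NULL)
}

draw_hypha <- function(state, spec) {
  id <- state$next_id
  state$next_id <- id + 1L
  h <- nrow(state$labels); w <- ncol(state$labels)
  thick <- expand.grid(dr = -1:1, dc = -1:1)
  rad <- spec$hypha_width / 2
  thick <- thick[thick$dr^2 + thick$dc^2 <= rad^2 + 0.26, ]
  # stack of pending branch tips: (row, col, angle, remaining steps)
  tips <- list(c(stats::runif(1, 1, h), stats::runif(1, 1, w),
                 stats::runif(1, 0, 2 * pi),
                 max(5, round(stats::rnorm(1, spec$hypha_mean_length,
                                           spec$hypha_mean_length / 4)))))
  branches <- 0L
  while (length(tips) > 0) {
    tip <- tips[[1]]; tips <- tips[-1]
    r <- tip[1]; c <- tip[2]; ang <- tip[3]; steps <- tip[4]
    while (steps > 0) {
      rr <- round(r) + thick$dr
      cc <- round(c) + thick$dc
      stamp_pixels(state, rr, cc, id)
      ang <- ang + stats::rnorm(1, 0, 0.25)
      r <- r + sin(ang); c <- c + cos(ang)
      steps <- steps - 1
      if (branches < 12L && steps > 3 &&
          stats::runif(1) < spec$branch_prob) {
        branches <- branches + 1L
        tips[[length(tips) + 1L]] <-
          c(r, c, ang + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.1),
            round(steps / 2))
      }
    }
  }
  invisible(NULL)
}

draw_spore <- function(state, spec) {
  id <- state$next_id
  state$next_id <- id + 1L
  h <- nrow(state$labels); w <- ncol(state$labels)
  r0 <- stats::runif(1, 1, h); c0 <- stats::runif(1, 1, w)
  a <- stats::runif(1, 1.5, 3); b <- stats::runif(1, 1.2, 2.2)
  th <- stats::runif(1, 0, pi)
  span <- ceiling(max(a, b))
  grid <- expand.grid(dr = -span:span, dc = -span:span)
  u <- grid$dr * cos(th) + grid$dc * sin(th)
  v <- -grid$dr * sin(th) + grid$dc * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  stamp_pixels(state, round(r0) + grid$dr[inside],
               round(c0) + grid$dc[inside], id)
  invisible(NULL)
}

draw_pellet <- function(state, spec) {
  id <- state$next_id
  state$next_id <- id + 1L
  h <- nrow(state$labels); w <- ncol(state$labels)
  r0 <- stats::runif(1, 1, h); c0 <- stats::runif(1, 1, w)
  rad <- spec$pellet_radius * stats::runif(1, 0.8, 1.2)
  span <- ceiling(rad)
  grid <- expand.grid(dr = -span:span, dc = -span:span)
  inside <- grid$dr^2 + grid$dc^2 <= rad^2
  stamp_pixels(state, round(r0) + grid$dr[inside],
               round(c0) + grid$dc[inside], id)
  invisible(NULL)
}

render_scene_image <- function(labels, spec, noise_seed) {
  h <- nrow(labels); w <- ncol(labels)
  ramp <- if (w > 1) (seq_len(w) - 1) / (w - 1) - 0.5 else 0
  img <- matrix(spec$background_level, h, w) +
    matrix(rep(ramp * spec$illumination_gradient, each = h), h, w)
  img[labels > 0L] <- spec$foreground_level
  withr::with_seed(noise_seed, {
    if (spec$gaussian_noise_sd > 0) {
      img <- img + stats::rnorm(h * w, 0, spec$gaussian_noise_sd)
    }
    if (spec$salt_speck_count > 0) {
      for (k in seq_len(spec$salt_speck_count)) {
        r0 <- sample.int(h, 1); c0 <- sample.int(w, 1)
        area <- sample.int(4L, 1)
        offs <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))[seq_len(area), ,
                                                          drop = FALSE]
        rr <- pmin(pmax(r0 + offs[, 1], 1L), h)
        cc <- pmin(pmax(c0 + offs[, 2], 1L), w)
        img[cbind(rr, cc)] <- 30
      }
    }
  })
  clip255(round_half_up(img))
}

#' Render a synthetic micrograph with ground truth
#'
#' Draws the scene described by a [scene_spec()]: hyphae as
#' correlated-random-walk polylines with per-step branching, spores as
#' ellipses, pellets as dense disks, all at `foreground_level` on a bright
#' ramped background, then adds Gaussian noise and dark impulse specks.
#' Ground truth (mask, per-object labels, pixel biomass) is recorded before
#' noise, so specks are *not* truth. Identical specs give bit-identical
#' scenes.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `mii_scene`: `image` (gray matrix), `truth_mask`
#'   (logical), `true_biomass_px`, `object_labels` (integer matrix) and
#'   `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  state <- new.env(parent = emptyenv())
  state$labels <- matrix(0L, spec$height, spec$width)
  state$next_id <- 1L
  withr::with_seed(derive_seed(spec$seed, 1L), {
    for (k in seq_len(spec$n_spores)) draw_spore(state, spec)
  })
  withr::with_seed(derive_seed(spec$seed, 2L), {
    for (k in seq_len(spec$n_hyphae)) draw_hypha(state, spec)
  })
  withr::with_seed(derive_seed(spec$seed, 3L), {
    for (k in seq_len(spec$n_pellets)) draw_pellet(state, spec)
  })
  finish_scene(state$labels, spec, derive_seed(spec$seed, 4L))
}

finish_scene <- function(labels, spec, noise_seed) {
  truth <- labels > 0L
  structure(
    list(image = render_scene_image(labels, spec, noise_seed),
         truth_mask = truth,
         true_biomass_px = sum(truth),
         object_labels = labels,
         spec = spec),
    class = "mii_scene"
  )
}

#' @export
print.mii_scene <- function(x, ...) {
  cat(sprintf("<mii_scene> %dx%d px | %d objects | true biomass %d px (%.2f%%)\n",
              nrow(x$image), ncol(x$image), max(x$object_labels),
              x$true_biomass_px,
              100 * x$true_biomass_px / length(x$image)))
  invisible(x)
}

#' Simulate a mycelial growth series
#'
#' Emulates culture-time morphology: spores dominate the first stages,
#' elongated branching hyphae appear from the second stage onward, and
#' pellets only in the final third. Stages are built cumulatively (each
#' stage adds objects to the previous one's ground truth), so true biomass
#' is non-decreasing by construction; each stage is re-rendered with its own
#' noise realisation.
#'
#' @param base A [scene_spec()] providing frame, morphology and noise
#'   parameters; its counts set the per-stage increments.
#' @param stages Number of stages (`>= 2`).
#' @return List of `mii_scene`, one per stage.
#' @export
generate_growth_series <- function(base, stages = 6) {
  stopifnot(inherits(base, "scene_spec"), stages >= 2)
  state <- new.env(parent = emptyenv())
  state$labels <- matrix(0L, base$height, base$width)
  state$next_id <- 1L
  scenes <- vector("list", stages)
  for (i in seq_len(stages)) {
    t_frac <- (i - 1) / (stages - 1)
    withr::with_seed(derive_seed(base$seed, 10L + i), {
      if (i == 1L) {
        for (k in seq_len(base$n_spores)) draw_spore(state, base)
      } else {
        if (t_frac <= 0.5) {
          for (k in seq_len(max(1L, base$n_spores %/% 2L))) {
            draw_spore(state, base)
          }
        }
        n_new <- max(1L, round(base$n_hyphae * t_frac / 2))
        for (k in seq_len(n_new)) draw_hypha(state, base)
        if (t_frac >= 2 / 3) {
          for (k in seq_len(max(1L, base$n_pellets))) {
            draw_pellet(state, base)
          }
        }
      }
    })
    scenes[[i]] <- finish_scene(state$labels, base,
                                derive_seed(base$seed, 100L + i))
  }
  scenes
}

#' Simulate a biomass density ramp
#'
#' A series of scenes with strictly increasing mycelial density, built
#' cumulatively by adding hyphae, for testing that MII rises with true
#' biomass.
#'
#' @param base A [scene_spec()].
#' @param n_scenes Number of scenes.
#' @param hyphae_per_step Hyphae added at each step.
#' @return List of `mii_scene` with non-decreasing (in practice strictly
#'   increasing) `true_biomass_px`.
#' @export
simulate_density_ramp <- function(base, n_scenes = 20, hyphae_per_step = 2) {
  stopifnot(inherits(base, "scene_spec"), n_scenes >= 2)
  state <- new.env(parent = emptyenv())
  state$labels <- matrix(0L, base$height, base$width)
  state$next_id <- 1L
  scenes <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    withr::with_seed(derive_seed(base$seed, 200L + i), {
      for (k in seq_len(hyphae_per_step)) draw_hypha(state, base)
    })
    scenes[[i]] <- finish_scene(state$labels, base,
                                derive_seed(base$seed, 300L + i))
  }
  scenes
}

#' Simulate MII-DCW calibration samples
#'
#' Draws MII values uniformly on `mii_range` and generates
#' `dcw = beta0 + beta1 * mii + N(0, noise_sd)`, truncated at zero. The
#' default coefficients are the fitted calibration of the fermentation
#' study this package reproduces, with `noise_sd` chosen so the realised
#' coefficient of determination sits near 0.94.
#'
#' @param n Number of samples (`>= 3`).
#' @param beta0 True intercept (mg/L).
#' @param beta1 True slope (mg/L per intensity unit).
#' @param mii_range Length-2 interval inside `[0, 255]`.
#' @param noise_sd SD of the Gaussian error (mg/L).
#' @param seed Integer seed.
#' @return A tibble `sample_id, mii, dcw` with attributes `true_beta0`,
#'   `true_beta1`, `noise_sd`, `seed`.
#' @export
simulate_calibration <- function(n = 30, beta0 = 70.095, beta1 = 5.982,
                                 mii_range = c(20, 70), noise_sd = 22,
                                 seed = 1) {
  stopifnot(n >= 3, length(mii_range) == 2,
            mii_range[1] >= 0, mii_range[2] <= 255,
            mii_range[1] < mii_range[2], noise_sd >= 0)
  withr::with_seed(as.integer(seed), {
    mii <- stats::runif(n, mii_range[1], mii_range[2])
    dcw <- pmax(0, beta0 + beta1 * mii + stats::rnorm(n, 0, noise_sd))
  })
  out <- tibble::tibble(
    sample_id = sprintf("synthetic_%03d", seq_len(n)),
    mii = mii, dcw = dcw
  )
  attr(out, "true_beta0") <- beta0
  attr(out, "true_beta1") <- beta1
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Simulate calibration samples across dilution factors
#'
#' Emulates the dilution experiment: a culture sample of concentration
#' `dcw` (drawn uniformly on `dcw_range`) is diluted `f`-fold before
#' imaging, so the expected number of objects in the frame is
#' `n_hyphae * (dcw / mean(dcw_range)) / f`. The realised count carries
#' counting (Poisson-like) dispersion `dispersion * sqrt(expected)`; the
#' measured frame coverage is converted to intensity and rescaled by `f` to
#' the undiluted-equivalent MII. Fewer objects per frame at high dilution
#' means larger relative counting error, so per-group calibration R^2
#' decreases with the dilution factor by construction; with
#' `dispersion = 0` the samples lie exactly on a line.
#'
#' @param base A [scene_spec()]; `n_hyphae` is the undiluted object count
#'   per frame, `hypha_mean_length * hypha_width` the pixels per object,
#'   and the frame size sets coverage.
#' @param factors Positive dilution factors.
#' @param replicates Samples per factor (`>= 3`).
#' @param dcw_range Range of true culture concentrations (mg/L).
#' @param gain Mean transformed-image gray level of a mycelium pixel,
#'   converting coverage to intensity.
#' @param dispersion Multiplier on the `sqrt(count)` counting noise; 0
#'   gives noiseless samples.
#' @param seed Integer seed.
#' @return A tibble `sample_id, mii, dcw, dilution_factor`.
#' @export
scene_to_dilution_samples <- function(base = scene_spec(width = 256,
                                                        height = 256,
                                                        n_hyphae = 240),
                                      factors = c(2, 5, 10, 100, 1000),
                                      replicates = 40,
                                      dcw_range = c(100, 500),
                                      gain = 150, dispersion = 1,
                                      seed = 1) {
  stopifnot(inherits(base, "scene_spec"), all(factors > 0), replicates >= 3)
  npx <- as.numeric(base$width) * base$height
  px_per_obj <- base$hypha_mean_length * base$hypha_width
  c_ref <- mean(dcw_range)
  rows <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(factors, function(f) {
      dcw <- stats::runif(replicates, dcw_range[1], dcw_range[2])
      lambda <- base$n_hyphae * (dcw / c_ref) / f
      count <- lambda + dispersion * sqrt(lambda) * stats::rnorm(replicates)
      count <- pmax(0, count)
      mii <- pmin(255, pmax(0, f * gain * count * px_per_obj / npx))
      tibble::tibble(dilution_factor = f, mii = mii, dcw = dcw)
    })
  })
  rows$sample_id <- sprintf("dil_%s_%02d",
                            format(rows$dilution_factor, trim = TRUE,
                                   scientific = FALSE),
                            stats::ave(seq_len(nrow(rows)),
                                       rows$dilution_factor,
                                       FUN = seq_along))
  dplyr::select(rows, "sample_id", "mii", "dcw", "dilution_factor")
}
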