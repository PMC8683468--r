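test_that("thresholding follows the boundary convention and polarity", {
  z <- matrix(0, 4, 4)
  expect_true(all(img_threshold(z, 154, "dark_on_bright")))
  # a pixel exactly at the level is foreground under <=
  expect_true(img_threshold(matrix(154, 1, 1), 154, "dark_on_bright")[1, 1])
  expect_true(img_threshold(matrix(154, 1, 1), 154, "bright_on_dark")[1, 1])
  expect_false(img_threshold(matrix(155, 1, 1), 154, "dark_on_bright")[1, 1])
  expect_error(img_threshold(z, 300), "\\[0, 255\\]")
})

test_that("thresholding a mask re-encoded as an image is idempotent", {
  for (s in 1:20) {
    m <- random_mask(16, 16, seed = s)
    as_img <- ifelse(m, 0, 255)
    expect_identical(img_threshold(as_img, 154, "dark_on_bright"), m)
  }
})

test_that("dilation matches brute force, is a superset, and handles edges", {
  one <- matrix(FALSE, 7, 7); one[4, 4] <- TRUE
  d <- dilate_mask(one, "square3")
  expect_identical(d, oracle_dilate(one, "square3"))
  expect_equal(sum(d), 9)
  expect_false(any(dilate_mask(matrix(FALSE, 5, 5))))
  for (s in 1:100) {
    m <- random_mask(16, 16, seed = s)
    for (se in c("square3", "cross3")) {
      got <- dilate_mask(m, se)
      expect_identical(got, oracle_dilate(m, se))
      expect_true(all(got[m])) # superset
    }
  }
})

test_that("median filter matches the truncated-window brute force", {
  const <- matrix(77, 10, 10)
  expect_identical(median_filter(const, 1), const)
  outl <- const; outl[5, 5] <- 255
  expect_identical(median_filter(outl, 1), const)
  for (s in 1:100) {
    img <- random_gray(16, 16, seed = s)
    r <- 1 + s %% 2
    expect_identical(median_filter(img, r), oracle_median(img, r))
  }
})

test_that("measure_mii equals brute-force accumulation and is bounded", {
  z <- matrix(0, 10, 10)
  expect_equal(measure_mii(z, z > 0), 0)
  half <- matrix(c(rep(100, 50), rep(0, 50)), 10, 10)
  expect_equal(measure_mii(half, half > 0, "whole_image"), 50)
  for (s in 1:100) {
    img <- random_gray(16, 16, seed = s)
    m <- random_mask(16, 16, seed = s + 1000)
    for (mode in c("whole_image", "mask_only")) {
      got <- measure_mii(img, m, mode)
      expect_equal(got, oracle_mii(img, m, mode))
      expect_gte(got, 0); expect_lte(got, 255)
    }
  }
  # empty mask in mask_only mode is defined as 0
  expect_equal(measure_mii(z, matrix(FALSE, 10, 10), "mask_only"), 0)
})

test_that("background subtraction removes flat and ramped backgrounds", {
  expect_true(all(subtract_background(matrix(180, 20, 20), 5) == 0))
  # bright field with one dark spot: residual only at the spot
  img <- matrix(200, 40, 40)
  img[20:22, 20:22] <- 60
  got <- subtract_background(img, 10)
  expect_identical(got, oracle_subtract_background(img, 10))
  expect_true(all(got[20:22, 20:22] > 0))
  spot <- matrix(FALSE, 40, 40); spot[20:22, 20:22] <- TRUE
  expect_true(all(got[!spot] == 0))
  # a featureless gentle illumination ramp (radius much larger than the
  # gray span) leaves at most 5 gray levels, and agrees with the oracle
  ramp <- matrix(rep(round(seq(196, 200, length.out = 40)), each = 40),
                 40, 40)
  expect_lte(max(subtract_background(ramp, 30)), 5)
  expect_identical(subtract_background(ramp, 30),
                   oracle_subtract_background(ramp, 30))
  # a steeper ramp is still removed exactly away from the frame border
  steep <- matrix(rep(round(seq(170, 210, length.out = 60)), each = 60),
                  60, 60)
  expect_true(all(subtract_background(steep, 12)[13:48, 13:48] == 0))
})

test_that("background subtraction agrees with the grayscale-morphology oracle", {
  for (s in 1:10) {
    img <- withr::with_seed(s, {
      base <- matrix(rep(seq(180, 220, length.out = 30), each = 30), 30, 30)
      base[sample(900, 40)] <- sample(40:120, 40, replace = TRUE)
      round(base)
    })
    expect_identical(subtract_background(img, 6),
                     oracle_subtract_background(img, 6))
  }
})

test_that("contrast enhancement stretches quantiles linearly", {
  full <- matrix(c(0, 255, 100, 30), 2, 2)
  expect_identical(enhance_contrast(full, 0), full)
  const <- matrix(99, 5, 5)
  expect_identical(enhance_contrast(const, 0.01), const)
  two <- matrix(c(50, 100), 4, 4)
  expect_identical(sort(unique(as.vector(enhance_contrast(two, 0)))),
                   c(0, 255))
  # hand-evaluated midpoint: (75 - 50) * 255 / 50 = 127.5 -> 128
  three <- matrix(c(50, 75, 100), 1, 3)
  expect_identical(enhance_contrast(three, 0)[1, ], c(0, 128, 255))
  expect_error(enhance_contrast(const, 0.6), "\\[0, 0.5\\)")
})

test_that("component labelling is 8-connected and matches flood fill", {
  diag2 <- matrix(FALSE, 4, 4); diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_equal(max(label_components(diag2)), 1)
  for (s in 1:50) {
    m <- random_mask(16, 16, seed = s, p = 0.3)
    got <- label_components(m)
    want <- oracle_label(m)
    # same partition: labels are a relabelling of each other
    expect_equal(max(got), max(want))
    expect_true(all((got > 0) == m))
    for (id in seq_len(max(want))) {
      expect_equal(length(unique(got[want == id])), 1)
    }
  }
})

test_that("noise-object removal drops sub-area components only", {
  m <- matrix(FALSE, 10, 10); m[5, 5] <- TRUE
  img <- matrix(200, 10, 10)
  expect_false(any(remove_noise_objects(m, img, min_area = 20)))
  # a component of exactly min_area pixels is retained
  m2 <- matrix(FALSE, 10, 10); m2[3:6, 3:7] <- TRUE # 20 px
  kept <- remove_noise_objects(m2, img, min_area = 20)
  attr(kept, "removed") <- NULL
  expect_identical(kept, m2)
  # result is always a subset
  for (s in 1:25) {
    m3 <- random_mask(16, 16, seed = s, p = 0.3)
    out <- remove_noise_objects(m3, random_gray(16, 16, seed = s),
                                min_area = 4)
    expect_true(all(m3[out]))
  }
})

test_that("speck removal keeps exactly the true hyphal components", {
  sc <- generate_scene(scene_spec(n_spores = 0, n_hyphae = 5,
                                  salt_speck_count = 30,
                                  gaussian_noise_sd = 0, seed = 21))
  # segment the noisy rendering: specks (area <= 4) enter the raw mask
  raw <- img_threshold(sc$image, 154, "dark_on_bright")
  expect_gt(max(label_components(raw)), max(sc$object_labels))
  cleaned <- remove_noise_objects(raw, sc$image, min_area = 20)
  # survivors are the hyphae: pixel-level agreement with the ground truth
  expect_equal(max(label_components(cleaned)),
               max(label_components(sc$truth_mask)))
  expect_gte(mask_f1(cleaned, sc$truth_mask), 0.99)
})
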