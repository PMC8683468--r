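test_that("a perfect line is recovered exactly", {
  d <- tibble::tibble(mii = 1:5, dcw = 2 * (1:5) + 1)
  fit <- fit_mii_calibration(d)
  expect_equal(fit$beta0, 1)
  expect_equal(fit$beta1, 2)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$residuals, rep(0, 5), tolerance = 1e-12)
  expect_equal(fit$df_residual, 3)
})

test_that("degenerate calibrations are refused", {
  expect_error(fit_mii_calibration(tibble::tibble(mii = c(1, 2),
                                                  dcw = c(1, 2))),
               "at least 3")
  expect_error(fit_mii_calibration(tibble::tibble(mii = rep(5, 4),
                                                  dcw = 1:4)),
               "degenerate")
})

test_that("all fit fields match the normal-equation oracle", {
  fields <- c("beta0", "beta1", "beta0_se", "beta1_se", "beta_std",
              "t_intercept", "t_slope", "p_intercept", "p_slope",
              "f_stat", "p_f", "r_squared", "ci95_beta0", "ci95_beta1")
  for (s in 1:30) {
    d <- withr::with_seed(s, tibble::tibble(
      mii = runif(12, 10, 90),
      dcw = 50 + 4 * runif(12, 10, 90) + rnorm(12, 0, 25)
    ))
    d$dcw <- pmax(d$dcw, 0)
    fit <- fit_mii_calibration(d)
    want <- oracle_ols(d$mii, d$dcw)
    for (f in fields) {
      expect_lt(max(rel_err(fit[[f]], want[[f]])), 1e-9, label = f)
    }
    expect_equal(fit$residuals, want$residuals, tolerance = 1e-9)
  }
})

test_that("the algebraic identities hold on every fit", {
  for (s in 1:50) {
    d <- simulate_calibration(n = 10 + s %% 20, noise_sd = 5 + s, seed = s)
    fit <- fit_mii_calibration(d)
    expect_lt(rel_err(fit$t_slope^2, fit$f_stat), 1e-9)
    expect_lt(rel_err(fit$beta_std^2, fit$r_squared), 1e-9)
    expect_equal(fit$beta_std, sign(fit$beta1) * sqrt(fit$r_squared))
    expect_equal(fit$df_residual, fit$n - 2)
  }
})

test_that("rescaling DCW scales coefficients but not t, F or R^2", {
  d <- simulate_calibration(n = 25, seed = 8)
  f1 <- fit_mii_calibration(d)
  f2 <- fit_mii_calibration(dplyr::mutate(d, dcw = dcw * 3.5))
  expect_equal(f2$beta0, 3.5 * f1$beta0)
  expect_equal(f2$beta1, 3.5 * f1$beta1)
  expect_equal(f2$beta1_se, 3.5 * f1$beta1_se)
  expect_equal(f2$t_slope, f1$t_slope)
  expect_equal(f2$f_stat, f1$f_stat)
  expect_equal(f2$r_squared, f1$r_squared)
})

test_that("prediction applies the calibration line and flags extrapolation", {
  d <- tibble::tibble(mii = c(10, 20, 30, 40), dcw = c(10, 20, 30, 40))
  ident <- fit_mii_calibration(d)
  expect_equal(predict_dcw(ident, 42), 42, tolerance = 1e-12)
  # intercept is the predicted DCW at zero intensity
  paper_like <- fit_mii_calibration(
    tibble::tibble(mii = c(10, 20, 30),
                   dcw = 70.095 + 5.982 * c(10, 20, 30))
  )
  expect_equal(predict_dcw(paper_like, 0), 70.095, tolerance = 1e-9)
  neg <- fit_mii_calibration(tibble::tibble(mii = c(10, 20, 30),
                                            dcw = c(30, 20, 10)))
  expect_warning(predict_dcw(neg, 250), "negative")
  # data-frame input gains predictions and, with actuals, accuracies
  out <- predict_dcw(ident, tibble::tibble(sample_id = "s", mii = 25,
                                           dcw = 20))
  expect_equal(out$predicted_dcw, 25, tolerance = 1e-12)
  expect_equal(out$accuracy_pct, 100 * 20 / 25, tolerance = 1e-12)
})

test_that("degree of accuracy reproduces the verification pairs", {
  expect_equal(round(accuracy_pct(270.1, 240.5), 1), 89.0)
  expect_equal(round(accuracy_pct(383.9, 409.9), 1), 93.7)
  expect_equal(accuracy_pct(123.4, 123.4), 100)
  expect_error(accuracy_pct(-1, 10), "positive")
})

test_that("accuracy is symmetric and never exceeds 100", {
  for (s in 1:50) {
    pa <- withr::with_seed(s, runif(2, 1, 1000))
    expect_equal(accuracy_pct(pa[1], pa[2]), accuracy_pct(pa[2], pa[1]))
    expect_lte(accuracy_pct(pa[1], pa[2]), 100)
    expect_gt(accuracy_pct(pa[1], pa[2]), 0)
  }
})

test_that("the verification table renders coefficients and stars", {
  d <- tibble::tibble(mii = 1:6, dcw = 3 * (1:6) + 2)
  vt <- verification_table(fit_mii_calibration(d))
  expect_equal(attr(vt, "r_squared"), 1)
  expect_equal(vt$coef, c(2, 3), tolerance = 1e-9)
  expect_equal(signif_stars(c(0.0005, 0.005, 0.03, 0.2)),
               c("***", "**", "*", ""))
  out <- capture.output(print(vt))
  expect_true(any(grepl("R\\^2 = 1.000", out)))
  # rendering reflects the fit's own fields
  fit2 <- fit_mii_calibration(simulate_calibration(n = 20, seed = 2))
  vt2 <- verification_table(fit2)
  expect_equal(vt2$coef, c(fit2$beta0, fit2$beta1))
  expect_equal(vt2$std_coef[2], fit2$beta_std)
  expect_equal(attr(vt2, "f_stat"), fit2$f_stat)
})

test_that("tidy and glance expose the fit as tibbles", {
  fit <- fit_mii_calibration(simulate_calibration(n = 20, seed = 5))
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "mii"))
  expect_equal(td$estimate, c(fit$beta0, fit$beta1))
  expect_equal(td$conf.low[2], fit$ci95_beta1[1])
  gl <- glance(fit)
  expect_equal(gl$r.squared, fit$r_squared)
  expect_equal(gl$nobs, 20)
})

test_that("dilution analysis reports per-group fits, tolerating small groups", {
  on_line <- tibble::tibble(mii = c(1:5, 1:2), dcw = c(2 * (1:5) + 3, 9, 9),
                            dilution_factor = c(rep(2, 5), rep(10, 2)))
  rep <- dilution_analysis(on_line)
  expect_equal(rep$r_squared[rep$dilution_label == "2"], 1)
  expect_true(is.na(rep$r_squared[rep$dilution_label == "10"]))
  # shuffling the sample order changes nothing
  d <- scene_to_dilution_samples(seed = 4)
  shuffled <- withr::with_seed(1, d[sample(nrow(d)), ])
  expect_equal(dilution_analysis(d, default_dilution_groups),
               dilution_analysis(shuffled, default_dilution_groups))
  # uncovered factors are an error
  expect_error(dilution_analysis(d, c("2" = "a")), "not covered")
})

test_that("plots build without error", {
  fit <- fit_mii_calibration(simulate_calibration(n = 20, seed = 3))
  expect_s3_class(autoplot(fit), "ggplot")
  rep <- dilution_analysis(scene_to_dilution_samples(seed = 1),
                           default_dilution_groups)
  expect_s3_class(autoplot(rep), "ggplot")
  sc <- generate_scene(scene_spec(seed = 2, width = 32, height = 32))
  expect_s3_class(plot(sc), "ggplot")
})
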