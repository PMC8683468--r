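#' Calibrate DCW against microscopic image intensity
#'
#' Fits the simple linear regression `dcw = beta0 + beta1 * mii + eps` by
#' ordinary least squares and returns the full verification panel:
#' unstandardized coefficients with standard errors, the standardized
#' coefficient (`beta1 * sd(mii)/sd(dcw)`, equal to Pearson's r in simple
#' regression), t statistics with two-sided p-values on `n - 2` df, the
#' ANOVA F statistic on `(1, n - 2)` df, the coefficient of determination
#' and 95% confidence intervals.
#'
#' @param data Data frame with one row per calibration sample.
#' @param mii,dcw Column names (tidy-eval) of the independent intensity
#'   variable and the dependent dry-cell-weight variable (mg/L).
#' @return An object of class `mii_fit` (see [tidy.mii_fit()],
#'   [glance.mii_fit()], [autoplot.mii_fit()], [verification_table()]).
#' @examples
#' d <- simulate_calibration(n = 30, seed = 1)
#' fit <- fit_mii_calibration(d)
#' glance(fit)
#' @export
fit_mii_calibration <- function(data, mii = mii, dcw = dcw) {
  x <- dplyr::pull(data, {{ mii }})
  y <- dplyr::pull(data, {{ dcw }})
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    stop("calibration needs at least 3 complete (mii, dcw) pairs",
         call. = FALSE)
  }
  if (length(unique(x)) < 2) {
    stop("degenerate design: all mii values are identical", call. = FALSE)
  }
  if (any(x < 0 | x > 255)) {
    stop("mii values must lie in [0, 255]", call. = FALSE)
  }
  if (any(y < 0)) stop("dcw must be non-negative", call. = FALSE)

  lmfit <- stats::lm(y ~ x)
  # noiseless verification lines are a supported input; the "essentially
  # perfect fit" warning is expected there, not actionable
  withCallingHandlers(
    {
      sm <- stats::summary.lm(lmfit)
      ci <- stats::confint(lmfit, level = 0.95)
    },
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- sm$coefficients
  fstat <- unname(sm$fstatistic)

  structure(
    list(
      beta0 = unname(co[1, 1]), beta0_se = unname(co[1, 2]),
      beta1 = unname(co[2, 1]), beta1_se = unname(co[2, 2]),
      beta_std = unname(co[2, 1]) * stats::sd(x) / stats::sd(y),
      t_intercept = unname(co[1, 3]), t_slope = unname(co[2, 3]),
      p_intercept = unname(co[1, 4]), p_slope = unname(co[2, 4]),
      f_stat = fstat[1],
      p_f = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
      r_squared = sm$r.squared,
      sigma = sm$sigma,
      df_residual = lmfit$df.residual,
      residuals = unname(stats::residuals(lmfit)),
      fitted = unname(stats::fitted(lmfit)),
      ci95_beta0 = unname(ci[1, ]), ci95_beta1 = unname(ci[2, ]),
      n = n,
      data = tibble::tibble(mii = x, dcw = y)
    ),
    class = "mii_fit"
  )
}

#' @export
print.mii_fit <- function(x, ...) {
  cat(sprintf("<mii_fit> DCW = %.3f + %.3f * MII   (n = %d)\n",
              x$beta0, x$beta1, x$n))
  cat(sprintf("  R^2 = %.3f | F(1, %d) = %.3f (p = %.3g) | residual SE = %.3f\n",
              x$r_squared, x$df_residual, x$f_stat, x$p_f, x$sigma))
  invisible(x)
}

#' Tidy the coefficients of an MII calibration fit
#'
#' @param x An `mii_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term: estimate, standard error,
#'   standardized estimate, t statistic, p-value and 95% CI bounds.
#' @export
tidy.mii_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "mii"),
    estimate = c(x$beta0, x$beta1),
    std.error = c(x$beta0_se, x$beta1_se),
    std.estimate = c(NA_real_, x$beta_std),
    statistic = c(x$t_intercept, x$t_slope),
    p.value = c(x$p_intercept, x$p_slope),
    conf.low = c(x$ci95_beta0[1], x$ci95_beta1[1]),
    conf.high = c(x$ci95_beta0[2], x$ci95_beta1[2])
  )
}

#' One-row model summary of an MII calibration fit
#'
#' @param x An `mii_fit`.
#' @param ... Unused.
#' @return A one-row tibble: R^2, residual sigma, F statistic with its
#'   p-value, residual df and n.
#' @export
glance.mii_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = x$sigma,
    statistic = x$f_stat,
    p.value = x$p_f,
    df.residual = x$df_residual,
    nobs = x$n
  )
}

#' Predict dry cell weight from MII
#'
#' Applies the calibration line `beta0 + beta1 * mii`. Negative predictions
#' (extrapolation below the calibrated range) are returned as-is with a
#' warning.
#'
#' @param fit An `mii_fit`.
#' @param mii Numeric vector of intensity values, or a data frame containing
#'   an `mii` column (and optionally `dcw`, in which case the per-sample
#'   [accuracy_pct()] is added).
#' @return Numeric vector for numeric input; for data-frame input a tibble
#'   with `predicted_dcw` (and `accuracy_pct` when actuals are present)
#'   appended.
#' @export
predict_dcw <- function(fit, mii) {
  stopifnot(inherits(fit, "mii_fit"))
  if (is.data.frame(mii)) {
    out <- tibble::as_tibble(mii)
    out$predicted_dcw <- predict_dcw(fit, out$mii)
    if ("dcw" %in% names(out)) {
      out$accuracy_pct <- accuracy_pct(out$predicted_dcw, out$dcw)
    }
    return(out)
  }
  pred <- fit$beta0 + fit$beta1 * mii
  if (any(pred < 0, na.rm = TRUE)) {
    warning("negative predicted DCW: MII outside the calibrated range",
            call. = FALSE)
  }
  pred
}

#' Degree of accuracy between predicted and measured DCW
#'
#' The symmetric agreement statistic `100 * min(predicted, actual) /
#' max(predicted, actual)` (percent): 100 for perfect agreement, identical
#' whichever argument is the prediction. Requires strictly positive inputs.
#'
#' @param predicted,actual Positive numerics (vectorised).
#' @return Percent agreement in `(0, 100]`.
#' @examples
#' accuracy_pct(270.1, 240.5) # 89.0
#' @export
accuracy_pct <- function(predicted, actual) {
  if (any(predicted <= 0 | actual <= 0, na.rm = TRUE)) {
    stop("accuracy_pct needs strictly positive predicted and actual values",
         call. = FALSE)
  }
  100 * pmin(predicted, actual) / pmax(predicted, actual)
}

signif_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Model verification table
#'
#' Renders the calibration fit as the standard SPSS-style simple-regression
#' verification panel: unstandardized coefficients with standard errors,
#' standardized coefficient, t with significance stars (* p < 0.05,
#' ** p < 0.01, *** p < 0.001), F and R^2.
#'
#' @param fit An `mii_fit`.
#' @return A tibble of class `mii_verification` with a print method drawing
#'   the panel layout.
#' @export
verification_table <- function(fit) {
  stopifnot(inherits(fit, "mii_fit"))
  tbl <- tibble::tibble(
    variable = c("(Constant)", "MII"),
    coef = c(fit$beta0, fit$beta1),
    std_error = c(fit$beta0_se, fit$beta1_se),
    std_coef = c(NA_real_, fit$beta_std),
    t = c(fit$t_intercept, fit$t_slope),
    t_stars = signif_stars(c(fit$p_intercept, fit$p_slope)),
    p = c(fit$p_intercept, fit$p_slope)
  )
  attr(tbl, "f_stat") <- fit$f_stat
  attr(tbl, "p_f") <- fit$p_f
  attr(tbl, "f_stars") <- signif_stars(fit$p_f)
  attr(tbl, "r_squared") <- fit$r_squared
  class(tbl) <- c("mii_verification", class(tbl))
  tbl
}

#' @export
print.mii_verification <- function(x, ...) {
  cat("Model verification (simple linear regression)\n")
  cat(sprintf("%-12s %12s %12s %12s %12s\n", "Variable", "B", "Std. error",
              "Beta", "t"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-12s %12.3f %12.3f %12s %12s\n",
                x$variable[i], x$coef[i], x$std_error[i],
                ifelse(is.na(x$std_coef[i]), "-",
                       sprintf("%.3f", x$std_coef[i])),
                paste0(sprintf("%.3f", x$t[i]), x$t_stars[i])))
  }
  cat(sprintf("F = %.3f%s | R^2 = %.3f\n", attr(x, "f_stat"),
              attr(x, "f_stars"), attr(x, "r_squared")))
  cat("*p < 0.05, **p < 0.01, ***p < 0.001\n")
  invisible(x)
}

#' Per-dilution-factor calibration quality
#'
#' Splits the calibration samples by dilution-factor group, fits a separate
#' MII-DCW regression in each, and reports the per-group coefficient of
#' determination. Groups with fewer than 3 samples (or no intensity spread)
#' are reported with `r_squared = NA` rather than raising an error.
#'
#' @param data Data frame with `mii`, `dcw` and `dilution_factor` columns.
#' @param groups Named character vector mapping dilution factors (names,
#'   e.g. `"2"`) to group labels; factors sharing a label are pooled into
#'   one regression. Defaults to one group per distinct factor.
#' @return A tibble of class `mii_dilution`: `dilution_label, n, r_squared`,
#'   ordered by the smallest factor in each group.
#' @export
dilution_analysis <- function(data, groups = NULL) {
  stopifnot(all(c("mii", "dcw", "dilution_factor") %in% names(data)))
  if (any(is.na(data$dilution_factor))) {
    stop("every sample needs a dilution_factor", call. = FALSE)
  }
  fac_chr <- format(data$dilution_factor, trim = TRUE, scientific = FALSE)
  if (is.null(groups)) {
    groups <- stats::setNames(unique(fac_chr), unique(fac_chr))
  }
  uncovered <- setdiff(unique(fac_chr), names(groups))
  if (length(uncovered) > 0) {
    stop(sprintf("dilution factor(s) not covered by grouping: %s",
                 paste(uncovered, collapse = ", ")), call. = FALSE)
  }
  out <- data |>
    dplyr::mutate(.label = unname(groups[fac_chr])) |>
    dplyr::group_by(.label) |>
    dplyr::summarise(
      .min_factor = min(.data$dilution_factor),
      n = dplyr::n(),
      r_squared = if (dplyr::n() >= 3 && length(unique(.data$mii)) >= 2) {
        tryCatch(
          fit_mii_calibration(dplyr::pick(dplyr::everything()))$r_squared,
          error = function(e) NA_real_
        )
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$.min_factor) |>
    dplyr::select(dilution_label = ".label", "n", "r_squared")
  class(out) <- c("mii_dilution", class(out))
  out
}
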