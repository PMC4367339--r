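#' Normalize binary-mixture samples to mixture-curve coordinates
#'
#' Maps each binary sample to the coordinate system the mixture curve lives
#' in: the mixing proportion of component a,
#' `x = lnOAV_a / (lnOAV_a + lnOAV_b)`, and the mean odor intensity per lnOAV
#' unit, `OI_m = OI / (lnOAV_a + lnOAV_b)`. Both components must be
#' supra-threshold (`lnOAV > 0`): per-unit averaging requires positive
#' amounts, and sub-threshold components are outside the model's domain.
#'
#' @param ln_oav_a,ln_oav_b numeric vectors, lnOAV of components a and b;
#'   strictly positive.
#' @param measured_oi numeric vector of panel-measured odor intensities.
#' @return data.frame with columns `x`, `oi_m` and `total_ln_oav`.
#' @examples
#' normalize_mixture(2.18, 0.56, 2.3)
#' @export
normalize_mixture <- function(ln_oav_a, ln_oav_b, measured_oi) {
  if (missing(measured_oi) || is.null(measured_oi) || anyNA(measured_oi)) {
    stop("`measured_oi` is required to normalize a sample", call. = FALSE)
  }
  if (!is.numeric(ln_oav_a) || !is.numeric(ln_oav_b) ||
      any(!is.finite(ln_oav_a)) || any(!is.finite(ln_oav_b))) {
    stop("`ln_oav_a` and `ln_oav_b` must be finite and numeric", call. = FALSE)
  }
  if (any(ln_oav_a <= 0) || any(ln_oav_b <= 0)) {
    stop("sub-threshold component: both `ln_oav_a` and `ln_oav_b` must be > 0",
         call. = FALSE)
  }
  total <- ln_oav_a + ln_oav_b
  data.frame(x = ln_oav_a / total, oi_m = measured_oi / total,
             total_ln_oav = total)
}

new_mixture_curve <- function(coefficients, n_points = NA_integer_,
                              residual_sd = NA_real_, confidence_level = 0.90,
                              xtx_inv = NULL, provenance = "fitted") {
  stopifnot(length(coefficients) == 3L, all(is.finite(coefficients)))
  structure(
    list(coefficients = stats::setNames(as.numeric(coefficients),
                                        c("a0", "a1", "a2")),
         n_points = as.integer(n_points), residual_sd = as.numeric(residual_sd),
         confidence_level = confidence_level, xtx_inv = xtx_inv,
         provenance = provenance),
    class = "mixture_curve"
  )
}

#' Fit the quadratic mixture curve
#'
#' Fits `OI_m = a0 + a1 x + a2 x^2` to normalized binary-mixture points by
#' unweighted ordinary least squares. The polynomial order is fixed at two:
#' the tangent-intercept decomposition needs a smooth curve and the
#' per-mixture data follow a "U" shape; no model selection is performed. The
#' fit stores what a pointwise mean-response confidence band needs (residual
#' standard deviation with n-3 denominator and the inverse cross-product of
#' the design matrix), evaluated by [confidence_band()].
#'
#' @param points data.frame with columns `x` and `oi_m`, as produced by
#'   [normalize_mixture()]; at least 4 points with at least 3 distinct `x`,
#'   all `x` within `[0, 1]`.
#' @param confidence_level confidence level of the band (default 0.90).
#' @return an object of class `mixture_curve`.
#' @examples
#' x <- seq(0.1, 0.9, by = 0.1)
#' fit_mixture_curve(data.frame(x = x, oi_m = 2.2 * x^2 - 2.2 * x + 1.32))
#' @export
fit_mixture_curve <- function(points, confidence_level = 0.90) {
  if (!is.data.frame(points) || !all(c("x", "oi_m") %in% names(points))) {
    stop("`points` must be a data.frame with columns `x` and `oi_m`", call. = FALSE)
  }
  x <- points$x
  y <- points$oi_m
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("`points` must be finite", call. = FALSE)
  }
  if (any(x < 0 | x > 1)) {
    stop("invalid point: mixing proportion `x` must lie within [0, 1]", call. = FALSE)
  }
  if (length(x) < 4L) {
    stop("need at least 4 points to fit the mixture curve", call. = FALSE)
  }
  if (length(unique(x)) < 3L) {
    stop("degenerate design: need at least 3 distinct `x` values", call. = FALSE)
  }
  if (!is.numeric(confidence_level) || confidence_level <= 0 || confidence_level >= 1) {
    stop("`confidence_level` must be a fraction in (0, 1)", call. = FALSE)
  }
  fit <- stats::lm(y ~ x + I(x^2))
  n <- length(x)
  rsd <- sqrt(sum(stats::residuals(fit)^2) / (n - 3L))
  X <- cbind(1, x, x^2)
  new_mixture_curve(unname(stats::coef(fit)), n_points = n, residual_sd = rsd,
                    confidence_level = confidence_level,
                    xtx_inv = solve(crossprod(X)), provenance = "fitted")
}

#' The pooled extended mixture model for aldehydes
#'
#' Binary mixtures of short-chain aldehydes with similar odor type share one
#' mixture curve; pooling their samples gives the fixed quadratic
#' `OI_m = 2.20 x^2 - 2.20 x + 1.32`, symmetric about `x = 0.5`. The returned
#' model is flagged `literature` provenance: it carries no residual
#' information, so no confidence band can be evaluated from it.
#'
#' @return a `mixture_curve` with coefficients `(a0, a1, a2) = (1.32, -2.20,
#'   2.20)`.
#' @examples
#' curve_value(extended_model(), 0.3)  # ~0.86
#' @export
extended_model <- function() {
  new_mixture_curve(c(1.32, -2.20, 2.20), provenance = "literature")
}

#' @export
print.mixture_curve <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("<mixture_curve> OI_m = %.4g*x^2 %+.4g*x %+.4g  [%s]\n",
              cf["a2"], cf["a1"], cf["a0"], x$provenance))
  if (!is.na(x$n_points)) {
    cat(sprintf("  n = %d, residual sd = %.4g, confidence level = %.2f\n",
                x$n_points, x$residual_sd, x$confidence_level))
  }
  invisible(x)
}

#' Evaluate the mixture curve and its derivative
#'
#' @param model a `mixture_curve`.
#' @param x mixing proportions; vectorized.
#' @return numeric vector: `curve_value()` gives `f(x)`, `curve_slope()`
#'   gives `f'(x)`.
#' @export
curve_value <- function(model, x) {
  stopifnot(inherits(model, "mixture_curve"))
  cf <- model$coefficients
  unname(cf["a0"] + cf["a1"] * x + cf["a2"] * x^2)
}

#' @rdname curve_value
#' @export
curve_slope <- function(model, x) {
  stopifnot(inherits(model, "mixture_curve"))
  cf <- model$coefficients
  unname(cf["a1"] + 2 * cf["a2"] * x)
}

#' Pointwise confidence band of the fitted mixture curve
#'
#' Mean-response band at the model's stored confidence level: Student-t
#' quantile with n-3 degrees of freedom times the standard error of the
#' fitted mean at each `x`.
#'
#' @param model a fitted `mixture_curve` (literature-fixed models carry no
#'   residual information and are rejected).
#' @param x mixing proportions at which to evaluate the band.
#' @param level optional override of the stored confidence level.
#' @return data.frame with columns `x`, `fit`, `lwr`, `upr`.
#' @export
confidence_band <- function(model, x, level = model$confidence_level) {
  stopifnot(inherits(model, "mixture_curve"))
  if (is.null(model$xtx_inv) || is.na(model$residual_sd)) {
    stop("confidence band unavailable: model has no residual information ",
         "(literature-fixed coefficients)", call. = FALSE)
  }
  X0 <- cbind(1, x, x^2)
  se <- model$residual_sd * sqrt(rowSums((X0 %*% model$xtx_inv) * X0))
  tq <- stats::qt(1 - (1 - level) / 2, df = model$n_points - 3L)
  fit <- curve_value(model, x)
  data.frame(x = x, fit = fit, lwr = fit - tq * se, upr = fit + tq * se)
}

#' Confidence intervals for mixture-curve coefficients
#'
#' @param object a fitted `mixture_curve`.
#' @param parm ignored; all three coefficients are returned.
#' @param level confidence level.
#' @param ... unused.
#' @return 3 x 2 matrix of lower and upper bounds for `a0`, `a1`, `a2`.
#' @export
confint.mixture_curve <- function(object, parm, level = 0.90, ...) {
  if (is.null(object$xtx_inv) || is.na(object$residual_sd)) {
    stop("confidence intervals unavailable: model has no residual information",
         call. = FALSE)
  }
  se <- object$residual_sd * sqrt(diag(object$xtx_inv))
  tq <- stats::qt(1 - (1 - level) / 2, df = object$n_points - 3L)
  cf <- object$coefficients
  out <- cbind(cf - tq * se, cf + tq * se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}

#' Tangent-intercept partial odor intensities
#'
#' Decomposes the per-unit mixture intensity at mixing proportion `x` into
#' per-component contributions by the tangent-intercept construction of
#' partial molar quantities: the tangent to the mixture curve at
#' `(x, f(x))` is evaluated at `x = 1` (component a's partial intensity,
#' `OI_a,m = (1 - x) f'(x) + f(x)`) and at `x = 0` (component b's,
#' `OI_b,m = -x f'(x) + f(x)`). Values below a component's unmixed per-unit
#' response indicate hypo-additive (masking) interaction and may be negative;
#' they are reported as-is.
#'
#' The construction needs `0 < x < 1`. Mixing proportions outside the
#' calibrated design range `[0.1, 0.9]` raise an
#' `odorblend_extrapolation` warning: a component holding under 20% of the
#' total lnOAV barely influences mixture intensity and such samples were not
#' part of the calibration.
#'
#' @param model a `mixture_curve`.
#' @param x mixing proportion(s) of component a, in `(0, 1)`.
#' @return data.frame with columns `x`, `oi_a_m`, `oi_b_m`.
#' @examples
#' partial_intensities(extended_model(), 0.3)  # ~ (0.24, 1.12)
#' @export
partial_intensities <- function(model, x) {
  stopifnot(inherits(model, "mixture_curve"))
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be finite and numeric", call. = FALSE)
  }
  if (any(x <= 0 | x >= 1)) {
    stop("out of domain: mixing proportion `x` must lie strictly within (0, 1)",
         call. = FALSE)
  }
  if (any(x < 0.1 - 1e-12 | x > 0.9 + 1e-12)) {
    odorblend_warning(
      "mixing proportion outside the calibrated design range [0.1, 0.9]",
      "odorblend_extrapolation"
    )
  }
  yv <- curve_value(model, x)
  sl <- curve_slope(model, x)
  data.frame(x = x, oi_a_m = (1 - x) * sl + yv, oi_b_m = -x * sl + yv,
             row.names = NULL)
}

#' Predict the odor intensity of a binary mixture
#'
#' From the two components' lnOAV values, computes the mixing proportion,
#' the tangent-intercept partial intensities, and the predicted mixture odor
#' intensity as the amount-weighted sum
#' `OI = OI_a,m * lnOAV_a + OI_b,m * lnOAV_b`. Algebraically this equals
#' `(lnOAV_a + lnOAV_b) * f(x)`; both routes are computed and cross-checked
#' internally.
#'
#' @param model a `mixture_curve`.
#' @param ln_oav_a,ln_oav_b numeric vectors of component lnOAVs, strictly
#'   positive.
#' @return data.frame with columns `ln_oav_a`, `ln_oav_b`, `x`, `oi_a_m`,
#'   `oi_b_m`, `oi_pre`.
#' @examples
#' predict_oi(extended_model(), 2.18, 0.56)
#' @export
predict_oi <- function(model, ln_oav_a, ln_oav_b) {
  stopifnot(inherits(model, "mixture_curve"))
  if (!is.numeric(ln_oav_a) || !is.numeric(ln_oav_b) ||
      any(!is.finite(ln_oav_a)) || any(!is.finite(ln_oav_b))) {
    stop("`ln_oav_a` and `ln_oav_b` must be finite and numeric", call. = FALSE)
  }
  if (any(ln_oav_a <= 0) || any(ln_oav_b <= 0)) {
    stop("sub-threshold component: both `ln_oav_a` and `ln_oav_b` must be > 0",
         call. = FALSE)
  }
  total <- ln_oav_a + ln_oav_b
  x <- ln_oav_a / total
  p <- partial_intensities(model, x)
  oi_pre <- p$oi_a_m * ln_oav_a + p$oi_b_m * ln_oav_b
  direct <- total * curve_value(model, x)
  if (max(abs(oi_pre - direct) / pmax(1, abs(direct))) > 1e-9) {
    stop("internal inconsistency: tangent-sum and direct-curve predictions disagree")
  }
  data.frame(ln_oav_a = ln_oav_a, ln_oav_b = ln_oav_b, x = x,
             oi_a_m = p$oi_a_m, oi_b_m = p$oi_b_m, oi_pre = oi_pre,
             row.names = NULL)
}

#' Evaluate predictive performance against panel measurements
#'
#' For each record forms the predictive coefficient `OI_pre / OI_mea` and
#' averages it arithmetically. In the default `"report"` mode predictions are
#' first taken to report precision with [round_oi_report()] (one decimal via a
#' two-decimal intermediate), the convention under which published validation
#' tables were summarized; `"raw"` uses full-precision predictions.
#'
#' @param oi_pre numeric vector of predicted odor intensities, or the
#'   data.frame returned by [predict_oi()] (its `oi_pre` column is used).
#' @param oi_mea numeric vector of measured odor intensities; records with
#'   missing or non-positive values are excluded with an
#'   `odorblend_excluded_record` warning.
#' @param rounding `"report"` (default) or `"raw"`.
#' @return an object of class `oi_evaluation`: list with `records`
#'   (data.frame of `oi_pre`, `oi_pre_reported`, `oi_mea`, `ratio`),
#'   `mean_ratio`, `rounding`, `n_used`, `n_excluded`.
#' @examples
#' ev <- evaluate_predictions(c(2.6, 4.6), c(2.3, 4.3))
#' ev$mean_ratio
#' @export
evaluate_predictions <- function(oi_pre, oi_mea, rounding = c("report", "raw")) {
  rounding <- match.arg(rounding)
  if (is.data.frame(oi_pre)) {
    if (missing(oi_mea) && "oi_mea" %in% names(oi_pre)) oi_mea <- oi_pre$oi_mea
    oi_pre <- oi_pre$oi_pre
  }
  if (length(oi_pre) != length(oi_mea)) {
    stop("`oi_pre` and `oi_mea` must have equal length", call. = FALSE)
  }
  bad <- !is.finite(oi_mea) | oi_mea <= 0
  if (any(bad)) {
    odorblend_warning(
      sprintf("excluded %d record(s) with missing or non-positive measured OI",
              sum(bad)),
      "odorblend_excluded_record"
    )
  }
  keep_pre <- oi_pre[!bad]
  keep_mea <- oi_mea[!bad]
  reported <- round_oi_report(keep_pre)
  ratio <- if (rounding == "report") reported / keep_mea else keep_pre / keep_mea
  structure(
    list(records = data.frame(oi_pre = keep_pre, oi_pre_reported = reported,
                              oi_mea = keep_mea, ratio = ratio),
         mean_ratio = mean(ratio), rounding = rounding,
         n_used = length(ratio), n_excluded = sum(bad)),
    class = "oi_evaluation"
  )
}

#' @export
print.oi_evaluation <- function(x, ...) {
  cat(sprintf("<oi_evaluation> mean predictive coefficient = %.4f (%s mode, n = %d",
              x$mean_ratio, x$rounding, x$n_used))
  if (x$n_excluded > 0) cat(sprintf(", %d excluded", x$n_excluded))
  cat(")\n")
  invisible(x)
}

#' Stratify binary-mixture samples by odor-intensity level
#'
#' Splits samples into the low/middle/high design bands of [oi_level()].
#' Used to check that the fitted mixture curve does not depend on sample
#' concentration level, only on mixing ratio.
#'
#' @param samples data.frame with a `measured_oi` column.
#' @return named list of data.frames keyed `low`, `middle`, `high` (empty
#'   groups are kept).
#' @export
stratify_by_level <- function(samples) {
  if (!is.data.frame(samples) || !"measured_oi" %in% names(samples)) {
    stop("`samples` must be a data.frame with a `measured_oi` column", call. = FALSE)
  }
  if (nrow(samples) == 0L) {
    lev <- factor(character(), levels = c("low", "middle", "high"))
  } else {
    if (anyNA(samples$measured_oi)) {
      stop("`measured_oi` must be present on all samples", call. = FALSE)
    }
    lev <- oi_level(samples$measured_oi)
  }
  split(samples, lev, drop = FALSE)
}
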