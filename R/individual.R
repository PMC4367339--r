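#' Fit the linear odor-intensity response of individual odorants
#'
#' For a single (supra-threshold) odorant, perceived odor intensity grows
#' linearly in the natural logarithm of its odor activity value. This fits
#' that line by ordinary least squares. Points from several odorants may be
#' pooled in one call if they are believed to share a response (odorants of
#' the same chemical group and similar odor type often do); pooling is the
#' caller's choice, not enforced.
#'
#' @param ln_oav numeric vector of lnOAV values (at least two distinct).
#' @param oi numeric vector of measured odor intensities (panel means, OIRS).
#' @return an object of class `linear_response` with elements `slope`,
#'   `intercept`, `n_points`, `residual_sd` (n-2 denominator; `NA` when
#'   n = 2), and `ln_oav_range`.
#' @examples
#' fit <- fit_linear_response(c(0, 1, 2, 3), c(0.5, 1.7, 2.9, 4.1))
#' fit$slope
#' @export
fit_linear_response <- function(ln_oav, oi) {
  if (!is.numeric(ln_oav) || !is.numeric(oi) || length(ln_oav) != length(oi)) {
    stop("`ln_oav` and `oi` must be numeric vectors of equal length", call. = FALSE)
  }
  if (any(!is.finite(ln_oav)) || any(!is.finite(oi))) {
    stop("`ln_oav` and `oi` must be finite", call. = FALSE)
  }
  n <- length(ln_oav)
  if (n < 2L || length(unique(ln_oav)) < 2L) {
    stop("degenerate design: need at least 2 points with distinct `ln_oav`",
         call. = FALSE)
  }
  fit <- stats::lm(oi ~ ln_oav)
  cf <- unname(stats::coef(fit))
  rsd <- if (n > 2L) sqrt(sum(stats::residuals(fit)^2) / (n - 2L)) else NA_real_
  out <- structure(
    list(slope = cf[2], intercept = cf[1], n_points = n,
         residual_sd = rsd, ln_oav_range = range(ln_oav)),
    class = "linear_response"
  )
  ends <- predict_individual_oi(out, out$ln_oav_range)
  if (any(ends < 0 | ends > 8)) {
    odorblend_warning(
      "fitted response leaves [0, 8] over the calibrated lnOAV range",
      "odorblend_off_scale_fit"
    )
  }
  out
}

#' @export
print.linear_response <- function(x, ...) {
  cat(sprintf("<linear_response> OI = %.4g * lnOAV + %.4g\n", x$slope, x$intercept))
  cat(sprintf("  n = %d, residual sd = %s, calibrated lnOAV range [%.3g, %.3g]\n",
              x$n_points,
              if (is.na(x$residual_sd)) "NA" else sprintf("%.3g", x$residual_sd),
              x$ln_oav_range[1], x$ln_oav_range[2]))
  invisible(x)
}

#' Predict individual-odorant odor intensity
#'
#' Evaluates a fitted [fit_linear_response()] line. Values are returned
#' unclamped; the logical attribute `on_scale` flags which predictions lie on
#' the rating scale `[1, 8]`.
#'
#' @param model a `linear_response` object.
#' @param ln_oav numeric vector of lnOAV values.
#' @return numeric vector of predicted odor intensities with attribute
#'   `on_scale`.
#' @export
predict_individual_oi <- function(model, ln_oav) {
  stopifnot(inherits(model, "linear_response"))
  if (!is.numeric(ln_oav) || any(!is.finite(ln_oav))) {
    stop("`ln_oav` must be finite and numeric", call. = FALSE)
  }
  out <- model$slope * ln_oav + model$intercept
  attr(out, "on_scale") <- out >= 1 & out <= 8
  out
}
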