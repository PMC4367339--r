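#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used by
#' printed sensory tables (base [round()] rounds half to even). A small guard
#' (1e-9 at the scaled magnitude) absorbs binary floating-point representation
#' error of decimal inputs.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(c(0.245, -0.245, 2.5), c(2, 2, 0))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Report-precision rounding of odor intensity
#'
#' Rounds a predicted odor intensity the way the published validation table
#' was produced: first to two decimals, then to one, both half away from zero.
#' The intermediate step matters: a value such as 3.3495 prints as 3.4 under
#' this convention but as 3.3 under direct one-decimal rounding, and only the
#' sequential convention reproduces the published per-sample predictions and
#' their section means.
#'
#' @param x numeric vector of odor intensities (OIRS units).
#' @return `x` at report precision (one decimal).
#' @seealso [round_half_up()], [evaluate_predictions()]
#' @export
round_oi_report <- function(x) {
  round_half_up(round_half_up(x, 2), 1)
}

#' Round ratings to the half-step OIRS grid
#'
#' Maps a continuous value onto the half-step rating grid (1.0, 1.5, ..., 8.0
#' by default) and clamps to the scale bounds. Exact ties (values ending in
#' .25 or .75) are rounded away from the nearer scale bound, i.e. toward the
#' scale midpoint.
#'
#' @param x numeric vector.
#' @param bounds length-2 numeric, scale bounds (default `c(1, 8)`).
#' @return values on the half-step grid within `bounds`.
#' @export
round_half_step <- function(x, bounds = c(1, 8)) {
  r <- 2 * x
  fl <- floor(r)
  tie <- abs(r - fl - 0.5) < 1e-9
  midpoint <- mean(bounds)
  out <- ifelse(tie, ifelse(x <= midpoint, fl + 1, fl) / 2, round(r) / 2)
  pmin(pmax(out, bounds[1]), bounds[2])
}

# shared argument checks; error messages name the offending field
check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite and numeric", name), call. = FALSE)
  }
  if (strict && any(x <= 0)) {
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  }
  if (!strict && any(x < 0)) {
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  }
  invisible(x)
}

odorblend_warning <- function(message, class) {
  warning(warningCondition(message, class = c(class, "odorblend_warning")))
}
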