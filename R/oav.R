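#' Define an odorant
#'
#' An odorant is a chemical species with an odor detection threshold, the
#' reference concentration that all odor activity values are computed
#' against. Thresholds are mass concentrations in mg/m3 (gas phase).
#'
#' @param name character, odorant name (e.g. `"propionaldehyde"`).
#' @param threshold_mg_m3 odor detection threshold in mg/m3; strictly positive.
#' @param cas optional CAS registry number.
#' @param molecular_weight optional molecular weight in g/mol, needed only for
#'   unit conversion to volume mixing ratios.
#' @return an object of class `odorant`.
#' @examples
#' pa <- odorant("propionaldehyde", 40.6e-3, cas = "123-38-6",
#'               molecular_weight = 58.08)
#' compute_oav(0.406, pa)
#' @export
odorant <- function(name, threshold_mg_m3, cas = NA_character_,
                    molecular_weight = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_positive(threshold_mg_m3, "threshold_mg_m3")
  stopifnot(length(threshold_mg_m3) == 1L)
  if (!is.na(molecular_weight)) {
    check_positive(molecular_weight, "molecular_weight")
  }
  structure(
    list(name = name, cas = as.character(cas),
         molecular_weight = as.numeric(molecular_weight),
         threshold_mg_m3 = as.numeric(threshold_mg_m3)),
    class = "odorant"
  )
}

#' @export
print.odorant <- function(x, ...) {
  cat(sprintf("<odorant> %s (CAS %s)\n", x$name,
              if (is.na(x$cas)) "unknown" else x$cas))
  cat(sprintf("  threshold: %g mg/m3", x$threshold_mg_m3))
  if (!is.na(x$molecular_weight)) {
    cat(sprintf(" | MW: %g g/mol", x$molecular_weight))
  }
  cat("\n")
  invisible(x)
}

#' Odor activity value
#'
#' The odor activity value (OAV) of an exposure is its concentration divided
#' by the odorant's detection threshold; it is numerically equivalent to the
#' dilution-to-threshold (D/T) ratio. The natural logarithm `lnOAV` is the
#' "amount" variable of the mixture model (see [normalize_mixture()]).
#'
#' @param concentration_mg_m3 gas-phase concentration in mg/m3, strictly
#'   positive; vectorized.
#' @param odorant an [odorant()] object.
#' @return `compute_oav()`: the dimensionless OAV; `compute_ln_oav()`: its
#'   natural logarithm.
#' @examples
#' pa <- odorant("propionaldehyde", 40.6e-3)
#' compute_oav(0.406, pa)     # 10
#' compute_ln_oav(0.406, pa)  # log(10)
#' @export
compute_oav <- function(concentration_mg_m3, odorant) {
  stopifnot(inherits(odorant, "odorant"))
  check_positive(concentration_mg_m3, "concentration_mg_m3")
  concentration_mg_m3 / odorant$threshold_mg_m3
}

#' @rdname compute_oav
#' @export
compute_ln_oav <- function(concentration_mg_m3, odorant) {
  log(compute_oav(concentration_mg_m3, odorant))
}

# molar volume of an ideal gas, L/mol
molar_volume_l <- function(temperature_c, pressure_kpa) {
  kelvin <- temperature_c + 273.15
  if (kelvin <= 0) stop("`temperature_c` must be above absolute zero", call. = FALSE)
  check_positive(pressure_kpa, "pressure_kpa")
  8.314462618 * kelvin / pressure_kpa
}

#' Convert between mass concentration and volume mixing ratio
#'
#' Ideal-gas conversion between mg/m3 and ppb (nmol/mol). The default
#' reference state of 20 degrees C and 101.325 kPa (molar volume about
#' 24.055 L/mol) reproduces the paired mg/m3 and ppb values of the packaged
#' aldehyde threshold table.
#'
#' @param concentration_mg_m3,concentration_ppb concentration to convert;
#'   non-negative, vectorized.
#' @param molecular_weight molecular weight in g/mol.
#' @param temperature_c reference temperature, degrees Celsius.
#' @param pressure_kpa reference pressure, kPa.
#' @return the converted concentration.
#' @examples
#' mgm3_to_ppb(40.6e-3, 58.08)  # ~16.8
#' @export
mgm3_to_ppb <- function(concentration_mg_m3, molecular_weight,
                        temperature_c = 20, pressure_kpa = 101.325) {
  if (length(molecular_weight) == 0L || anyNA(molecular_weight)) {
    stop("conversion to ppb requires `molecular_weight`", call. = FALSE)
  }
  check_positive(molecular_weight, "molecular_weight")
  check_positive(concentration_mg_m3, "concentration_mg_m3", strict = FALSE)
  vm <- molar_volume_l(temperature_c, pressure_kpa)
  # mg/m3 -> ug/m3 -> umol/m3 -> uL/m3 == ppb
  concentration_mg_m3 * 1000 / molecular_weight * vm
}

#' @rdname mgm3_to_ppb
#' @export
ppb_to_mgm3 <- function(concentration_ppb, molecular_weight,
                        temperature_c = 20, pressure_kpa = 101.325) {
  if (length(molecular_weight) == 0L || anyNA(molecular_weight)) {
    stop("conversion from ppb requires `molecular_weight`", call. = FALSE)
  }
  check_positive(molecular_weight, "molecular_weight")
  check_positive(concentration_ppb, "concentration_ppb", strict = FALSE)
  vm <- molar_volume_l(temperature_c, pressure_kpa)
  concentration_ppb / vm * molecular_weight / 1000
}

#' Classify measured odor intensity into level bands
#'
#' Partitions the OIRS range into the three design bands used to stratify
#' binary-mixture samples: low `[1, 2.5)`, middle `[2.5, 4.5)` and high
#' `[4.5, 8]`. Bands are half-open with the boundary assigned to the upper
#' band, so every value in `[1, 8]` receives exactly one label. Samples are
#' designed below 7.0 OIRS; values above 7 are still classified `high` but
#' raise an `odorblend_above_design_range` warning.
#'
#' @param measured_oi numeric vector of panel-mean odor intensities in `[1, 8]`.
#' @return factor with levels `low`, `middle`, `high`.
#' @examples
#' oi_level(c(1.7, 2.5, 4.8))
#' @export
oi_level <- function(measured_oi) {
  if (!is.numeric(measured_oi) || any(!is.finite(measured_oi))) {
    stop("`measured_oi` must be finite and numeric", call. = FALSE)
  }
  if (any(measured_oi < 1 | measured_oi > 8)) {
    stop("`measured_oi` must lie on the OIRS range [1, 8]", call. = FALSE)
  }
  if (any(measured_oi > 7)) {
    odorblend_warning(
      "measured_oi above 7.0 is outside the sample design range; classified high",
      "odorblend_above_design_range"
    )
  }
  lab <- ifelse(measured_oi < 2.5, "low",
                ifelse(measured_oi < 4.5, "middle", "high"))
  factor(lab, levels = c("low", "middle", "high"))
}
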