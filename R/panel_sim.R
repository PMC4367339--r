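#' Sensory-panel configuration
#'
#' Describes a simulated OIRS panel: number of assessors and the standard
#' deviation of each assessor's rating error around the true intensity.
#' Noise is additive Gaussian applied before half-step grid rounding; the
#' default sd of 0.2 OIRS units places about 95% of 8-assessor panel means
#' within the +/- 0.4 fluctuation envelope observed in repeated ratings.
#' `rating_sd` may also be a function of the true intensity, to emulate the
#' poorer precision of weak samples.
#'
#' @param n_assessors number of assessors (default 8).
#' @param rating_sd non-negative numeric, or a function `true_oi -> sd`.
#' @param scale_bounds rating-scale bounds (default `c(1, 8)`).
#' @return an object of class `panel_config`.
#' @export
panel_config <- function(n_assessors = 8, rating_sd = 0.2,
                         scale_bounds = c(1, 8)) {
  stopifnot(is.numeric(n_assessors), length(n_assessors) == 1L, n_assessors >= 1)
  if (!is.function(rating_sd)) {
    stopifnot(is.numeric(rating_sd), length(rating_sd) == 1L, rating_sd >= 0)
  }
  stopifnot(is.numeric(scale_bounds), length(scale_bounds) == 2L,
            scale_bounds[1] < scale_bounds[2])
  structure(
    list(n_assessors = as.integer(n_assessors), rating_sd = rating_sd,
         scale_bounds = scale_bounds),
    class = "panel_config"
  )
}

rating_sd_at <- function(config, true_oi) {
  if (is.function(config$rating_sd)) config$rating_sd(true_oi) else config$rating_sd
}

#' Simulate one panel rating of an odor sample
#'
#' Each assessor's rating is the true intensity plus Gaussian error, rounded
#' to the half-step OIRS grid (ties toward the scale midpoint) and clamped to
#' the scale bounds; the panel mean of those ratings is the simulated
#' measured odor intensity.
#'
#' @param true_oi true odor intensity of the sample, within the scale bounds.
#' @param config a [panel_config()].
#' @param seed optional integer seed for reproducibility.
#' @return list with `ratings` (length `n_assessors`, on the half-step grid)
#'   and `mean` (the panel mean).
#' @examples
#' simulate_panel_rating(4.0, panel_config(), seed = 1)
#' @export
simulate_panel_rating <- function(true_oi, config = panel_config(), seed = NULL) {
  stopifnot(inherits(config, "panel_config"),
            is.numeric(true_oi), length(true_oi) == 1L, is.finite(true_oi))
  b <- config$scale_bounds
  if (true_oi < b[1] || true_oi > b[2]) {
    stop(sprintf("`true_oi` must lie within the scale bounds [%g, %g]", b[1], b[2]),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sd <- rating_sd_at(config, true_oi)
  raw <- true_oi + if (sd > 0) stats::rnorm(config$n_assessors, 0, sd) else
    rep(0, config$n_assessors)
  ratings <- round_half_step(raw, bounds = b)
  list(ratings = ratings, mean = mean(ratings))
}

#' Binary-mixture experiment design
#'
#' The sampling design emulated by [generate_mixture_dataset()]: number of
#' samples, the mixing-proportion design range, the odor-intensity ceiling
#' (samples are prepared below 7.0 OIRS to avoid overly strong stimulation),
#' and how many samples fall in each intensity band.
#'
#' @param n_samples total samples (default 24).
#' @param ratio_range mixing-proportion range, a sub-interval of (0, 1)
#'   (default `c(0.1, 0.9)`).
#' @param oi_ceiling maximum intended odor intensity (default 7.0).
#' @param level_allocation named counts per band (default 8 each for `low`,
#'   `middle`, `high`); must sum to `n_samples`.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(n_samples = 24, ratio_range = c(0.1, 0.9),
                        oi_ceiling = 7,
                        level_allocation = c(low = 8, middle = 8, high = 8)) {
  stopifnot(is.numeric(ratio_range), length(ratio_range) == 2L,
            ratio_range[1] > 0, ratio_range[2] < 1,
            ratio_range[1] < ratio_range[2])
  stopifnot(oi_ceiling <= 8, oi_ceiling > 1)
  if (!all(c("low", "middle", "high") %in% names(level_allocation))) {
    stop("`level_allocation` must have entries named low, middle, high", call. = FALSE)
  }
  if (sum(level_allocation) != n_samples) {
    stop("`level_allocation` must sum to `n_samples`", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples), ratio_range = ratio_range,
         oi_ceiling = oi_ceiling,
         level_allocation = level_allocation[c("low", "middle", "high")]),
    class = "design_spec"
  )
}

# half-step grid of feasible true-intensity targets for one band
band_target_grid <- function(lo, hi, oi_ceiling, bounds) {
  # samples are prepared at intended scale levels; keep clear of the scale
  # floor so clamping cannot bias panel means, and strictly below both the
  # band top and the design ceiling
  lo_eff <- max(lo, bounds[1] + 0.5)
  hi_eff <- min(hi, oi_ceiling) - 1e-9
  if (ceiling(lo_eff * 2) / 2 > floor(hi_eff * 2) / 2) return(numeric())
  seq(ceiling(lo_eff * 2) / 2, floor(hi_eff * 2) / 2, by = 0.5)
}

#' Generate a synthetic binary-mixture dataset
#'
#' Emulates the 24-sample binary-mixture experiment: for each intensity band
#' it draws mixing proportions uniformly over the design range and true odor
#' intensities from the half-step grid inside the band (samples are prepared
#' at intended scale levels), derives the component lnOAVs from the truth
#' curve — the total lnOAV is `true_oi / f(x)` — converts them back to
#' gas-phase concentrations through the odorants' thresholds, and attaches a
#' simulated panel mean as `measured_oi`. Fully reproducible under `seed`.
#'
#' @param odorant_a,odorant_b [odorant()] objects for the two components.
#' @param truth the generating `mixture_curve` (default [extended_model()]).
#' @param design a [design_spec()].
#' @param config a [panel_config()].
#' @param seed optional integer seed.
#' @return data.frame with columns `mixture_id`, `odorant_a`,
#'   `conc_a_mg_m3`, `odorant_b`, `conc_b_mg_m3`, `ln_oav_a`, `ln_oav_b`,
#'   `true_oi`, `level`, `measured_oi`.
#' @examples
#' pa <- odorant("propionaldehyde", 40.6e-3)
#' va <- odorant("n-valeraldehyde", 20.5e-3)
#' d <- generate_mixture_dataset(pa, va, seed = 1)
#' table(d$level)
#' @export
generate_mixture_dataset <- function(odorant_a, odorant_b,
                                     truth = extended_model(),
                                     design = design_spec(),
                                     config = panel_config(), seed = NULL) {
  stopifnot(inherits(odorant_a, "odorant"), inherits(odorant_b, "odorant"),
            inherits(truth, "mixture_curve"), inherits(design, "design_spec"),
            inherits(config, "panel_config"))
  if (!is.null(seed)) set.seed(seed)
  bands <- list(low = c(1, 2.5), middle = c(2.5, 4.5), high = c(4.5, 7))
  rows <- list()
  for (band in names(bands)) {
    n_b <- design$level_allocation[[band]]
    if (n_b == 0L) next
    grid <- band_target_grid(bands[[band]][1], bands[[band]][2],
                             design$oi_ceiling, config$scale_bounds)
    if (length(grid) == 0L) {
      stop(sprintf("infeasible design: no feasible intensity targets in band `%s` under ceiling %g",
                   band, design$oi_ceiling), call. = FALSE)
    }
    x <- stats::runif(n_b, design$ratio_range[1], design$ratio_range[2])
    true_oi <- sample(grid, n_b, replace = TRUE)
    fx <- curve_value(truth, x)
    if (any(fx <= 0)) {
      stop("`truth` curve must be positive over the ratio range", call. = FALSE)
    }
    total <- true_oi / fx
    ln_a <- x * total
    ln_b <- (1 - x) * total
    measured <- vapply(true_oi, function(t) simulate_panel_rating(t, config)$mean,
                       numeric(1))
    rows[[band]] <- data.frame(
      odorant_a = odorant_a$name,
      conc_a_mg_m3 = odorant_a$threshold_mg_m3 * exp(ln_a),
      odorant_b = odorant_b$name,
      conc_b_mg_m3 = odorant_b$threshold_mg_m3 * exp(ln_b),
      ln_oav_a = ln_a, ln_oav_b = ln_b,
      true_oi = true_oi, level = band, measured_oi = measured
    )
  }
  out <- do.call(rbind, rows)
  out <- cbind(mixture_id = sprintf("S%02d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Repeated-rating precision experiment
#'
#' Replicates the precision analysis of repeated panel ratings: each sample's
#' odor intensity is measured `n_repeats` times, the per-sample mean of those
#' repeats is subtracted from each repeat, and deviations outside the
#' fluctuation envelope are counted.
#'
#' @param true_oi_set numeric vector of true sample intensities.
#' @param n_repeats number of repeated measurements per sample (>= 2).
#' @param config a [panel_config()]; set `rating_sd` to a function of the
#'   true intensity to emulate level-dependent precision.
#' @param seed optional integer seed.
#' @param envelope half-width of the fluctuation envelope (default 0.4 OIRS).
#' @return an object of class `precision_experiment`: list with `deviations`
#'   (data.frame of `sample`, `true_oi`, `rep`, `panel_mean`, `deviation`),
#'   `n_outside` (per-sample count of `|deviation| > envelope`), and
#'   `envelope`.
#' @export
precision_experiment <- function(true_oi_set, n_repeats = 10,
                                 config = panel_config(), seed = NULL,
                                 envelope = 0.4) {
  stopifnot(is.numeric(true_oi_set), length(true_oi_set) >= 1, n_repeats >= 2)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_along(true_oi_set), function(i) {
    means <- vapply(seq_len(n_repeats),
                    function(r) simulate_panel_rating(true_oi_set[i], config)$mean,
                    numeric(1))
    data.frame(sample = i, true_oi = true_oi_set[i], rep = seq_len(n_repeats),
               panel_mean = means, deviation = means - mean(means))
  })
  dev <- do.call(rbind, rows)
  n_outside <- tapply(abs(dev$deviation) > envelope, dev$sample, sum)
  structure(
    list(deviations = dev,
         n_outside = stats::setNames(as.integer(n_outside), names(n_outside)),
         envelope = envelope),
    class = "precision_experiment"
  )
}

#' @export
print.precision_experiment <- function(x, ...) {
  cat(sprintf("<precision_experiment> %d samples x %d repeats; |deviation| > %.2g in %d/%d measurements\n",
              length(unique(x$deviations$sample)), max(x$deviations$rep),
              x$envelope, sum(abs(x$deviations$deviation) > x$envelope),
              nrow(x$deviations)))
  invisible(x)
}
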