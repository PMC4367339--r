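test_that("normalization maps samples to (mixing proportion, per-unit intensity)", {
  # symmetric pair: x = 0.5, oi_m = OI / total
  expect_equal(normalize_mixture(1.0, 1.0, 3.0),
               data.frame(x = 0.5, oi_m = 1.5, total_ln_oav = 2))
  # a weak sample: OI 1.7 over total lnOAV 2.2
  n <- normalize_mixture(1.1, 1.1, 1.7)
  expect_equal(n$oi_m, 0.7727, tolerance = 1e-4)
  # an uneven pair
  n2 <- normalize_mixture(2.18, 0.56, 2.3)
  expect_equal(n2$x, 0.7956, tolerance = 1e-4)
  expect_error(normalize_mixture(2, 1, NA), "measured_oi")
  expect_error(normalize_mixture(-0.2, 1, 2), "sub-threshold")
  expect_error(normalize_mixture(1, 0, 2), "sub-threshold")
})

test_that("noiseless gridded points recover the pooled quadratic exactly", {
  x <- seq(0.1, 0.9, by = 0.1)
  fit <- fit_mixture_curve(data.frame(x = x, oi_m = pooled_f(x)))
  expect_equal(unname(fit$coefficients), POOLED_COEF, tolerance = 1e-9)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-9)
})

test_that("the fit enforces its rank and domain conditions", {
  ok <- data.frame(x = c(0.2, 0.5, 0.5, 0.8), oi_m = c(1, 0.8, 0.85, 1.1))
  expect_s3_class(fit_mixture_curve(ok), "mixture_curve")
  two_x <- data.frame(x = c(0.2, 0.2, 0.8, 0.8), oi_m = c(1, 1.02, 1.1, 1.08))
  expect_error(fit_mixture_curve(two_x), "degenerate")
  expect_error(fit_mixture_curve(ok[1:3, ]), "at least 4")
  bad_x <- data.frame(x = c(0.2, 0.5, 0.8, 1.2), oi_m = c(1, 0.8, 1.1, 1.3))
  expect_error(fit_mixture_curve(bad_x), "\\[0, 1\\]")
})

test_that("quadratic OLS equals the brute-force normal-equations oracle", {
  set.seed(31)
  for (i in 1:15) {
    n <- sample(4:10, 1)
    x <- runif(n)
    while (length(unique(x)) < 3) x <- runif(n)
    y <- pooled_f(x) + rnorm(n, 0, 0.1)
    fit <- fit_mixture_curve(data.frame(x = x, oi_m = y))
    expect_equal(unname(fit$coefficients), brute_force_poly_fit(x, y, 2),
                 tolerance = 1e-9)
  }
})

test_that("the pooled extended model reproduces its worked values", {
  m <- extended_model()
  expect_equal(round_half_up(curve_value(m, 0.3), 2), 0.86)
  expect_equal(round_half_up(curve_value(m, 0.6), 2), 0.79)
  # symmetric about x = 0.5, where the curve sits at its vertex value 0.77
  expect_equal(curve_slope(m, 0.5), 0, tolerance = 1e-12)
  expect_equal(curve_value(m, 0.5), 0.77, tolerance = 1e-12)
  expect_identical(m$provenance, "literature")
})

test_that("tangent intercepts give the worked partial intensities", {
  m <- extended_model()
  p3 <- partial_intensities(m, 0.3)
  expect_equal(round_half_up(p3$oi_a_m, 2), 0.24)
  expect_equal(round_half_up(p3$oi_b_m, 2), 1.12)
  p6 <- partial_intensities(m, 0.6)
  expect_equal(round_half_up(p6$oi_a_m, 2), 0.97)
  expect_equal(round_half_up(p6$oi_b_m, 2), 0.53)
  # at the vertex of a symmetric curve both components contribute equally
  p5 <- partial_intensities(m, 0.5)
  expect_equal(p5$oi_a_m, p5$oi_b_m, tolerance = 1e-12)
  expect_equal(p5$oi_a_m, curve_value(m, 0.5), tolerance = 1e-12)
})

test_that("partial intensities enforce the domain and warn on extrapolation", {
  m <- extended_model()
  expect_error(partial_intensities(m, 0), "out of domain")
  expect_error(partial_intensities(m, 1), "out of domain")
  expect_warning(partial_intensities(m, 0.05), class = "odorblend_extrapolation")
  expect_silent(partial_intensities(m, c(0.1, 0.9)))
})

test_that("tangent identity holds for random models and mixing proportions", {
  set.seed(41)
  for (i in 1:1000) {
    m <- random_curve()
    x <- runif(1, 0.01, 0.99)
    p <- suppressWarnings(partial_intensities(m, x))
    expect_equal(x * p$oi_a_m + (1 - x) * p$oi_b_m, curve_value(m, x),
                 tolerance = 1e-9)
  }
})

test_that("partial intensities are the marginal lnOAV contributions", {
  set.seed(43)
  h <- 1e-6
  for (i in 1:25) {
    m <- random_curve()
    a <- runif(1, 0.3, 3)
    b <- runif(1, 0.3, 3)
    pred <- suppressWarnings(predict_oi(m, a, b))
    up <- suppressWarnings(predict_oi(m, a + h, b))$oi_pre
    dn <- suppressWarnings(predict_oi(m, a - h, b))$oi_pre
    expect_equal((up - dn) / (2 * h), pred$oi_a_m, tolerance = 1e-5)
    upb <- suppressWarnings(predict_oi(m, a, b + h))$oi_pre
    dnb <- suppressWarnings(predict_oi(m, a, b - h))$oi_pre
    expect_equal((upb - dnb) / (2 * h), pred$oi_b_m, tolerance = 1e-5)
  }
})

test_that("swapping the two components swaps partials and preserves the prediction", {
  set.seed(47)
  for (i in 1:25) {
    m <- random_curve()
    cf <- m$coefficients
    # relabelled curve g(x) = f(1 - x)
    m_swap <- odorblend:::new_mixture_curve(c(
      cf["a0"] + cf["a1"] + cf["a2"], -cf["a1"] - 2 * cf["a2"], cf["a2"]))
    a <- runif(1, 0.3, 3)
    b <- runif(1, 0.3, 3)
    pred <- suppressWarnings(predict_oi(m, a, b))
    pred_swap <- suppressWarnings(predict_oi(m_swap, b, a))
    expect_equal(pred_swap$x, 1 - pred$x, tolerance = 1e-12)
    expect_equal(pred_swap$oi_a_m, pred$oi_b_m, tolerance = 1e-9)
    expect_equal(pred_swap$oi_b_m, pred$oi_a_m, tolerance = 1e-9)
    expect_equal(pred_swap$oi_pre, pred$oi_pre, tolerance = 1e-9)
  }
  # the pooled model is its own relabelling: oi_a_m(x) = oi_b_m(1 - x)
  m <- extended_model()
  xs <- seq(0.1, 0.9, by = 0.05)
  p <- partial_intensities(m, xs)
  p_rev <- partial_intensities(m, 1 - xs)
  expect_equal(p$oi_a_m, p_rev$oi_b_m, tolerance = 1e-12)
})

test_that("prediction follows the amount-weighted tangent sum", {
  m <- extended_model()
  expect_equal(round_oi_report(predict_oi(m, 2.18, 0.56)$oi_pre), 2.6)
  expect_equal(round_oi_report(predict_oi(m, 2.87, 2.17)$oi_pre), 3.9)
  near <- predict_oi(m, 2.18, 2.17)
  expect_equal(round_half_up(near$oi_a_m, 2), 0.77)
  expect_equal(round_half_up(near$oi_b_m, 2), 0.77)
  expect_equal(round_oi_report(near$oi_pre), 3.4)
  # hypo-additive contributions stay negative, not floored
  expect_lt(predict_oi(m, 2.18, 0.56)$oi_b_m, 0)
  expect_error(predict_oi(m, -1, 2), "sub-threshold")
})

test_that("coefficient bias shrinks as the number of samples grows", {
  err_at <- function(n, seeds) {
    colMeans(t(vapply(seeds, function(s) {
      set.seed(s)
      x <- runif(n, 0.1, 0.9)
      y <- pooled_f(x) + rnorm(n, 0, 0.05)
      unname(fit_mixture_curve(data.frame(x = x, oi_m = y))$coefficients) -
        POOLED_COEF
    }, numeric(3))))
  }
  bias24 <- abs(err_at(24, 1:60))
  bias240 <- abs(err_at(240, 1:60))
  expect_true(all(bias240 < pmax(bias24, 0.02)))
  expect_true(all(bias240 < 0.05))
})

test_that("stratification groups samples by design band", {
  oi <- c(seq(1.2, 2.3, length.out = 8), seq(2.6, 4.4, length.out = 8),
          seq(4.6, 6.9, length.out = 8))
  samples <- data.frame(id = seq_along(oi), measured_oi = oi)
  groups <- stratify_by_level(samples)
  expect_named(groups, c("low", "middle", "high"))
  expect_equal(vapply(groups, nrow, integer(1)),
               c(low = 8L, middle = 8L, high = 8L))
  empty <- stratify_by_level(data.frame(measured_oi = numeric()))
  expect_named(empty, c("low", "middle", "high"))
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))
})

test_that("noiseless fits are identical across intensity-level groups", {
  # same curve, different totals per band: the curve must not depend on level
  set.seed(53)
  x <- rep(seq(0.15, 0.85, length.out = 8), 3)
  oi_target <- c(rep(1.8, 8), rep(3.5, 8), rep(5.5, 8))
  total <- oi_target / pooled_f(x[1:8])
  samples <- data.frame(measured_oi = oi_target, x = x)
  groups <- stratify_by_level(samples)
  coefs <- lapply(groups, function(g) {
    unname(fit_mixture_curve(data.frame(x = g$x, oi_m = pooled_f(g$x)))$coefficients)
  })
  expect_equal(coefs$low, coefs$middle, tolerance = 1e-9)
  expect_equal(coefs$middle, coefs$high, tolerance = 1e-9)
  expect_equal(coefs$low, POOLED_COEF, tolerance = 1e-9)
})

test_that("predictive-coefficient evaluation averages prediction/measurement ratios", {
  ev <- evaluate_predictions(c(2.0, 3.0, 4.0), c(2.0, 3.0, 4.0))
  expect_equal(ev$mean_ratio, 1.0)
  # report mode reproduces the sequential printed-precision convention
  ev2 <- evaluate_predictions(3.3495, 3.3)
  expect_equal(ev2$records$oi_pre_reported, 3.4)
  ev_raw <- evaluate_predictions(3.3495, 3.3, rounding = "raw")
  expect_equal(ev_raw$mean_ratio, 3.3495 / 3.3, tolerance = 1e-12)
  expect_warning(
    ev3 <- evaluate_predictions(c(2, 3), c(2, NA)),
    class = "odorblend_excluded_record"
  )
  expect_equal(ev3$n_used, 1L)
  expect_equal(ev3$n_excluded, 1L)
})

test_that("the confidence band is a pointwise Student-t mean-response band", {
  set.seed(59)
  x <- rep(seq(0.1, 0.9, by = 0.1), 3)
  y <- pooled_f(x) + rnorm(length(x), 0, 0.05)
  fit <- fit_mixture_curve(data.frame(x = x, oi_m = y), confidence_level = 0.90)
  band <- confidence_band(fit, c(0.25, 0.5, 0.75))
  # oracle: lm's own predict with interval = "confidence"
  ref_fit <- lm(y ~ x + I(x^2))
  ref <- predict(ref_fit, newdata = data.frame(x = c(0.25, 0.5, 0.75)),
                 interval = "confidence", level = 0.90)
  expect_equal(band$fit, unname(ref[, "fit"]), tolerance = 1e-9)
  expect_equal(band$lwr, unname(ref[, "lwr"]), tolerance = 1e-9)
  expect_equal(band$upr, unname(ref[, "upr"]), tolerance = 1e-9)
  expect_error(confidence_band(extended_model(), 0.5), "residual information")
})
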