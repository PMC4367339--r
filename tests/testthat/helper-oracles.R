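# Independent brute-force oracles, deliberately naive: polynomial least
# squares by explicit normal equations, used to cross-check the lm-backed
# fitting surfaces.

brute_force_poly_fit <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# pooled aldehyde curve constants, lowest order first
POOLED_COEF <- c(1.32, -2.20, 2.20)

pooled_f <- function(x) POOLED_COEF[1] + POOLED_COEF[2] * x + POOLED_COEF[3] * x^2

# random strictly-convex-or-concave quadratic models for property tests
random_curve <- function() {
  odorblend:::new_mixture_curve(c(runif(1, 0.5, 2), runif(1, -3, 1), runif(1, -1, 3)))
}

pa_odorant <- function() odorant("propionaldehyde", 40.6e-3, molecular_weight = 58.08)
va_odorant <- function() odorant("n-valeraldehyde", 20.5e-3, molecular_weight = 86.13)
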