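# Shared fixtures: a noiseless instrument for exact oracle checks, a small
# noisy instrument, and a random full-rank linear regression problem.

quiet_instrument <- function(...) {
  thz_instrument(amplitude_noise_sd = 0, additive_noise_sd = 0, ...)
}

small_instrument <- function(...) {
  thz_instrument(n_points = 256L, pulse_center = 5, ...)
}

# y lies exactly in the column space of X (full column rank), so least
# squares and full-rank PLS must agree.
rand_lin_problem <- function(seed, n = 12L, p = 6L, noisy_y = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  b <- rnorm(p)
  y <- drop(X %*% b) + if (noisy_y) rnorm(n, 0, 0.3) else 0
  list(X = X, y = y, b = b)
}

# Least-squares oracle fitted values via QR (with intercept, matching the
# centring PLS applies).
ls_oracle_predictions <- function(X, y, X_new = X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  drop(cbind(1, X_new) %*% fit$coefficients)
}
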