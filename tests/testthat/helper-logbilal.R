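# Shared oracles, independent of the implementation paths they check.

# cdf written straight from the closed form, used by bisection oracles
cdf_direct <- function(y, theta) 3 * y^(2 / theta) - 2 * y^(3 / theta)

# quantile by bisection on the direct cdf
quantile_bisect <- function(u, theta, tol = 1e-13) {
  vapply(u, function(ui) {
    uniroot(function(y) cdf_direct(y, theta) - ui,
            interval = c(1e-300, 1 - 1e-16), tol = tol)$root
  }, numeric(1))
}

# adaptive quadrature with tight tolerances
quad <- function(f, lower, upper, ...) {
  integrate(f, lower, upper, ..., rel.tol = 1e-12, abs.tol = 1e-12,
            subdivisions = 500L)$value
}

# Sampler for the parent lifetime (Bilal) distribution on (0, Inf), by
# inverting its cdf 1 - exp(-2x/theta) * (3 - 2 exp(-x/theta)) with uniroot
# in s = exp(-x/theta); independent of the package's trig-form quantile.
rbilal_parent <- function(n, theta) {
  u <- runif(n)
  s <- vapply(u, function(ui) {
    uniroot(function(s) 1 - s^2 * (3 - 2 * s) - ui,
            interval = c(1e-16, 1 - 1e-16), tol = 1e-13)$root
  }, numeric(1))
  -theta * log(s)
}

# log-spaced theta grid spanning the supported shapes
theta_grid <- function(k = 9L, lo = 0.05, hi = 50) {
  exp(seq(log(lo), log(hi), length.out = k))
}

# simulate a regression data set at known coefficients (uniform covariates)
sim_regression <- function(n, beta) {
  p <- length(beta)
  X <- cbind(1, if (p > 1) matrix(runif(n * (p - 1)), n, p - 1))
  mu <- plogis(as.numeric(X %*% beta))
  y <- qlogbilal(runif(n), mu_to_theta(mu))
  dat <- data.frame(y = y)
  if (p > 1) dat[paste0("x", seq_len(p - 1))] <- X[, -1, drop = FALSE]
  dat
}
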