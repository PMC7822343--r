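test_that("log-likelihood is the sum of log densities and the score its slope", {
  expect_equal(logbilal_loglik(1, 0.5), log(1.5))
  set.seed(10)
  y <- rlogbilal(50, 1.7)
  for (th in c(0.5, 1.7))
    expect_equal(logbilal_loglik(th, y), sum(dlogbilal(y, th, log = TRUE)),
                 tolerance = 1e-14)
  h <- 1e-6
  fd <- (logbilal_loglik(1.7 + h, y) - logbilal_loglik(1.7 - h, y)) / (2 * h)
  expect_equal(logbilal_score(1.7, y), fd, tolerance = 1e-6)
})

test_that("method of moments is closed form and moment-matching", {
  fit <- fit_unitdist(c(0.4, 0.5, 0.6), method = "mm")
  expect_equal(coef(fit)[["theta"]], 1)
  expect_true(fit$converged)
  # the fitted mean reproduces the sample mean, always
  set.seed(11)
  for (i in 1:5) {
    y <- rlogbilal(30, runif(1, 0.2, 6))
    expect_equal(theta_to_mu(coef(fit_unitdist(y, method = "mm"))[["theta"]]),
                 mean(y), tolerance = 1e-12)
  }
  # consistency at large n
  set.seed(12)
  y <- rlogbilal(1e5, 1.7)
  expect_lt(abs(coef(fit_unitdist(y, method = "mm"))[["theta"]] - 1.7), 0.05)
})

test_that("MLE recovers the truth, zeroes the score, and beats a grid search", {
  set.seed(13)
  y <- rlogbilal(5000, 1.7)
  fit <- fit_unitdist(y, method = "mle")
  th <- coef(fit)[["theta"]]
  se <- fit$se[["theta"]]
  expect_true(fit$converged)
  expect_lt(abs(th - 1.7), 3 * se)
  expect_lt(abs(logbilal_score(th, y)), 1e-6)
  expect_equal(fit$loglik, logbilal_loglik(th, y))

  # brute-force grid oracle on a smaller sample
  set.seed(14)
  z <- rlogbilal(200, 1.7)
  grid <- seq(0.5, 4, by = 0.002)
  ll <- vapply(grid, function(t) logbilal_loglik(t, z), numeric(1))
  th_grid <- grid[which.max(ll)]
  th_hat <- coef(fit_unitdist(z, method = "mle"))[["theta"]]
  expect_lt(abs(th_hat - th_grid), 0.002)
})

test_that("least squares drives the plotting-position objective to zero", {
  n <- 50
  y <- qlogbilal(seq_len(n) / (n + 1), 1.7)   # zero-residual construction
  fit <- fit_unitdist(y, method = "lse")
  expect_equal(coef(fit)[["theta"]], 1.7, tolerance = 1e-4)
  expect_lt(fit$objective, 1e-12)
  wfit <- fit_unitdist(y, method = "wlse")
  expect_equal(coef(wfit)[["theta"]], 1.7, tolerance = 1e-4)
})

test_that("least-squares objective equals a hand-computed sum", {
  set.seed(15)
  y <- rlogbilal(10, 1.2)
  ys <- sort(y)
  n <- length(y)
  for (th in c(0.7, 1.2, 3)) {
    manual <- 0
    for (i in 1:n)
      manual <- manual + (cdf_direct(ys[i], th) - i / (n + 1))^2
    expect_equal(logbilal:::lse_objective(th, y, weighted = FALSE), manual,
                 tolerance = 1e-12)
    wmanual <- 0
    for (i in 1:n)
      wmanual <- wmanual + (n + 1)^2 * (n + 2) / (i * (n - i + 1)) *
        (cdf_direct(ys[i], th) - i / (n + 1))^2
    expect_equal(logbilal:::lse_objective(th, y, weighted = TRUE), wmanual,
                 tolerance = 1e-12)
  }
  # weight values at n = 3
  w <- (3 + 1)^2 * (3 + 2) / (1:3 * (3 - 1:3 + 1))
  expect_equal(w, c(80 / 3, 20, 80 / 3))
})

test_that("estimators are invariant under sample permutation", {
  set.seed(16)
  y <- rlogbilal(60, 2.5)
  yp <- sample(y)
  for (m in c("mle", "mm", "lse", "wlse"))
    expect_equal(coef(fit_unitdist(y, method = m)),
                 coef(fit_unitdist(yp, method = m)), tolerance = 1e-9)
})

test_that("fit objects expose the standard accessors", {
  set.seed(17)
  y <- rlogbilal(100, 1.7)
  fit <- fit_unitdist(y)
  expect_s3_class(fit, "unitdist_fit")
  expect_equal(AIC(fit), -2 * fit$loglik + 2)
  expect_equal(BIC(fit), -2 * fit$loglik + log(100))
  expect_equal(dim(vcov(fit)), c(1L, 1L))
  expect_output(print(fit), "log-Bilal")
  expect_output(print(summary(fit)), "Std. Error")
  expect_error(vcov(fit_unitdist(y, method = "mm")), "covariance")
  expect_error(fit_unitdist(y, family = "beta", method = "mm"),
               "only available")
})
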