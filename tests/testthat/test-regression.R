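test_that("regression likelihood equals the direct mean-parametrized form", {
  # single observation, intercept 0: mu = 1/2 so theta = 1
  expect_equal(logbilal:::lbreg_loglik(0, matrix(1, 1, 1), 0.5), log(1.5))
  set.seed(20)
  dat <- sim_regression(30, c(0.5, -0.4, 0.3))
  X <- cbind(1, dat$x1, dat$x2)
  for (beta in list(c(0.5, -0.4, 0.3), c(0, 0, 0), c(1, 1, -1))) {
    expect_equal(logbilal:::lbreg_loglik(beta, X, dat$y),
                 logbilal:::lbreg_loglik_direct(beta, X, dat$y),
                 tolerance = 1e-12)
    expect_equal(logbilal:::lbreg_loglik(beta, X, dat$y),
                 sum(dlogbilal(dat$y,
                               mu_to_theta(plogis(as.numeric(X %*% beta))),
                               log = TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("likelihood gradient is smooth: coarse and fine differences agree", {
  set.seed(21)
  dat <- sim_regression(40, c(0.8, -0.6))
  X <- cbind(1, dat$x1)
  beta <- c(0.5, -0.2)
  num_grad <- function(h) {
    vapply(seq_along(beta), function(j) {
      e <- replace(numeric(length(beta)), j, h)
      (logbilal:::lbreg_loglik(beta + e, X, dat$y) -
         logbilal:::lbreg_loglik(beta - e, X, dat$y)) / (2 * h)
    }, numeric(1))
  }
  g_coarse <- num_grad(1e-4)
  g_fine <- (4 * num_grad(5e-5) - g_coarse) / 3   # Richardson refinement
  expect_lt(max(abs(g_coarse - g_fine)), 1e-6)
})

test_that("coefficients are recovered on correctly specified data", {
  set.seed(22)
  dat <- sim_regression(2000, c(1.0, -0.5))
  fit <- lbreg(y ~ x1, data = dat)
  expect_true(fit$converged)
  expect_true(all(abs(coef(fit) - c(1.0, -0.5)) < 3 * fit$se))
  expect_true(all(fit$fitted.values > 0 & fit$fitted.values < 1))
  expect_lt(coef(fit)[["x1"]], 0)       # effect keeps the generating sign
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 2)
  expect_equal(fit$bic, -2 * fit$loglik + 2 * log(2000))
})

test_that("intercept-only regression reproduces the univariate MLE", {
  set.seed(23)
  y <- rlogbilal(300, 2.4)
  fit <- lbreg(y ~ 1, data = data.frame(y = y))
  th_reg <- mu_to_theta(plogis(coef(fit)[[1]]))
  th_mle <- coef(fit_unitdist(y, method = "mle"))[["theta"]]
  expect_equal(th_reg, th_mle, tolerance = 1e-5)
  expect_equal(fit$loglik, logbilal_loglik(th_mle, y), tolerance = 1e-8)
})

test_that("quantile residuals are median-zero and standard normal when the
           model is right", {
  set.seed(24)
  dat <- sim_regression(500, c(1.2, -0.7))
  fit <- lbreg(y ~ x1, data = dat)
  # an observation at the fitted conditional median has residual zero
  y_med <- qlogbilal(rep(0.5, fit$n), fit$theta)
  expect_lt(max(abs(qnorm(plogbilal(y_med, fit$theta)))), 1e-7)
  # Q-Q points of the actual residuals hug the diagonal
  r <- sort(residuals(fit))
  qq_dev <- max(abs(r - qnorm(seq_len(fit$n) / (fit$n + 1))))
  expect_lt(qq_dev, 0.5)
  expect_identical(residuals(fit), fit$residuals)
  expect_equal(residuals(fit, type = "response"),
               fit$y - fit$fitted.values)

  # calibration: most well-specified replicates pass a 1%-level normality
  # K-S test of the residuals
  set.seed(25)
  pass <- vapply(1:40, function(i) {
    d <- sim_regression(200, c(0.8, -0.5))
    f <- lbreg(y ~ x1, data = d)
    suppressWarnings(stats::ks.test(residuals(f), "pnorm")$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("prediction and simulation are consistent with the fit", {
  set.seed(26)
  dat <- sim_regression(200, c(0.5, 0.8))
  fit <- lbreg(y ~ x1, data = dat)
  expect_equal(predict(fit), fit$fitted.values, tolerance = 1e-12)
  nd <- data.frame(x1 = c(0.1, 0.9))
  mu <- predict(fit, nd)
  expect_equal(qlogis(mu), predict(fit, nd, type = "link"),
               tolerance = 1e-9)
  expect_equal(predict(fit, nd, type = "theta"), mu_to_theta(mu))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(200L, 2L))
  expect_true(all(sim > 0 & sim < 1))
})

test_that("degenerate designs and bad starts raise distinct errors", {
  set.seed(27)
  dat <- sim_regression(50, c(0.5, -0.5))
  dat$x2 <- 2 * dat$x1
  expect_error(lbreg(y ~ x1 + x2, data = dat), "rank deficient")
  expect_error(lbreg(y ~ x1, data = dat[1:2, ]), "more observations")
  expect_error(lbreg(y ~ x1, data = dat, start = c(0, 0, 0)), "length")
  bad <- dat; bad$y[1] <- 1
  expect_error(lbreg(y ~ x1, data = bad), "strictly inside")
})
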