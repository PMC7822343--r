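test_that("density reduces to Beta(2,2) at theta = 1 and is normalized", {
  y <- seq(0.001, 0.999, length.out = 201)
  expect_equal(dlogbilal(y, 1), dbeta(y, 2, 2), tolerance = 1e-14)
  expect_equal(dlogbilal(0.5, 1), 1.5)
  for (th in theta_grid()) {
    expect_equal(quad(function(y) dlogbilal(y, th), 0, 1), 1,
                 tolerance = 1e-8)
  }
})

test_that("density is the derivative of the cdf", {
  h <- 1e-6
  for (case in list(c(0.1, 4.7063), c(0.5, 1.7), c(0.9, 0.3))) {
    y <- case[1]; th <- case[2]
    fd <- (plogbilal(y + h, th) - plogbilal(y - h, th)) / (2 * h)
    expect_equal(dlogbilal(y, th), fd, tolerance = 1e-6)
  }
})

test_that("cdf matches quadrature of the density and hits its boundaries", {
  expect_equal(plogbilal(0.5, 1), 0.5)
  expect_equal(plogbilal(0.3, 1.7),
               quad(function(y) dlogbilal(y, 1.7), 0, 0.3),
               tolerance = 1e-8)
  for (th in theta_grid(5)) {
    expect_identical(plogbilal(0, th), 0)
    expect_identical(plogbilal(1, th), 1)
    p <- plogbilal(seq(0, 1, length.out = 101), th)
    expect_true(all(diff(p) >= 0))
  }
  # survival companion
  expect_equal(plogbilal(0.4, 2.2, lower.tail = FALSE),
               1 - plogbilal(0.4, 2.2))
})

test_that("quantile function inverts the cdf to 1e-10", {
  u <- c(1e-6, 1e-3, 0.1, 0.25, 0.5, 0.75, 0.9, 1 - 1e-3, 1 - 1e-6)
  for (th in theta_grid()) {
    q <- qlogbilal(u, th)
    expect_true(all(diff(q) > 0))
    expect_lt(max(abs(plogbilal(q, th) - u)), 1e-10)
  }
  expect_equal(qlogbilal(0.5, 1), 0.5, tolerance = 1e-14)
  # independent bisection oracle on the closed-form cdf
  expect_equal(qlogbilal(0.25, 1.7), quantile_bisect(0.25, 1.7),
               tolerance = 1e-10)
  expect_equal(qlogbilal(c(0.05, 0.6, 0.95), 0.3),
               quantile_bisect(c(0.05, 0.6, 0.95), 0.3), tolerance = 1e-10)
})

test_that("random generation is reproducible and follows the law", {
  set.seed(42); a <- rlogbilal(100, 1.7)
  set.seed(42); b <- rlogbilal(100, 1.7)
  expect_identical(a, b)

  set.seed(7)
  y <- rlogbilal(1e6, 1)
  expect_equal(mean(y), 0.5, tolerance = 3 * sd(y) / 1000)

  set.seed(8)
  z <- rlogbilal(1e5, 1.7)
  ks <- suppressWarnings(
    stats::ks.test(z, function(q) plogbilal(q, 1.7)))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(1e5))  # 1% critical value
})

test_that("exp(-X) of the parent lifetime law matches the unit-interval cdf", {
  set.seed(99)
  x <- rbilal_parent(2e4, 1.7)
  y <- exp(-x)
  ks <- suppressWarnings(
    stats::ks.test(y, function(q) plogbilal(q, 1.7)))
  expect_gt(ks$p.value, 0.01)
})

test_that("hazard satisfies h * S = f and its shape diagnostic works", {
  y <- seq(0.01, 0.99, length.out = 50)
  for (th in c(0.4, 1, 3)) {
    expect_equal(hlogbilal(y, th) * plogbilal(y, th, lower.tail = FALSE),
                 dlogbilal(y, th), tolerance = 1e-12)
  }
  expect_identical(hazard_shape(0.5)$shape, "increasing")
  expect_identical(hazard_shape(5)$shape, "bathtub")
})

test_that("domain violations raise errors instead of being clamped", {
  expect_error(dlogbilal(0, 1), "strictly inside")
  expect_error(dlogbilal(1, 1), "strictly inside")
  expect_error(dlogbilal(c(0.2, 1.2), 1), "strictly inside")
  expect_error(dlogbilal(0.5, -1), "positive")
  expect_error(plogbilal(1.5, 1))
  expect_error(plogbilal(0.5, 0), "positive")
  expect_error(qlogbilal(0, 1), "strictly inside")
  expect_error(qlogbilal(1, 1), "strictly inside")
  expect_error(rlogbilal(0, 1), "integer")
  expect_error(hlogbilal(0.5, -2), "positive")
})
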