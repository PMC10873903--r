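test_that("check loss matches its closed form", {
  expect_equal(check_loss(1, 0.3), 0.3)
  expect_equal(check_loss(-1, 0.3), 0.7)
  expect_equal(check_loss(0, 0.9), 0)
  v <- seq(-2, 2, by = 0.25)
  expect_true(all(check_loss(v, 0.17) >= 0))
  # piecewise-linear: slopes tau and tau - 1
  expect_equal(check_loss(2, 0.17), 2 * 0.17)
  expect_equal(check_loss(-2, 0.17), 2 * 0.83)
  expect_error(check_loss(1, 1.2), "between 0 and 1")
})

test_that("noiseless linear data is recovered (slope exactly, intercept to
           within the smoothing bias at the floor bandwidth)", {
  x <- seq(-2, 2, length.out = 25)
  X <- cbind(1, x)
  y <- 1 + 2 * x
  f5 <- fit_quantile(X, y, 0.5, se = "none")
  expect_equal(unname(f5$coefficients), c(1, 2), tolerance = 1e-7)
  f3 <- fit_quantile(X, y, 0.3, se = "none")
  expect_equal(unname(f3$coefficients[2]), 2, tolerance = 1e-6)
  # smoothing shifts the noiseless intercept by at most h*|qnorm(tau)|
  expect_lt(abs(f3$coefficients[1] - 1), f3$h * abs(qnorm(0.3)) + 1e-6)
})

test_that("solver agrees with the basis-enumeration oracle on small
           instances after bandwidth continuation", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(8:14, 1)
    tau <- sample(c(0.25, 0.5, 0.75), 1)
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- drop(X %*% c(1, -2, 0.5)) + rnorm(n)
    oracle <- exact_rq(X, y, tau)
    fit <- fit_quantile_sharp(X, y, tau)
    expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
                 tolerance = 1e-5)
    expect_equal(sum(check_loss(fit$residuals, tau)), oracle$loss,
                 tolerance = 1e-6)
  }
})

test_that("intercept-only median fit is consistent for the sample median", {
  set.seed(2)
  y <- rnorm(10000)
  f <- fit_quantile(matrix(1, length(y), 1), y, 0.5, se = "none")
  mc_se <- sqrt(pi / 2) / sqrt(length(y))
  expect_lt(abs(f$coefficients[1] - 0), 3 * mc_se)
})

test_that("objective equals the mean check loss and is locally optimal", {
  set.seed(4)
  n <- 12
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  fit <- fit_quantile_sharp(X, y, 0.5)
  expect_equal(fit$objective, mean(check_loss(y - X %*% fit$coefficients, 0.5)))
  # axis perturbations cannot improve the convex check loss at the optimum
  for (j in 1:2) for (s in c(-1, 1)) {
    b <- fit$coefficients
    b[j] <- b[j] + s * 1e-3
    expect_gte(mean(check_loss(y - X %*% b, 0.5)), fit$objective - 1e-10)
  }
})

test_that("residual signs balance at the quantile (first-order condition)", {
  set.seed(9)
  for (tau in c(0.2, 0.5, 0.8)) {
    n <- 30
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- rnorm(n)
    fit <- fit_quantile_sharp(X, y, tau)
    r <- fit$residuals
    n_neg <- sum(r < -1e-7)
    n_zero <- sum(abs(r) <= 1e-7)
    expect_lte(n_neg, n * tau + 1e-9)
    expect_lte(n * tau, n_neg + n_zero + ncol(X) + 1e-9)
  }
})

test_that("the smoothed fit is affine-equivariant when the bandwidth
           scales with the response", {
  set.seed(6)
  n <- 80
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 2)) + rnorm(n)
  h0 <- 0.3
  f1 <- fit_quantile(X, y, 0.3, h = h0, se = "none")
  f2 <- fit_quantile(X, 10 * y + drop(X %*% c(0.5, -1)), 0.3, h = 10 * h0,
                     se = "none")
  expect_equal(unname(f2$coefficients),
               unname(10 * f1$coefficients + c(0.5, -1)), tolerance = 1e-6)
})

test_that("sandwich SEs match the Gaussian closed form at the median", {
  set.seed(8)
  n <- 5000
  X <- cbind(1, rnorm(n))
  sigma <- 1.5
  y <- drop(X %*% c(0.5, 1)) + rnorm(n, sd = sigma)
  f <- fit_quantile(X, y, 0.5, se = "kernel")
  closed <- sigma * sqrt(pi / 2) * sqrt(diag(solve(crossprod(X))))
  expect_equal(unname(f$standard_errors), closed, tolerance = 0.15)
})

test_that("sandwich SEs are scale-equivariant", {
  set.seed(10)
  n <- 300
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 1)) + rnorm(n)
  h0 <- sqr_bandwidth(n, 2)
  f1 <- fit_quantile(X, y, 0.5, h = h0, se = "kernel")
  f2 <- fit_quantile(X, 10 * y, 0.5, h = 10 * h0, se = "kernel")
  expect_equal(unname(f2$standard_errors), unname(10 * f1$standard_errors),
               tolerance = 1e-8)
})

test_that("bootstrap and sandwich SEs agree on a fixed instance", {
  set.seed(12)
  n <- 200
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 2)) + rnorm(n)
  fk <- fit_quantile(X, y, 0.5, se = "kernel")
  fb <- fit_quantile(X, y, 0.5, se = "bootstrap", boot_reps = 500,
                     seed = 99)
  expect_equal(unname(fb$standard_errors), unname(fk$standard_errors),
               tolerance = 0.25)
})

test_that("degenerate designs are rejected", {
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_error(fit_quantile(X, rnorm(4), 0.5), "rank deficient")
  expect_error(fit_quantile(cbind(1, rnorm(2)), rnorm(2), 0.5),
               "more observations")
})
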