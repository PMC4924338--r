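test_that("noiseless linear data is interpolated and differentiated exactly", {
  m <- fit_hgp(0:6, 2 * (0:6) + 1)
  expect_equal(posterior_mean(m, 3), 7, tolerance = 1e-3,
               ignore_attr = TRUE)
  d <- posterior_derivative(m, c(2, 3, 4))
  expect_equal(d$rate_mean, rep(2, 3), tolerance = 1e-2)
  expect_false(any(d$boundary))
  expect_true(posterior_derivative(m, 0)$boundary)
})

test_that("constant series predicts the constant everywhere", {
  m <- fit_hgp(c(0, 5, 10, 15), rep(3.3, 4))
  expect_equal(posterior_mean(m, c(2, 7, 12)), rep(3.3, 3),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("posterior mean agrees with a dense-matrix GP oracle", {
  set.seed(21)
  t <- sort(runif(12, 0, 50))
  y <- 3 + 0.2 * t + rnorm(12, 0, 0.3)
  m <- fit_hgp(t, y)
  # naive oracle using the fitted hyperparameters directly
  tt <- seq(2, 48, length.out = 9)
  K <- m$kernel$signal_variance *
    exp(-outer(m$train_times, m$train_times, "-")^2 /
          (2 * m$kernel$lengthscale^2))
  C <- K + diag((m$noise_sd / m$scale)^2, length(t))
  ks <- m$kernel$signal_variance *
    exp(-outer(tt, m$train_times, "-")^2 / (2 * m$kernel$lengthscale^2))
  yn <- (y[order(t)] - m$mean_offset) / m$scale
  oracle <- m$scale * as.numeric(ks %*% solve(C, yn)) + m$mean_offset
  expect_equal(posterior_mean(m, tt), oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("derivative posterior matches the analytic derivative of sin", {
  set.seed(22)
  t <- seq(0.2, 12.4, length.out = 40)
  y <- sin(t) + rnorm(40, 0, 0.01)
  m <- fit_hgp(t, y, config = hgp_config(seed = 22))
  tt <- seq(1, 12, by = 0.5)
  d <- posterior_derivative(m, tt)
  expect_lt(max(abs(d$rate_mean - cos(tt))), 0.05)
})

test_that("derivative equals central finite differences of the mean", {
  set.seed(23)
  t <- sort(runif(10, 0, 100))
  y <- 5 + 0.05 * t + rnorm(10, 0, 0.2)
  m <- fit_hgp(t, y, config = hgp_config(restarts = 2, seed = 23))
  tt <- seq(min(t) + 1, max(t) - 1, length.out = 15)
  h <- 1e-4
  fd <- (posterior_mean(m, tt + h) - posterior_mean(m, tt - h)) / (2 * h)
  expect_equal(posterior_derivative(m, tt)$rate_mean, as.numeric(fd),
               tolerance = 1e-6)
})

test_that("homoscedastic noise level is recovered within a factor band", {
  set.seed(10)
  t <- seq(0, 10, length.out = 100)
  y <- sin(t / 2) + rnorm(100, 0, 0.1)
  m <- fit_hgp(t, y, config = hgp_config(restarts = 2, seed = 10))
  expect_true(all(m$noise_sd >= 0.05 & m$noise_sd <= 0.2))
})

test_that("two-segment noise is resolved with the right contrast", {
  set.seed(3)
  t <- seq(0, 10, length.out = 200)
  sdv <- ifelse(t < 5, 0.05, 0.5)
  y <- sin(t / 2) + rnorm(200, 0, sdv)
  m <- fit_hgp(t, y, config = hgp_config(restarts = 2, seed = 3))
  expect_gt(mean(m$noise_sd[t >= 5]), 3 * mean(m$noise_sd[t < 5]))
})

test_that("predictions are linear in the (centered) observations", {
  set.seed(24)
  t <- sort(runif(9, 0, 30))
  y <- 2 + 0.3 * t + rnorm(9, 0, 0.1)
  m <- fit_hgp(t, y)
  m2 <- m
  m2$alpha <- 2 * m$alpha  # doubled centered observations, same kernel
  tt <- c(5, 15, 25)
  expect_equal(posterior_mean(m2, tt) - m$mean_offset,
               2 * (posterior_mean(m, tt) - m$mean_offset),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(posterior_derivative(m2, tt)$rate_mean,
               2 * posterior_derivative(m, tt)$rate_mean, tolerance = 1e-12)
})

test_that("fit is invariant to permutation of input points", {
  set.seed(25)
  t <- sort(runif(10, 0, 60))
  y <- 1 + 0.1 * t + rnorm(10, 0, 0.2)
  perm <- sample(10)
  m1 <- fit_hgp(t, y, config = hgp_config(seed = 5))
  m2 <- fit_hgp(t[perm], y[perm], config = hgp_config(seed = 5))
  tt <- c(10, 30, 50)
  expect_equal(posterior_mean(m1, tt), posterior_mean(m2, tt),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("specific rates divide the derivative by biomass, sign-aware", {
  # concentration falling at 1 g/l/h, biomass flat at 2 g/l
  t <- seq(0, 10, length.out = 15)
  conc <- fit_hgp(t, 20 - t)
  bio <- fit_hgp(t, rep(2, 15))
  sr <- specific_rates(conc, bio, c(3, 5, 7), uptake = TRUE)
  expect_equal(sr$specific_rate, rep(0.5, 3), tolerance = 1e-2)

  # constant concentration: rate indistinguishable from zero
  flat <- fit_hgp(t, rep(7, 15))
  sr0 <- specific_rates(flat, bio, c(3, 5, 7))
  expect_true(all(abs(sr0$rate_mean) <= pmax(3 * sr0$rate_sd, 1e-6)))
})

test_that("growth rate recovers an exponential and a stationary phase", {
  t <- seq(0, 20, length.out = 15)
  bio <- fit_hgp(t, 0.5 * exp(0.1 * t))
  mu <- growth_rate(bio, c(6, 10, 14))
  expect_equal(mu$mu, rep(0.1, 3), tolerance = 1e-2)

  biolog <- fit_hgp(t, 0.5 * exp(0.1 * t), log_transform = TRUE)
  mulog <- growth_rate(biolog, c(6, 10, 14))
  expect_equal(mulog$mu, rep(0.1, 3), tolerance = 3e-3)

  flat <- fit_hgp(t, rep(4, 15))
  muf <- growth_rate(flat, c(6, 10, 14))
  expect_lt(max(abs(muf$mu)), 1e-3)
})

test_that("molar conversion and its inverse are exact", {
  expect_equal(to_molar(0.0565, 56545), 0.0565 * 1000 / 56545,
               tolerance = 1e-12)
  expect_equal(to_molar(1, 180.16), 5.5506, tolerance = 1e-4)
  expect_equal(to_molar(0.0565, 56545) * 56545 / 1000, 0.0565,
               tolerance = 1e-12)
  expect_error(to_molar(1, NA), "molecular weight")
})

test_that("fit contracts reject degenerate inputs", {
  expect_error(fit_hgp(c(0, 1), c(1, 2)), "3 distinct")
  expect_error(fit_hgp(c(0, 1, 2), c(1, NA, 2)), "finite")
})
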