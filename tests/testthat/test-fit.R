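test_that("noiseless isotherm data is recovered exactly", {
  fit <- fit_binding(make_series(K = 0.8, delta_c = 0.8))
  expect_equal(fit$K, 0.8, tolerance = 1e-6)
  expect_equal(fit$delta_c, 0.8, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  withr::with_seed(21, {
    for (i in 1:20) {
      K <- runif(1, 0.05, 2)
      dc <- runif(1, 0.1, 1.5)
      f <- fit_binding(make_series(K = K, delta_c = dc))
      expect_equal(f$K, K, tolerance = 1e-6)
      expect_equal(f$delta_c, dc, tolerance = 1e-6)
    }
  })
})

test_that("fit agrees with an independent Levenberg-Marquardt solver", {
  skip_if_not_installed("minpack.lm")
  dat <- make_series(K = 0.6, delta_c = 0.9, noise_sd = 0.003, seed = 5)
  mine <- fit_binding(dat)$fit[[1]]
  lm_fit <- minpack.lm::nlsLM(
    delta ~ bound_fraction(K, 0.001, d0) * dc,
    data = dat, start = list(K = 1, dc = 1),
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14)
  )
  expect_equal(unname(mine$estimate), unname(coef(lm_fit)),
               tolerance = 1e-6)
  expect_equal(unname(mine$se),
               unname(summary(lm_fit)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
})

test_that("fitting AUS-contaminated data with the plain isotherm biases K", {
  dat <- make_series(K = 0.8, delta_c = 0.8, a1 = 0.09, a2 = 0.01)
  fit <- fit_binding(dat)
  expect_equal(fit$K, 0.776, tolerance = 0.02)
  expect_lt(fit$K, 0.8)
  expect_gt(fit$delta_c, 0.8)
})

test_that("standard errors shrink to zero with the noise", {
  z <- withr::with_seed(22, stats::rnorm(9))
  ses <- vapply(c(1e-2, 1e-3, 1e-4), function(s) {
    dat <- make_series(K = 0.8, delta_c = 0.8)
    dat$delta <- dat$delta + s * z
    fit_binding(dat)$se_K
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
  # SEs become proportional to the error scale as it shrinks
  expect_equal(ses[2] / ses[3], 10, tolerance = 0.05)
})

test_that("fit is invariant to point order and linear in delta_c", {
  dat <- make_series(K = 0.5, delta_c = 1.1, noise_sd = 0.002, seed = 3)
  f1 <- fit_binding(dat)
  f2 <- fit_binding(dat[sample(nrow(dat)), ])
  expect_equal(f1$K, f2$K, tolerance = 1e-9)
  expect_equal(f1$delta_c, f2$delta_c, tolerance = 1e-9)
  # doubling delta_c doubles every fitted shift
  a <- fit_binding(make_series(delta_c = 0.6))$fit[[1]]
  b <- fit_binding(make_series(delta_c = 1.2))$fit[[1]]
  expect_equal(2 * a$fitted, b$fitted, tolerance = 1e-8)
})

test_that("under-determined or invalid series are rejected", {
  dat <- make_series()[1:2, ]
  expect_error(fit_binding(dat), "fewer than 3")
  flat <- tibble::tibble(acceptor = "a", proton = "H", a0 = 0.001,
                         d0 = c(0, 0, 0.5), delta = c(0, 0, 0.1))
  expect_error(fit_binding(flat), "duplicated")
})

test_that("fixed-AUS refits recover the generating parameters", {
  dat <- make_series(K = 0.8, delta_c = 0.8, a1 = 0.09, a2 = 0.04)
  refit <- fit_binding(dat, a1 = 0.09, a2 = 0.04)
  expect_equal(refit$K, 0.8, tolerance = 1e-6)
  expect_equal(refit$delta_c, 0.8, tolerance = 1e-6)
  # zero AUS coefficients give the identical plain-isotherm result
  noisy <- make_series(noise_sd = 0.002, seed = 9)
  expect_equal(fit_binding(noisy, a1 = 0, a2 = 0)$K,
               fit_binding(noisy)$K, tolerance = 1e-10)
})

test_that("dilute-acceptor a2-free AUS data maps to a shifted isotherm", {
  # with a2 = 0 and a0 -> 0, AUS data is exactly an isotherm with
  # K' = K and delta_c' = delta_c + a1/K
  dat <- make_series(K = 0.8, delta_c = 0.8, a1 = 0.09, a2 = 0, a0 = 1e-8)
  fit <- fit_binding(dat)
  expect_equal(fit$K, 0.8, tolerance = 1e-4)
  expect_equal(fit$delta_c, 0.8 + 0.09 / 0.8, tolerance = 1e-4)
  expect_equal(fit$delta_c, 0.9125, tolerance = 1e-4)
})

test_that("broom-style accessors expose the fit", {
  fit <- fit_binding(make_series(noise_sd = 0.002, seed = 4))$fit[[1]]
  td <- tidy(fit)
  expect_equal(td$term, c("K", "delta_c"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_equal(gl$nobs, 9L)
  expect_gt(gl$r.squared, 0.999)
  au <- augment(fit)
  expect_equal(au$.resid, au$delta - au$.fitted, tolerance = 1e-12)
  expect_equal(predict(fit), fit$fitted)
  expect_s3_class(autoplot(fit), "ggplot")
})
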