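test_that("noiseless data bootstraps to a point mass at the estimate", {
  fit <- fit_binding(make_series())$fit[[1]]
  bb <- bootstrap_binding(fit, B = 100, seed = 1)
  expect_true(all(abs(bb$K - fit$estimate[["K"]]) < 1e-6))
  expect_true(all(abs(bb$delta_c - fit$estimate[["delta_c"]]) < 1e-6))
  expect_identical(bb$n_failed, 0L)
})

test_that("bootstrap is reproducible given the seed", {
  fit <- fit_binding(make_series(noise_sd = 0.003, seed = 8))$fit[[1]]
  b1 <- bootstrap_binding(fit, B = 200, seed = 42)
  b2 <- bootstrap_binding(fit, B = 200, seed = 42)
  expect_identical(b1$K, b2$K)
  expect_identical(b1$delta_c, b2$delta_c)
  b3 <- bootstrap_binding(fit, B = 200, seed = 43)
  expect_false(identical(b1$K, b3$K))
  expect_error(bootstrap_binding(fit, B = 50), "B")
})

test_that("bootstrap spread tracks the Jacobian standard error", {
  fit <- fit_binding(make_series(noise_sd = 0.003, seed = 15))$fit[[1]]
  bb <- bootstrap_binding(fit, B = 1000, seed = 2)
  expect_lt(abs(sd(bb$K) - fit$se[["K"]]) / fit$se[["K"]], 0.3)
  expect_lt(abs(sd(bb$delta_c) - fit$se[["delta_c"]]) / fit$se[["delta_c"]],
            0.3)
})

test_that("Anderson-Darling gate distinguishes normal from skewed draws", {
  x_norm <- withr::with_seed(30, stats::rnorm(10000))
  x_exp <- withr::with_seed(31, stats::rexp(10000))
  expect_true(ad_normality(x_norm)$normal)
  expect_false(ad_normality(x_exp)$normal)
  deg <- ad_normality(rep(1, 1000))
  expect_false(deg$normal)
  expect_true(is.na(deg$statistic))
})

test_that("pairwise comparison routes and decides correctly", {
  x <- withr::with_seed(32, stats::rnorm(5000, 10, 1))
  same <- compare_bootstraps(fake_boot(x, proton = "H2"),
                             fake_boot(x, proton = "H4"), "K")
  expect_equal(same$p_value, 1)
  expect_equal(same$decision, "accept")
  expect_equal(same$null, "H2 = H4")

  y <- withr::with_seed(33, stats::rnorm(5000, 10, 1))
  far <- compare_bootstraps(fake_boot(x), fake_boot(y + 20), "K")
  expect_equal(far$method, "normal")
  expect_lt(far$p_value, 1e-10)
  expect_equal(far$decision, "reject")

  skew <- withr::with_seed(34, stats::rexp(5000))
  routed <- compare_bootstraps(fake_boot(x), fake_boot(skew), "K")
  expect_equal(routed$method, "mann_whitney")

  # normal and rank routes agree on well-separated normal draws
  mw <- suppressWarnings(
    stats::wilcox.test(x, y + 20, exact = FALSE)$p.value)
  expect_lt(mw, far$alpha)
  expect_error(compare_bootstraps(fake_boot(x), fake_boot(x, B = 10)[c(1)]),
               class = "error")
})

test_that("Bonferroni level divides the family level by the count", {
  expect_equal(bonferroni_alpha(1), 0.05)
  expect_equal(bonferroni_alpha(2), 0.025)
  expect_equal(bonferroni_alpha(3), 0.05 / 3)
  expect_error(bonferroni_alpha(0), "count")
})

test_that("percentile intervals use interpolated order statistics", {
  expect_equal(percentile_interval(rep(3, 50)),
               tibble::tibble(lower = 3, upper = 3, negative = FALSE))
  pi <- percentile_interval(as.numeric(1:10000))
  # closed-form type-7 interpolation: 1 + p * (n - 1)
  expect_equal(pi$lower, 1 + 0.025 * 9999)
  expect_equal(pi$upper, 1 + 0.975 * 9999)
  expect_equal(round(pi$lower, 3), 250.975)
  neg <- percentile_interval(-(1:100))
  expect_true(neg$negative)
})

test_that("normal-route comparisons keep their nominal type-I rate", {
  # two independent titrations with identical truth, compared pairwise;
  # conditioning on the normal (z) route, rejection should be near alpha
  set.seed(7)
  n_rep <- 100
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    mk <- function(s) {
      dat <- make_series(noise_sd = 0.003, seed = 1000 + s)
      bootstrap_binding(fit_binding(dat)$fit[[1]], B = 400, seed = s)
    }
    out[[r]] <- compare_bootstraps(mk(2 * r), mk(2 * r + 1), "K",
                                   alpha = 0.05)
  }
  out <- dplyr::bind_rows(out)
  normal <- out[out$method == "normal", ]
  expect_gt(nrow(normal), 30)
  rate <- mean(normal$decision == "reject")
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(normal)))
  # the rank route, in contrast, is overpowered for bootstrap draws: it
  # treats B as the sample size, so tiny estimate differences reject
  mw <- out[out$method == "mann_whitney", ]
  if (nrow(mw) > 0) expect_gt(mean(mw$decision == "reject"), 0.5)
})

test_that("whole-acceptor comparison yields a decision matrix", {
  sc <- offset_complex_scenario(3, noise_sd = 0.002, seed = 5)
  fits <- fit_binding(simulate_titration(sc))
  res <- compare_protons(fits, B = 300, seed = 9)
  expect_equal(nrow(res), 6L)  # 3 pairs x 2 parameters
  expect_setequal(unique(res$parameter), c("K", "delta_c"))
  expect_equal(unique(res$alpha), 0.05 / 3)
  expect_true(all(res$decision %in% c("accept", "reject")))
  expect_true(all((res$p_value < res$alpha) == (res$decision == "reject")))
})

test_that("bootstrap tidier returns one row per draw and parameter", {
  fit <- fit_binding(make_series(noise_sd = 0.002, seed = 2))$fit[[1]]
  bb <- bootstrap_binding(fit, B = 150, seed = 3)
  td <- tidy(bb)
  expect_equal(nrow(td), 300L)
  expect_setequal(unique(td$parameter), c("K", "delta_c"))
})
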