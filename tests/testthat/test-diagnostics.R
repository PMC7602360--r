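test_that("ratio plot on dilute noiseless data has slope -K", {
  # Scatchard-form identity: delta/d0 = K*delta_c - K*delta as a0 -> 0
  for (K in c(0.3, 0.8, 1.5)) {
    dat <- make_series(K = K, delta_c = 0.9, a0 = 1e-8)
    d <- stamm_diagnostic(dat)
    expect_equal(d$slope, -K, tolerance = 1e-3)
    expect_equal(d$intercept, K * 0.9, tolerance = 1e-3)
    expect_equal(d$classification, "negative_slope")
  }
})

test_that("pure collision shielding classifies horizontal", {
  dat <- tibble::tibble(acceptor = "a", proton = "H", a0 = 0.001,
                        d0 = exp_d0, delta = 0.09 * exp_d0)
  d <- stamm_diagnostic(dat)
  expect_equal(d$classification, "horizontal")
  # noisy flat ratio stays horizontal at the test level
  noisy <- dat
  noisy$delta <- noisy$delta +
    withr::with_seed(41, stats::rnorm(9, 0, 1e-4))
  expect_equal(stamm_diagnostic(noisy)$classification, "horizontal")
})

test_that("convex series classifies positive slope", {
  dat <- tibble::tibble(acceptor = "a", proton = "H", a0 = 0.001,
                        d0 = exp_d0, delta = 0.5 * exp_d0^2)
  expect_equal(stamm_diagnostic(dat)$classification, "positive_slope")
  flat <- dat
  flat$delta <- rep(0.2, 9)
  expect_error(stamm_diagnostic(flat), "constant")
})

test_that("max-K selection follows the worked examples", {
  fits <- mstl_complex_fits()
  dnb <- select_best_k(fits[fits$acceptor == "1,3-DNB", ])
  expect_equal(dnb$best_K, 0.769)
  expect_equal(dnb$best_proton, "H2")
  py <- select_best_k(fits[fits$acceptor == "Py", ], exclude = "H2")
  expect_equal(py$best_K, 0.082)
  expect_equal(py$best_proton, "H4")
  expect_equal(py$excluded[[1]], "H2")
  # single passing proton returns itself
  one <- select_best_k(fits[fits$acceptor == "TA" & fits$proton == "HAld", ])
  expect_equal(one$best_K, 0.379)
})

test_that("selection is permutation invariant and honours diagnostics", {
  fits <- mstl_complex_fits()
  dnb <- fits[fits$acceptor == "1,3-DNB", ]
  shuffled <- select_best_k(dnb[c(3, 1, 2), ])
  expect_equal(shuffled, select_best_k(dnb))
  # diagnostics exclude non-complexing protons
  diag <- tibble::tibble(acceptor = "1,3-DNB", proton = c("H2", "H4", "H5"),
                         classification = c("positive_slope",
                                            "negative_slope",
                                            "horizontal"))
  sel <- select_best_k(dnb, diagnostics = diag)
  expect_equal(sel$best_proton, "H4")
  expect_setequal(sel$excluded[[1]], c("H2", "H5"))
  all_out <- diag
  all_out$classification <- "horizontal"
  expect_error(select_best_k(dnb, diagnostics = all_out), "No valid K")
})

test_that("K and delta_c orderings match the worked examples", {
  fits <- mstl_complex_fits()
  tests <- mstl_complex_tests()
  dnb_k <- rank_protons(fits[fits$acceptor == "1,3-DNB", ], tests = tests)
  expect_equal(dnb_k$order, "H2 > H5 > (H4, H6)")
  btf_k <- rank_protons(fits[fits$acceptor == "1,3-BTFMB", ], tests = tests)
  expect_equal(btf_k$order, "H5 > (H4, H6) > H2")
  dnb_dc <- rank_protons(fits[fits$acceptor == "1,3-DNB", ],
                         by = "delta_c", tests = tests)
  expect_equal(dnb_dc$order, "H5 > (H4, H6) > H2")
})

test_that("tie grouping merges equal values and accepted nulls", {
  fits <- tibble::tibble(acceptor = "x", proton = c("Ha", "Hb", "Hc"),
                         K = c(0.5, 0.3, 0.3))
  r <- rank_protons(fits)
  expect_equal(r$order, "Ha > (Hb, Hc)")
  expect_equal(r$groups[[1]], c("Ha", "(Hb, Hc)"))
  # an accepted pairwise null merges estimates beyond the tolerance
  tests <- tibble::tibble(acceptor = "x", null = "Ha = Hb",
                          parameter = "K", decision = "accept")
  expect_equal(rank_protons(fits, tests = tests)$order, "(Ha, Hb, Hc)")
  # a rejected null keeps numerically close values apart
  fits2 <- tibble::tibble(acceptor = "x", proton = c("Ha", "Hb"),
                          K = c(0.301, 0.3))
  tests2 <- tibble::tibble(acceptor = "x", null = "Ha = Hb",
                           parameter = "K", decision = "reject")
  expect_equal(rank_protons(fits2)$order, "(Ha, Hb)")
  expect_equal(rank_protons(fits2, tests = tests2)$order, "Ha > Hb")
})
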