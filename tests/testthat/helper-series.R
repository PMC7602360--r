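# Shared fixture builders: all synthetic, generated at test time.

exp_d0 <- seq(0.1, 0.9, by = 0.1)  # experimental titration design

make_series <- function(K = 0.8, delta_c = 0.8, a1 = 0, a2 = 0,
                        a0 = 0.001, d0 = exp_d0, noise_sd = 0,
                        seed = 1, proton = "H", acceptor = "acceptor") {
  truth <- shift_isotherm_aus(d0, K, delta_c, a1, a2, a0)
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(length(d0), 0, noise_sd))
  } else 0
  tibble::tibble(acceptor = acceptor, proton = proton, a0 = a0,
                 d0 = d0, delta = truth + noise)
}

# Independent oracle for the bound fraction: the complexed concentration
# solves K = c / ((a0 - c)(d0 - c)); located by bisection, fraction = c/a0.
oracle_bound_fraction <- function(K, a0, d0) {
  if (d0 == 0 || K == 0) return(0)
  g <- function(c) K * (a0 - c) * (d0 - c) - c
  c_root <- stats::uniroot(g, c(0, min(a0, d0) * (1 - 1e-12)),
                           tol = 1e-15)$root
  c_root / a0
}

# A fake bootstrap result with prescribed draws, for testing the
# comparison machinery in isolation.
fake_boot <- function(K, delta_c = K, proton = "H", B = length(K)) {
  structure(
    list(K = K, delta_c = delta_c,
         point = c(K = mean(K), delta_c = mean(delta_c)),
         B = B, seed = 0L, n_failed = 0L,
         acceptor = "acceptor", proton = proton),
    class = "binding_boot"
  )
}
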