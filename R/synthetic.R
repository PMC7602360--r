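# Seeded generator of synthetic titration datasets with the structure the
# analysis assumes: one shared true K per complex, per-proton delta_c and
# AUS coefficients reflecting offset geometry, additive Gaussian ppm noise.

#' Specify a synthetic titration scenario
#'
#' One acceptor whose protons share a single true association constant
#' but differ in complexation shift and AUS coefficients — the structure
#' an offset-stacked complex imposes. Noise on the shifts is iid Gaussian
#' in ppm: peak-position error at fixed acquisition settings is well
#' approximated as additive and homoscedastic. The default
#' `noise_sd = 0.002` ppm is consistent with the near-perfect fit quality
#' (R^2 >= 0.999) the experimental design achieves.
#'
#' @param true_K Shared association constant, 1/M.
#' @param protons A data frame with columns `proton`, `delta_c` (ppm),
#'   `a1`, `a2` (ppm/M); optional `equivalent` display label.
#' @param acceptor Acceptor label.
#' @param a0 Acceptor concentration, M (default 0.001).
#' @param d0 Donor grid, M (default the experimental design, 0.1-0.9 M in
#'   0.1 M steps).
#' @param noise_sd Gaussian noise standard deviation, ppm, `>= 0`.
#' @param seed Integer seed used by [simulate_titration()].
#' @return A `"scenario_spec"` list.
#' @export
scenario_spec <- function(true_K, protons, acceptor = "synthetic",
                          a0 = 0.001, d0 = seq(0.1, 0.9, by = 0.1),
                          noise_sd = 0.002, seed = 1) {
  protons <- tibble::as_tibble(protons)
  stopifnot(
    is.numeric(true_K), length(true_K) == 1L,
    nrow(protons) >= 1L,
    all(c("proton", "delta_c", "a1", "a2") %in% names(protons)),
    a0 > 0, all(d0 > 0), all(diff(sort(d0)) > 0),
    is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0
  )
  if (any(protons$a1 < 0) || any(protons$a2 < 0)) {
    stop("AUS coefficients must be >= 0.", call. = FALSE)
  }
  structure(
    list(true_K = true_K, protons = protons, acceptor = acceptor,
         a0 = a0, d0 = sort(d0), noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' Offset-complex scenario with graded shielding
#'
#' Encodes the offset-stacking gradient: protons farther from the donor
#' ring centre sense weaker ring current (smaller true `delta_c`) and
#' more free-donor collisions (larger `a2`). Both quantities are linearly
#' interpolated from the nearest to the farthest proton; `a1` is shared.
#'
#' @param n_protons Number of protons (positions 1 = nearest donor).
#' @param true_K Shared association constant, 1/M.
#' @param delta_c_near,delta_c_far True complexation shifts at the
#'   nearest/farthest proton, ppm; must satisfy
#'   `delta_c_near > delta_c_far >= 0`.
#' @param a2_near,a2_far AUS coefficients at the nearest/farthest proton,
#'   ppm/M; must satisfy `a2_far >= a2_near >= 0`.
#' @param a1 Shared noncomplexed-acceptor AUS coefficient, ppm/M.
#' @inheritParams scenario_spec
#' @return A `"scenario_spec"`.
#' @examples
#' sc <- offset_complex_scenario(3, true_K = 0.8,
#'                               delta_c_near = 0.8, delta_c_far = 0.2,
#'                               a2_near = 0.01, a2_far = 0.09)
#' sc$protons
#' @export
offset_complex_scenario <- function(n_protons = 3, true_K = 0.8,
                                    delta_c_near = 0.8, delta_c_far = 0.2,
                                    a2_near = 0.01, a2_far = 0.09,
                                    a1 = 0.09, acceptor = "offset",
                                    a0 = 0.001,
                                    d0 = seq(0.1, 0.9, by = 0.1),
                                    noise_sd = 0.002, seed = 1) {
  if (!(delta_c_near > delta_c_far && delta_c_far >= 0)) {
    stop("Need `delta_c_near > delta_c_far >= 0`.", call. = FALSE)
  }
  if (!(a2_far >= a2_near && a2_near >= 0)) {
    stop("Need `a2_far >= a2_near >= 0`.", call. = FALSE)
  }
  w <- if (n_protons == 1L) 0 else (seq_len(n_protons) - 1) / (n_protons - 1)
  protons <- tibble::tibble(
    proton = paste0("H", seq_len(n_protons)),
    delta_c = delta_c_near + w * (delta_c_far - delta_c_near),
    a1 = a1,
    a2 = a2_near + w * (a2_far - a2_near)
  )
  scenario_spec(true_K, protons, acceptor = acceptor, a0 = a0, d0 = d0,
                noise_sd = noise_sd, seed = seed)
}

#' Generate titration data from a scenario
#'
#' Noiseless shifts come from the AUS-extended isotherm at the scenario's
#' truth; seeded Gaussian noise (independent across points and protons)
#' is added on top. With `noise_sd = 0` the output equals
#' [shift_isotherm_aus()] exactly.
#'
#' @param spec A `"scenario_spec"`.
#' @param seed Optional override of the scenario seed.
#' @return A titration tibble: `acceptor`, `proton`, `a0`, `d0`, `delta`,
#'   plus `delta_true` (the noiseless shift) and, when present in the
#'   scenario, `equivalent`.
#' @examples
#' sc <- offset_complex_scenario(3, noise_sd = 0)
#' simulate_titration(sc)
#' @export
simulate_titration <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  base <- tidyr::expand_grid(
    proton = spec$protons$proton,
    d0 = spec$d0
  ) |>
    dplyr::left_join(spec$protons, by = "proton")
  truth <- shift_isotherm_aus(base$d0, spec$true_K, base$delta_c,
                              base$a1, base$a2, spec$a0)
  noise <- withr::with_seed(seed, stats::rnorm(nrow(base), 0, spec$noise_sd))
  out <- tibble::tibble(
    acceptor = spec$acceptor,
    proton = base$proton,
    a0 = spec$a0,
    d0 = base$d0,
    delta = truth + noise,
    delta_true = truth
  )
  if ("equivalent" %in% names(spec$protons)) {
    out <- dplyr::left_join(
      out, spec$protons[, c("proton", "equivalent")], by = "proton"
    )
  }
  as_titration(out)
}
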