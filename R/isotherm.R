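#' Fraction of acceptor bound in a 1:1 complex
#'
#' Closed-form complexed fraction of the acceptor for 1:1 association
#' \eqn{A + D \rightleftharpoons AD} with association constant
#' \eqn{K = [AD]/([A][D])} at initial concentrations `a0` (acceptor) and
#' `d0` (donor). The complexed concentration is the physical root of the
#' mass-balance quadratic
#' \deqn{K c^2 - (K a_0 + K d_0 + 1)\, c + K a_0 d_0 = 0,}
#' and the fraction is \eqn{c / a_0}. The root is evaluated in the
#' rationalised form
#' \deqn{c/a_0 = \frac{2 K d_0}{b + \sqrt{b^2 - 4 K^2 a_0 d_0}}, \quad
#'       b = K a_0 + K d_0 + 1,}
#' which avoids the catastrophic cancellation (and the division by `K`)
#' that the textbook \eqn{(b - \sqrt{\cdot})/(2 a_0 K)} form suffers as
#' \eqn{K \to 0}; it is exact at `K = 0` and remains defined for the
#' small negative `K` that unconstrained least squares can visit.
#'
#' @param K Association constant, 1/M. May be a vector; recycled against
#'   `d0`. Physically meaningful values are `K >= 0`, for which the result
#'   lies in `[0, 1]`; negative values are tolerated (they arise during
#'   unconstrained estimation) and yield negative fractions.
#' @param a0 Initial acceptor concentration, M. Scalar, `> 0`.
#' @param d0 Initial donor concentration(s), M, `>= 0`.
#'
#' @return Numeric vector of bound fractions, dimensionless.
#'
#' @examples
#' bound_fraction(K = 0.8, a0 = 0.001, d0 = c(0, 0.5))
#' @seealso [shift_isotherm()], [shift_isotherm_aus()]
#' @export
bound_fraction <- function(K, a0, d0) {
  if (!is.numeric(a0) || length(a0) != 1L || !is.finite(a0) || a0 <= 0) {
    stop("`a0` must be a single positive concentration (M).", call. = FALSE)
  }
  if (any(!is.finite(d0)) || any(d0 < 0)) {
    stop("`d0` must be finite and >= 0 (M).", call. = FALSE)
  }
  if (any(!is.finite(K))) {
    stop("`K` must be finite (1/M).", call. = FALSE)
  }
  b <- K * a0 + K * d0 + 1
  disc <- b^2 - 4 * K^2 * a0 * d0
  if (any(disc < 0)) {
    stop("Negative discriminant in the mass-balance quadratic; ",
         "inputs are outside the representable range.", call. = FALSE)
  }
  2 * K * d0 / (b + sqrt(disc))
}

#' Upfield shift predicted by the 1:1 binding isotherm
#'
#' Fast-exchange observed upfield shift \eqn{\Delta = \delta_A - \delta}
#' of an acceptor proton at donor concentration `d0`:
#' the bound fraction times the complexation shift
#' \eqn{\Delta_C = \delta_A - \delta_C} (the shift the proton would show
#' if fully complexed).
#'
#' @inheritParams bound_fraction
#' @param delta_c Complexation shift \eqn{\Delta_C}, ppm.
#' @return Predicted upfield shifts, ppm.
#' @examples
#' shift_isotherm(d0 = seq(0.1, 0.9, 0.1), K = 0.8, delta_c = 0.8, a0 = 0.001)
#' @export
shift_isotherm <- function(d0, K, delta_c, a0) {
  bound_fraction(K, a0, d0) * delta_c
}

#' Upfield shift under additional unspecific shielding (AUS)
#'
#' Extends the 1:1 isotherm with the AUS contributions of non-complexing
#' collisions by excess free donor: coefficient `a1` (ppm/M) acts on the
#' noncomplexed acceptor and `a2` on the complexed acceptor, each scaling
#' linearly with `d0`. The observed upfield shift becomes
#' \deqn{\Delta = f(K, a_0, d_0)\,(\Delta_C - a_1 d_0 + a_2 d_0) + a_1 d_0,}
#' with \eqn{f} the bound fraction. With `a1 = a2 = 0` this reduces exactly
#' to [shift_isotherm()].
#'
#' @inheritParams shift_isotherm
#' @param a1,a2 AUS coefficients, ppm/M, `>= 0`.
#' @return Predicted upfield shifts, ppm.
#' @examples
#' shift_isotherm_aus(d0 = 0.5, K = 0.8, delta_c = 0.8,
#'                    a1 = 0.09, a2 = 0.01, a0 = 0.001)
#' @export
shift_isotherm_aus <- function(d0, K, delta_c, a1, a2, a0) {
  if (any(a1 < 0) || any(a2 < 0)) {
    stop("AUS coefficients `a1`, `a2` must be >= 0 (ppm/M).", call. = FALSE)
  }
  bound_fraction(K, a0, d0) * (delta_c - a1 * d0 + a2 * d0) + a1 * d0
}

#' AUS-shifted reference chemical shifts
#'
#' Under AUS both reference shifts move upfield with donor concentration:
#' the noncomplexed-acceptor shift becomes
#' \eqn{\delta_{A(AUS)} = \delta_A - a_1 d_0} and the fully-complexed shift
#' \eqn{\delta_{C(AUS)} = (\delta_A - \Delta_C) - a_2 d_0}. The observed
#' shift interpolates between these moving references, which is why naive
#' isotherm fitting of AUS-affected data is biased.
#'
#' @param delta_a Chemical shift of the noncomplexed acceptor proton, ppm.
#' @param delta_c Complexation shift \eqn{\Delta_C}, ppm.
#' @inheritParams shift_isotherm_aus
#' @return A tibble with columns `d0`, `delta_a_aus`, `delta_c_aus` (ppm).
#' @examples
#' aus_reference_shifts(delta_a = 8, delta_c = 0.8,
#'                      a1 = 0.09, a2 = 0.05, d0 = c(0, 0.5))
#' @export
aus_reference_shifts <- function(delta_a, delta_c, a1, a2, d0) {
  if (any(d0 < 0)) stop("`d0` must be >= 0 (M).", call. = FALSE)
  if (any(a1 < 0) || any(a2 < 0)) {
    stop("AUS coefficients `a1`, `a2` must be >= 0 (ppm/M).", call. = FALSE)
  }
  tibble::tibble(
    d0 = d0,
    delta_a_aus = delta_a - a1 * d0,
    delta_c_aus = (delta_a - delta_c) - a2 * d0
  )
}

# Validates AUS coefficients against the sweep cap (default the rounded
# average collision shielding of mesitylene, 0.09 ppm/M).
check_aus_cap <- function(a1, a2, cap = 0.09) {
  if (any(a1 < 0) || any(a2 < 0) || any(a1 > cap) || any(a2 > cap)) {
    stop("AUS coefficients must lie in [0, ", cap, "] ppm/M.", call. = FALSE)
  }
  invisible(TRUE)
}
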