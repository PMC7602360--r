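# Diagnostics for near-zero-K protons, best-estimate selection, and
# K-order / delta_c-order geometry ranking.

#' Slope diagnostic for genuine complexation
#'
#' Ordinary least squares of \eqn{\Delta/d_0} on \eqn{\Delta} (the
#' Scatchard-type rearrangement of the dilute-acceptor isotherm, for which
#' \eqn{\Delta/d_0 = K\Delta_C - K\Delta}). A proton that genuinely
#' reports 1:1 complexation gives a line of slope \eqn{\approx -K};
#' shifts that are purely collision shielding grow linearly in `d0`, so
#' \eqn{\Delta/d_0} is flat (or convex data give a positive slope) and
#' the apparent `K` is near zero or negative. Classification:
#' `"horizontal"` when the two-sided t-test of zero slope is not rejected
#' at `alpha`, otherwise the sign of the slope decides.
#'
#' @param data A titration table; every `d0` must be positive, at least 3
#'   points per series.
#' @param alpha Significance level for the zero-slope test.
#' @return A tibble, one row per series: `acceptor`, `proton`, `slope`,
#'   `intercept`, `p_slope`, `classification` (`"negative_slope"`,
#'   `"horizontal"`, `"positive_slope"`), `alpha`.
#' @examples
#' d0 <- seq(0.1, 0.9, 0.1)
#' dat <- data.frame(a0 = 1e-8, d0 = d0,
#'                   delta = shift_isotherm(d0, 0.8, 0.8, 1e-8))
#' stamm_diagnostic(dat)
#' @export
stamm_diagnostic <- function(data, alpha = 0.05) {
  series <- split_series(data)
  purrr::map(series, function(s) {
    if (nrow(s) < 3L) {
      stop("Series ", s$acceptor[1], "/", s$proton[1],
           " has fewer than 3 points.", call. = FALSE)
    }
    if (any(s$d0 <= 0)) {
      stop("Series ", s$acceptor[1], "/", s$proton[1],
           " has nonpositive `d0`; the ratio plot needs d0 > 0.",
           call. = FALSE)
    }
    if (stats::sd(s$delta) == 0) {
      stop("Series ", s$acceptor[1], "/", s$proton[1],
           " has constant shifts; the diagnostic is degenerate.",
           call. = FALSE)
    }
    m <- stats::lm(I(delta / d0) ~ delta, data = s)
    # summary warns on numerically perfect fits; handled explicitly below
    cf <- suppressWarnings(summary(m)$coefficients)
    slope <- cf["delta", "Estimate"]
    p <- cf["delta", "Pr(>|t|)"]
    if (is.nan(p)) {
      # Residual variance ~ 0: an exact line is decisively sloped, an
      # exact constant is decisively horizontal.
      p <- if (abs(slope) > 1e-8 * (1 + abs(cf["(Intercept)", "Estimate"]))) 0 else 1
    }
    cls <- if (p >= alpha) "horizontal"
           else if (slope < 0) "negative_slope" else "positive_slope"
    tibble::tibble(
      acceptor = s$acceptor[1], proton = s$proton[1],
      slope = slope, intercept = cf["(Intercept)", "Estimate"],
      p_slope = p, classification = cls, alpha = alpha
    )
  }) |>
    dplyr::bind_rows()
}

#' Select the best association-constant estimate per acceptor
#'
#' Unmodelled collision shielding only ever depresses apparent `K`, so of
#' the per-proton estimates of one complex the largest is the least
#' biased and is selected as the best estimate. Protons whose ratio-plot
#' diagnostic is `"horizontal"` or `"positive_slope"` (no evidence of
#' genuine complexation; near-zero or negative `K`) are excluded first,
#' as are any listed in `exclude`.
#'
#' @param fits A tibble with columns `acceptor`, `proton`, `K` (e.g. from
#'   [fit_binding()] or [mstl_complex_fits()]).
#' @param diagnostics Optional [stamm_diagnostic()] output; matched by
#'   `(acceptor, proton)`.
#' @param exclude Optional character vector of proton labels to exclude
#'   regardless of diagnostics.
#' @return A tibble, one row per acceptor: `acceptor`, `best_K`,
#'   `best_proton`, `excluded` (list-column of excluded proton labels).
#'   Errors if every proton of an acceptor is excluded.
#' @examples
#' fits <- mstl_complex_fits()
#' select_best_k(fits[fits$acceptor == "Py", ], exclude = "H2")
#' @export
select_best_k <- function(fits, diagnostics = NULL, exclude = character(0)) {
  stopifnot(all(c("acceptor", "proton", "K") %in% names(fits)))
  fits <- tibble::as_tibble(fits)
  fits$.excluded <- fits$proton %in% exclude
  if (!is.null(diagnostics)) {
    d <- diagnostics[, c("acceptor", "proton", "classification")]
    fits <- dplyr::left_join(fits, d, by = c("acceptor", "proton"))
    fits$.excluded <- fits$.excluded |
      (!is.na(fits$classification) &
         fits$classification != "negative_slope")
  }
  fits |>
    dplyr::group_by(.data$acceptor) |>
    dplyr::group_modify(function(g, key) {
      kept <- g[!g$.excluded, ]
      if (nrow(kept) == 0L) {
        stop("No valid K estimate for acceptor ", key$acceptor,
             ": every proton was excluded by the diagnostics.",
             call. = FALSE)
      }
      i <- which.max(kept$K)
      tibble::tibble(
        best_K = kept$K[i],
        best_proton = kept$proton[i],
        excluded = list(g$proton[g$.excluded])
      )
    }) |>
    dplyr::ungroup()
}

#' Rank protons by estimated K or complexation shift
#'
#' Orders the protons of each acceptor by the chosen estimate,
#' descending, grouping ties. Protons with larger `K` estimates sit
#' closer to the stacking donor (collision shielding biases `K` downward
#' more strongly for remote protons), so the `K` order is the preferred
#' geometry readout; the `delta_c` order is computed for comparison but
#' can be scrambled by the same bias.
#'
#' Ties are grouped, in order of precedence, when (1) a supplied pairwise
#' `tests` table accepted the null for the pair, or (2) the estimates
#' differ by at most `tie_tolerance`. Chemically equivalent protons
#' (identical `equivalent` label in `fits`) are displayed as one group
#' member, e.g. `"(H4, H6)"`.
#'
#' @param fits A tibble with `acceptor`, `proton`, and the ranking column
#'   (`K` or `delta_c`); an optional `equivalent` column holds display
#'   labels for chemically equivalent proton sets.
#' @param by `"K"` or `"delta_c"`.
#' @param tie_tolerance Absolute difference at or below which two
#'   adjacent estimates are tied (default 0.005, in the units of `by`).
#' @param tests Optional pairwise decisions (e.g. [compare_protons()] or
#'   [mstl_complex_tests()] output): columns `acceptor`, `null`
#'   (`"Hi = Hj"`), `parameter`, `decision`. Pairs with decision
#'   `"accept"` are tied; pairs with `"reject"` are never merged by the
#'   tolerance.
#' @return A tibble, one row per acceptor: `acceptor`, `order` (the
#'   rendered string, e.g. `"H2 > H5 > (H4, H6)"`), `groups` (list-column
#'   of character vectors of proton labels, strongest first).
#' @examples
#' fits <- mstl_complex_fits()
#' rank_protons(fits[fits$acceptor == "1,3-DNB", ],
#'              tests = mstl_complex_tests())
#' @export
rank_protons <- function(fits, by = c("K", "delta_c"), tie_tolerance = 0.005,
                         tests = NULL) {
  by <- match.arg(by)
  stopifnot(all(c("acceptor", "proton", by) %in% names(fits)))
  fits <- tibble::as_tibble(fits)
  if (!"equivalent" %in% names(fits)) fits$equivalent <- NA_character_
  fits |>
    dplyr::group_by(.data$acceptor) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2L) {
        lab <- display_label(g$proton[1], g$equivalent[1])
        return(tibble::tibble(order = lab, groups = list(lab)))
      }
      g <- g[order(g[[by]], decreasing = TRUE), ]
      tested <- NULL
      if (!is.null(tests)) {
        tested <- tests[tests$acceptor == key$acceptor &
                          tests$parameter == by, , drop = FALSE]
      }
      grp <- integer(nrow(g))
      grp[1] <- 1L
      for (i in 2:nrow(g)) {
        tie <- pair_tied(g$proton[i - 1], g$proton[i],
                         g[[by]][i - 1], g[[by]][i],
                         tested, tie_tolerance)
        grp[i] <- if (tie) grp[i - 1] else grp[i - 1] + 1L
      }
      labels <- vapply(split(seq_len(nrow(g)), grp), function(idx) {
        members <- unlist(lapply(idx, function(j) {
          strsplit(display_label(g$proton[j], g$equivalent[j]), ", ")[[1]]
        }))
        if (length(members) > 1L) {
          paste0("(", paste(members, collapse = ", "), ")")
        } else members
      }, character(1))
      tibble::tibble(order = paste(labels, collapse = " > "),
                     groups = list(unname(labels)))
    }) |>
    dplyr::ungroup()
}

display_label <- function(proton, equivalent) {
  if (!is.na(equivalent) && nzchar(equivalent)) equivalent else proton
}

# Tie rule: an explicit pairwise test decision wins; otherwise the
# absolute tolerance.
pair_tied <- function(p1, p2, v1, v2, tested, tol) {
  if (!is.null(tested) && nrow(tested) > 0L) {
    hit <- tested$null %in% c(paste(p1, "=", p2), paste(p2, "=", p1))
    if (any(hit)) return(tested$decision[hit][1] == "accept")
  }
  abs(v1 - v2) <= tol
}
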