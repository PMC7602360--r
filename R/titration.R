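#' Validate and normalise a titration table
#'
#' Canonical tidy layout for proton-NMR titration data: one row per
#' (acceptor, proton, donor concentration), columns
#' `acceptor`, `proton`, `a0` (M), `d0` (M) and either the upfield shift
#' `delta` (ppm) or the raw shifts `delta_a` (noncomplexed acceptor, ppm)
#' and `delta_obs` (observed in donor presence, ppm), from which
#' `delta = delta_a - delta_obs` is derived. Shifts are stored with the
#' positive-upfield sign convention.
#'
#' Checks per series (one series = one `(acceptor, proton)` pair):
#' a single positive `a0`, nonnegative pairwise-distinct `d0`, finite
#' shifts, and — when both layouts are present — exact agreement
#' `delta == delta_a - delta_obs`.
#'
#' @param data A data frame in either layout. A missing `acceptor` or
#'   `proton` column is filled with a single placeholder label.
#' @return A tibble with columns `acceptor`, `proton`, `a0`, `d0`, `delta`
#'   (plus `delta_a`, `delta_obs` when supplied), validated.
#' @examples
#' as_titration(data.frame(a0 = 0.001, d0 = c(0.1, 0.2, 0.3),
#'                         delta_a = 8, delta_obs = c(7.98, 7.96, 7.95)))
#' @export
as_titration <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"acceptor" %in% names(data)) data$acceptor <- "acceptor"
  if (!"proton" %in% names(data)) data$proton <- "H"
  if (!all(c("a0", "d0") %in% names(data))) {
    stop("Titration data needs `a0` and `d0` columns (M).", call. = FALSE)
  }
  has_delta <- "delta" %in% names(data)
  has_raw <- all(c("delta_a", "delta_obs") %in% names(data))
  if (!has_delta && !has_raw) {
    stop("Titration data needs a `delta` column (ppm) or raw-shift ",
         "columns `delta_a` and `delta_obs`.", call. = FALSE)
  }
  num_cols <- intersect(
    c("a0", "d0", "delta", "delta_a", "delta_obs"), names(data)
  )
  for (cl in num_cols) {
    if (!is.numeric(data[[cl]]) || any(!is.finite(data[[cl]]))) {
      bad <- if (is.numeric(data[[cl]])) which(!is.finite(data[[cl]])) else seq_len(nrow(data))
      stop("Non-numeric or missing values in `", cl, "` (rows ",
           paste(utils::head(bad, 5L), collapse = ", "), ").", call. = FALSE)
    }
  }
  if (has_raw && !has_delta) {
    data$delta <- data$delta_a - data$delta_obs
  } else if (has_raw && has_delta) {
    if (any(abs(data$delta - (data$delta_a - data$delta_obs)) > 0)) {
      stop("`delta` disagrees with `delta_a - delta_obs`.", call. = FALSE)
    }
  }
  split_idx <- split(seq_len(nrow(data)),
                     paste(data$acceptor, data$proton, sep = "\r"))
  for (idx in split_idx) {
    key <- paste0(data$acceptor[idx[1]], "/", data$proton[idx[1]])
    a0 <- unique(data$a0[idx])
    if (length(a0) != 1L) {
      stop("Series ", key, " has more than one `a0` value.", call. = FALSE)
    }
    if (a0 <= 0) stop("Series ", key, " has `a0` <= 0.", call. = FALSE)
    if (any(data$d0[idx] < 0)) {
      stop("Series ", key, " has negative `d0`.", call. = FALSE)
    }
    if (anyDuplicated(data$d0[idx])) {
      stop("Series ", key, " has duplicated `d0` values.", call. = FALSE)
    }
  }
  data
}

#' Read a titration CSV
#'
#' Reads a comma-separated titration table in either the `delta` or the
#' raw-shift layout (see [as_titration()]) and returns the validated tidy
#' table. Malformed files fail with the offending series or column named.
#'
#' @param path Path to a CSV file with a header row.
#' @param ... Passed on to [readr::read_csv()].
#' @return A validated titration tibble.
#' @export
read_titration_csv <- function(path, ...) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  data <- readr::read_csv(path, show_col_types = FALSE, ...)
  as_titration(data)
}

#' Write a titration table to CSV
#'
#' @param data A titration tibble (validated with [as_titration()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(data, path) {
  readr::write_csv(as_titration(data), path)
  invisible(path)
}

# One series per (acceptor, proton), each validated; fitting additionally
# requires >= 3 points and >= 2 distinct positive d0.
split_series <- function(data) {
  data <- as_titration(data)
  keys <- unique(data[, c("acceptor", "proton")])
  purrr::map(seq_len(nrow(keys)), function(i) {
    data[data$acceptor == keys$acceptor[i] & data$proton == keys$proton[i], ]
  })
}

check_fittable <- function(series) {
  if (nrow(series) < 3L) {
    stop("Series ", series$acceptor[1], "/", series$proton[1],
         " has fewer than 3 points; the two-parameter isotherm fit is ",
         "under-determined.", call. = FALSE)
  }
  if (length(unique(series$d0[series$d0 > 0])) < 2L) {
    stop("Series ", series$acceptor[1], "/", series$proton[1],
         " needs at least 2 distinct positive `d0` values.", call. = FALSE)
  }
  invisible(TRUE)
}
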