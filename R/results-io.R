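#' Write analysis results to CSV or JSON
#'
#' Serialises a results table (fits, bias records, test decisions,
#' rankings) with a stable column order. Numeric columns are rounded to 3
#' significant digits by default; pass `digits = NA` for full precision.
#'
#' @param x A data frame of results. List-columns are dropped with a
#'   message (they hold model objects, not serialisable records).
#' @param path Output path; the format is taken from the extension unless
#'   `format` is given.
#' @param format `"csv"` or `"json"`; default inferred from `path`.
#' @param digits Significant digits for numeric columns; `NA` keeps full
#'   precision.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = NULL, digits = 3) {
  x <- tibble::as_tibble(x)
  is_list <- vapply(x, is.list, logical(1))
  if (any(is_list)) {
    message("Dropping list-column(s): ",
            paste(names(x)[is_list], collapse = ", "))
    x <- x[, !is_list, drop = FALSE]
  }
  if (!is.na(digits)) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], signif, digits = digits)
  }
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    readr::write_csv(x, path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("JSON output needs the jsonlite package.", call. = FALSE)
    }
    jsonlite::write_json(x, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
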