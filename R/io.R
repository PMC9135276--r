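# Tabular I/O: long-format plate tables are the canonical interchange.

#' Read and validate a long-format plate table
#'
#' The canonical schema is one row per well with columns `well`,
#' `condition`, `dose_M`, `replicate`, `value`, and optionally `channel`.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Plate table `%s` does not exist.", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("well", "condition", "dose_M", "replicate", "value"),
                sprintf("plate table `%s`", path))
  if (!is.numeric(df$dose_M)) {
    abort(sprintf("Column `dose_M` of `%s` must be numeric (molar doses).", path))
  }
  if (!is.numeric(df$value)) {
    abort(sprintf("Column `value` of `%s` must be numeric.", path))
  }
  key <- if ("channel" %in% names(df)) paste(df$well, df$channel) else df$well
  if (anyDuplicated(key)) {
    abort(sprintf("Duplicate well%s rows in `%s`.",
                  if ("channel" %in% names(df)) " x channel" else "", path))
  }
  as_tibble(df)
}

#' Convert a wide 8 x 12 plate layout to the canonical long format
#'
#' @param mat An 8 x 12 matrix (rows A-H, columns 1-12) of values.
#' @param condition,dose_M,replicate Metadata recycled over wells; each may
#'   be a scalar or an 8 x 12 matrix laid out like `mat`.
#' @return Long tibble with the canonical plate columns.
#' @export
plate_wide_to_long <- function(mat, condition = NA_character_, dose_M = NA_real_,
                               replicate = 1L) {
  stopifnot(is.matrix(mat), nrow(mat) == 8, ncol(mat) == 12)
  expand <- function(x) if (is.matrix(x)) as.vector(x) else rep(x, 96)
  tibble(
    well = paste0(rep(LETTERS[1:8], times = 12), rep(1:12, each = 8)),
    condition = expand(condition),
    dose_M = expand(dose_M),
    replicate = expand(replicate),
    value = as.vector(mat)
  )
}

#' Write ground truth (or any report) as JSON
#'
#' Matrices and rasters are omitted; tibbles become row-wise records.
#'
#' @param truth A list (e.g. the `truth` element of a generator result).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  slim <- purrr::map(truth, function(x) if (is.matrix(x)) NULL else x)
  slim <- slim[!vapply(slim, is.null, logical(1))]
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
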