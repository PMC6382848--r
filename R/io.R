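CELL_TABLE_HEADER <- c(
  cell_id = "cell_id", lon = "lon", lat = "lat", tree = "T", grass = "G",
  mar = "MAR", si = "SI", lambda_w = "lambda_w", alpha_w = "alpha_w",
  log_afi = "log_afi", mar_range = "mar_range"
)

#' Write a cell table to CSV
#'
#' Writes the analysis table with the fixed exchange header
#' `cell_id, lon, lat, T, G, MAR, SI, lambda_w, alpha_w, log_afi, mar_range`.
#'
#' @param cells A cell table (internal column names, e.g. from
#'   [build_cell_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  missing_cols <- setdiff(names(CELL_TABLE_HEADER), names(cells))
  if (length(missing_cols) > 0) {
    abort(paste0("cell table is missing column(s): ",
      paste(missing_cols, collapse = ", ")), class = "tgbcover_error_input")
  }
  out <- cells[names(CELL_TABLE_HEADER)]
  names(out) <- unname(CELL_TABLE_HEADER)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a cell table from CSV
#'
#' Inverse of [write_cell_table()]: reads the fixed exchange header back into
#' internal column names (`tree`, `grass`, `mar`, ...).
#'
#' @param path CSV file path.
#' @return A tibble with `mar_range` as a factor.
#' @export
read_cell_table <- function(path) {
  raw <- read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(unname(CELL_TABLE_HEADER), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("file is missing column(s): ",
      paste(missing_cols, collapse = ", ")), class = "tgbcover_error_input")
  }
  out <- raw[unname(CELL_TABLE_HEADER)]
  names(out) <- names(CELL_TABLE_HEADER)
  out$mar_range <- factor(out$mar_range, levels = c("R1", "R2", "R3", "excluded"))
  out$mar_range <- droplevels(out$mar_range)
  tibble::as_tibble(out)
}
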