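#' Average annual burnt-area fraction
#'
#' Aggregates monthly burnt-area fractions to the average annual burnt
#' fraction `ba`. Within a year the monthly fractions are summed and clipped
#' at 1 (a patch re-burning within the same year is counted once); `ba` is
#' the mean of the yearly fractions over the record.
#'
#' @param monthly A data frame with columns `year`, `month`, `burnt_fraction`
#'   (in \[0, 1\]) and optionally `cell_id`.
#' @return A tibble with column `ba` (y^-1), one row per cell.
#' @export
#' @examples
#' monthly <- tibble::tibble(
#'   year = c(1, 1, 2), month = c(7, 8, 7),
#'   burnt_fraction = c(0.1, 0.1, 0.4)
#' )
#' annual_burnt_fraction(monthly) # (0.2 + 0.4) / 2 = 0.3
annual_burnt_fraction <- function(monthly) {
  need <- c("year", "month", "burnt_fraction")
  if (!all(need %in% names(monthly))) {
    abort("`monthly` needs columns year, month, burnt_fraction.",
      class = "tgbcover_error_input"
    )
  }
  bf <- monthly$burnt_fraction
  if (any(!is.finite(bf)) || any(bf < 0) || any(bf > 1)) {
    abort("burnt fractions must lie in [0, 1].", class = "tgbcover_error_input")
  }
  grp <- intersect("cell_id", names(monthly))
  monthly |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "year")))) |>
    dplyr::summarise(yearly = min(1, sum(.data$burnt_fraction)), .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(ba = mean(.data$yearly), .groups = "drop")
}

#' Average fire interval from burnt-area fraction
#'
#' The average fire interval is the expected fire return time,
#' `afi = 1 / (ba + epsilon)`. The small regularization constant `epsilon`
#' (default 0.0001 y^-1) caps the interval of unburnt cells (`ba = 0`) at
#' 10,000 years instead of infinity. Because fire intervals span several
#' orders of magnitude, `log_afi = log10(afi)` is the variable used in the
#' cover models.
#'
#' @param ba Numeric vector of average annual burnt fractions (>= 0).
#' @param epsilon Positive regularization constant (y^-1).
#' @return A tibble with columns `ba`, `afi` (years) and `log_afi`.
#' @export
#' @examples
#' fire_interval(c(0, 0.1999, 0.9999))
fire_interval <- function(ba, epsilon = 1e-4) {
  if (!is.numeric(ba) || any(!is.finite(ba)) || any(ba < 0)) {
    abort("`ba` must be non-negative and finite.", class = "tgbcover_error_input")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    abort("`epsilon` must be a single positive number.", class = "tgbcover_error_param")
  }
  afi <- 1 / (ba + epsilon)
  tibble::tibble(ba = ba, afi = afi, log_afi = log10(afi))
}
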