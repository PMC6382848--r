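#' Monthly rainfall climatology
#'
#' Averages, over the years of record, the rainfall total of each calendar
#' month. The resulting 12-value climatology is the basis of the seasonality
#' index and of wet-season detection.
#'
#' @param daily A data frame of daily rainfall with columns `year`, `doy`
#'   (1-365) and `depth` (mm), and optionally `cell_id` for multi-cell input.
#'   Only complete 365-day years are accepted.
#' @return A tibble with columns `month` (1-12) and `mean_monthly`
#'   (mm month^-1), one set of 12 rows per cell (`cell_id` retained when
#'   present). The per-cell annual mean (mm y^-1) is the sum of the 12 values.
#' @export
#' @examples
#' daily <- simulate_daily_rainfall(n_years = 2, seed = 1)
#' monthly_climatology(daily)
monthly_climatology <- function(daily) {
  check_daily(daily)
  grp <- intersect("cell_id", names(daily))
  daily |>
    dplyr::mutate(month = doy_month(.data$doy)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "year", "month")))) |>
    dplyr::summarise(total = sum(.data$depth), .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "month")))) |>
    dplyr::summarise(mean_monthly = mean(.data$total), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "month"))))
}

#' Mean annual rainfall
#'
#' @inheritParams monthly_climatology
#' @return A tibble with column `mar` (mm y^-1), one row per cell.
#' @export
#' @examples
#' daily <- simulate_daily_rainfall(n_years = 3, seed = 1)
#' mean_annual_rainfall(daily)
mean_annual_rainfall <- function(daily) {
  check_daily(daily)
  grp <- intersect("cell_id", names(daily))
  daily |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "year")))) |>
    dplyr::summarise(total = sum(.data$depth), .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(mar = mean(.data$total), .groups = "drop")
}

#' Walsh-Lawler rainfall seasonality index
#'
#' SI is the sum of absolute deviations of the climatological monthly rainfall
#' from the uniform monthly share, divided by the annual total:
#' \deqn{SI = \frac{1}{R} \sum_{m=1}^{12} \left| x_m - R/12 \right|}
#' It is 0 when rainfall is spread evenly over the year and 22/12 (about 1.83)
#' when the entire annual total falls in a single month.
#'
#' @param clim A monthly climatology as returned by [monthly_climatology()]:
#'   columns `month` and `mean_monthly`, optionally `cell_id`.
#' @return A tibble with column `si`, one row per cell.
#' @export
#' @examples
#' clim <- tibble::tibble(month = 1:12, mean_monthly = c(1200, rep(0, 11)))
#' seasonality_index(clim) # 22/12
seasonality_index <- function(clim) {
  per_cell(clim, function(x, ...) {
    check_clim(x)
    r <- sum(x$mean_monthly)
    if (r <= 0) {
      abort("seasonality index is undefined for a zero annual total.",
        class = "tgbcover_error_zero_rainfall"
      )
    }
    tibble::tibble(si = sum(abs(x$mean_monthly - r / 12)) / r)
  })
}

check_clim <- function(clim, call = rlang::caller_env()) {
  if (!all(c("month", "mean_monthly") %in% names(clim))) {
    abort("climatology needs columns `month` and `mean_monthly`.",
      class = "tgbcover_error_input", call = call
    )
  }
  if (nrow(clim) != 12 || !setequal(clim$month, 1:12)) {
    abort("climatology must have exactly one row per month 1..12.",
      class = "tgbcover_error_input", call = call
    )
  }
  if (any(clim$mean_monthly < 0)) {
    abort("monthly rainfall must be non-negative.",
      class = "tgbcover_error_input", call = call
    )
  }
  invisible(clim)
}

#' Wet-season detection from a monthly climatology
#'
#' A month belongs to the wet season when its climatological rainfall exceeds
#' a fraction `p_thr` of the climatological mean monthly rainfall (annual mean
#' divided by 12); the comparison is strict, so ties count as dry. Wet months
#' need not be contiguous. The wet-season length `l_w` is the sum of the civil
#' calendar lengths of the wet months.
#'
#' @inheritParams seasonality_index
#' @param p_thr Fraction of the mean monthly rainfall above which a month is
#'   wet; strictly between 0 and 1 (default 0.5).
#' @return A tibble, one row per cell, with `wet_months` (list column of
#'   integer month indices), `n_wet_months`, and `l_w` (days). A cell with a
#'   zero annual total gets an empty wet season and `l_w = 0`, with a warning.
#' @export
#' @examples
#' clim <- tibble::tibble(month = 1:12, mean_monthly = c(rep(100, 5), rep(1, 7)))
#' wet_season(clim)
wet_season <- function(clim, p_thr = 0.5) {
  if (!is.numeric(p_thr) || length(p_thr) != 1 || is.na(p_thr) ||
    p_thr <= 0 || p_thr >= 1) {
    abort("`p_thr` must be a single number strictly between 0 and 1.",
      class = "tgbcover_error_param"
    )
  }
  per_cell(clim, function(x, ...) {
    check_clim(x)
    x <- dplyr::arrange(x, .data$month)
    r <- sum(x$mean_monthly)
    if (r <= 0) {
      warn("zero annual rainfall: empty wet season (l_w = 0).")
      return(tibble::tibble(
        wet_months = list(integer(0)), n_wet_months = 0L, l_w = 0L
      ))
    }
    wet <- which(x$mean_monthly > p_thr * r / 12)
    tibble::tibble(
      wet_months = list(as.integer(wet)),
      n_wet_months = length(wet),
      l_w = sum(MONTH_LENGTHS[wet])
    )
  })
}

#' Wet-season length implied by the seasonality index
#'
#' Linear mapping from SI to an alternative wet-season length:
#' `l_w_si = 365/12 * (11 * (1 - si / 1.83) + 1)`, i.e. 365 d at SI = 0 and
#' about 30.4 d at SI = 1.83. Used to calibrate the wet-month threshold
#' `p_thr` (see [calibrate_pthr()]).
#'
#' @param si Numeric vector of seasonality indices in \[0, 22/12\].
#' @return Numeric vector of lengths in days.
#' @export
#' @examples
#' lw_from_si(c(0, 1.83))
lw_from_si <- function(si) {
  if (!is.numeric(si) || any(is.na(si)) || any(si < 0 | si > SI_MAX + 1e-12)) {
    abort("`si` must lie in [0, 22/12].", class = "tgbcover_error_param")
  }
  365 / 12 * (11 * (1 - si / 1.83) + 1)
}

#' Wet-day intensity and frequency statistics
#'
#' Within the wet-season months, a wet day is a day whose rainfall exceeds
#' `wet_day_threshold` (default 0.1 mm d^-1, guarding against measurement
#' noise). The statistics returned are:
#' * `alpha_w`: mean rainfall depth over all wet days (mm d^-1),
#' * `lambda_w`: average annual number of wet days divided by `l_w` (d^-1),
#' * `mar_w`: mean annual rainfall total within the wet months (mm y^-1),
#' * `c`: the closing term of the water balance
#'   `mar_w = alpha_w * lambda_w * l_w + c`, i.e. the mean annual sub-threshold
#'   rainfall inside the wet season. The identity holds by construction.
#'
#' @param daily A single-cell daily rainfall data frame (columns `year`,
#'   `doy`, `depth`).
#' @param wet_months Integer vector of wet-season month indices (1-12),
#'   typically from [wet_season()]. Must be non-empty.
#' @param wet_day_threshold Positive depth (mm d^-1) above which a day is wet.
#' @return A one-row tibble with `mar_w`, `alpha_w`, `lambda_w`, `c`, `l_w`
#'   and `n_wet_days` (average per year). If no day exceeds the threshold,
#'   `alpha_w` is `NA` (flagged by a warning), `lambda_w = 0` and `c = mar_w`.
#' @export
#' @examples
#' daily <- simulate_daily_rainfall(n_years = 5, seed = 1)
#' wet_day_stats(daily, wet_months = c(11, 12, 1, 2, 3))
wet_day_stats <- function(daily, wet_months, wet_day_threshold = 0.1) {
  check_daily(daily)
  if (has_cell(daily) && length(unique(daily$cell_id)) > 1) {
    abort("`wet_day_stats()` takes a single cell; use `rainfall_metrics()` for grids.",
      class = "tgbcover_error_input"
    )
  }
  if (length(wet_months) == 0) {
    abort("`wet_months` must be non-empty.", class = "tgbcover_error_param")
  }
  wet_months <- as.integer(wet_months)
  if (any(wet_months < 1L | wet_months > 12L) || anyDuplicated(wet_months)) {
    abort("`wet_months` must be distinct month indices in 1..12.",
      class = "tgbcover_error_param"
    )
  }
  if (!is.numeric(wet_day_threshold) || wet_day_threshold <= 0) {
    abort("`wet_day_threshold` must be positive.", class = "tgbcover_error_param")
  }
  mat <- daily_to_matrix(daily)
  tibble::as_tibble(
    wet_stats_from_matrix(mat, wet_months, wet_day_threshold)
  )
}

# core wet-day computation on a 365 x n_years depth matrix
wet_stats_from_matrix <- function(mat, wet_months, wet_day_threshold) {
  n_years <- ncol(mat)
  l_w <- sum(MONTH_LENGTHS[wet_months])
  in_wet <- MONTH_OF_DOY %in% wet_months
  wet_depths <- mat[in_wet, , drop = FALSE]
  mar_w <- sum(wet_depths) / n_years
  is_wet_day <- wet_depths > wet_day_threshold
  n_wet_total <- sum(is_wet_day)
  if (n_wet_total == 0) {
    warn("no day exceeds the wet-day threshold: alpha_w is undefined (NA).")
    alpha_w <- NA_real_
    lambda_w <- 0
  } else {
    alpha_w <- sum(wet_depths[is_wet_day]) / n_wet_total
    lambda_w <- (n_wet_total / n_years) / l_w
  }
  cc <- mar_w - ifelse(is.na(alpha_w), 0, alpha_w) * lambda_w * l_w
  list(
    mar_w = mar_w, alpha_w = alpha_w, lambda_w = lambda_w, c = cc,
    l_w = l_w, n_wet_days = n_wet_total / n_years
  )
}

# all rainfall metrics for one 365 x n_years matrix
metrics_from_matrix <- function(mat, p_thr, wet_day_threshold) {
  n_years <- ncol(mat)
  monthly <- rowsum(mat, group = MONTH_OF_DOY)
  mean_monthly <- rowMeans(monthly)
  mar <- sum(mean_monthly)
  if (mar <= 0) {
    return(list(
      mar = 0, mar_w = 0, si = NA_real_, l_w = 0L, l_w_si = NA_real_,
      alpha_w = NA_real_, lambda_w = 0, c = 0,
      wet_months = integer(0), n_wet_months = 0L
    ))
  }
  si <- sum(abs(mean_monthly - mar / 12)) / mar
  wet <- which(mean_monthly > p_thr * mar / 12)
  if (length(wet) == 0) {
    return(list(
      mar = mar, mar_w = 0, si = si, l_w = 0L, l_w_si = lw_from_si(si),
      alpha_w = NA_real_, lambda_w = 0, c = 0,
      wet_months = integer(0), n_wet_months = 0L
    ))
  }
  ws <- suppressWarnings(wet_stats_from_matrix(mat, wet, wet_day_threshold))
  list(
    mar = mar, mar_w = ws$mar_w, si = si, l_w = ws$l_w,
    l_w_si = lw_from_si(si), alpha_w = ws$alpha_w, lambda_w = ws$lambda_w,
    c = ws$c, wet_months = as.integer(wet), n_wet_months = length(wet)
  )
}

#' Per-cell rainfall metrics from daily series
#'
#' Computes, for every cell, the full set of rainfall descriptors: mean annual
#' rainfall (`mar`), wet-season rainfall (`mar_w`), the Walsh-Lawler
#' seasonality index (`si`), wet-season length from the monthly climatology
#' (`l_w`) and from SI (`l_w_si`), wet-day intensity `alpha_w` and frequency
#' `lambda_w`, and the water-balance closing term `c`.
#'
#' @inheritParams monthly_climatology
#' @inheritParams wet_season
#' @inheritParams wet_day_stats
#' @return A tibble with one row per cell and columns `mar`, `mar_w`, `si`,
#'   `l_w`, `l_w_si`, `alpha_w`, `lambda_w`, `c`, `wet_months` (list column)
#'   and `n_wet_months`.
#' @export
#' @examples
#' daily <- simulate_daily_rainfall(n_years = 5, event_prob = 0.4, seed = 2)
#' rainfall_metrics(daily)
rainfall_metrics <- function(daily, p_thr = 0.5, wet_day_threshold = 0.1) {
  check_daily(daily)
  if (!is.numeric(p_thr) || p_thr <= 0 || p_thr >= 1) {
    abort("`p_thr` must be strictly between 0 and 1.", class = "tgbcover_error_param")
  }
  per_cell(daily, function(x, ...) {
    m <- metrics_from_matrix(daily_to_matrix(x), p_thr, wet_day_threshold)
    tibble::tibble(
      mar = m$mar, mar_w = m$mar_w, si = m$si, l_w = m$l_w, l_w_si = m$l_w_si,
      alpha_w = m$alpha_w, lambda_w = m$lambda_w, c = m$c,
      wet_months = list(m$wet_months), n_wet_months = m$n_wet_months
    )
  })
}

#' Calibrate the wet-month threshold against the SI-based season length
#'
#' For each candidate threshold, wet-season lengths `l_w` are computed for all
#' cells and correlated (squared Pearson) with the threshold-free lengths
#' `l_w_si` implied by the seasonality index. The chosen threshold maximises
#' this R^2; at the default grid the maximum is typically at 0.5.
#'
#' @param daily Multi-cell daily rainfall data frame (must contain `cell_id`;
#'   at least 3 cells with non-zero rainfall).
#' @param p_thr_grid Numeric vector of candidate thresholds in (0, 1).
#' @return An object of class `pthr_calibration`: a list with `p_thr` (the
#'   argmax) and `curve`, a tibble of (`p_thr`, `r_squared`). A length-1 grid
#'   is returned unchanged as the chosen value.
#' @export
#' @examples
#' daily <- purrr::map(1:4, function(i) {
#'   dplyr::mutate(
#'     simulate_daily_rainfall(
#'       n_years = 3,
#'       wet_months = seq_len(2 + 2 * i), seed = i
#'     ),
#'     cell_id = i
#'   )
#' }) |> purrr::list_rbind()
#' calibrate_pthr(daily, p_thr_grid = c(0.3, 0.5, 0.7))
calibrate_pthr <- function(daily, p_thr_grid = seq(0.1, 0.9, by = 0.1)) {
  check_daily(daily)
  if (!has_cell(daily)) {
    abort("`daily` must contain `cell_id` (calibration is across cells).",
      class = "tgbcover_error_input"
    )
  }
  if (length(p_thr_grid) < 1 || any(p_thr_grid <= 0 | p_thr_grid >= 1)) {
    abort("`p_thr_grid` must contain thresholds strictly between 0 and 1.",
      class = "tgbcover_error_param"
    )
  }
  mats <- daily |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_map(~ daily_to_matrix(.x))
  clim_list <- purrr::map(mats, function(m) rowMeans(rowsum(m, MONTH_OF_DOY)))
  ok <- purrr::map_lgl(clim_list, ~ sum(.x) > 0)
  if (sum(ok) < 3) {
    abort("need at least 3 cells with non-zero rainfall.",
      class = "tgbcover_error_input"
    )
  }
  clim_list <- clim_list[ok]
  si <- purrr::map_dbl(clim_list, ~ sum(abs(.x - sum(.x) / 12)) / sum(.x))
  lwsi <- lw_from_si(pmin(si, SI_MAX))
  if (length(p_thr_grid) == 1) {
    curve <- tibble::tibble(p_thr = p_thr_grid, r_squared = NA_real_)
    lw <- lw_at_threshold(clim_list, p_thr_grid)
    if (sd(lw) > 0 && sd(lwsi) > 0) {
      curve$r_squared <- cor(lw, lwsi)^2
    }
    return(structure(list(p_thr = p_thr_grid, curve = curve),
      class = "pthr_calibration"
    ))
  }
  r2 <- purrr::map_dbl(p_thr_grid, function(p) {
    lw <- lw_at_threshold(clim_list, p)
    if (sd(lw) == 0 || sd(lwsi) == 0) {
      return(NA_real_)
    }
    cor(lw, lwsi)^2
  })
  if (all(is.na(r2))) {
    abort("degenerate correlation: wet-season length has zero variance at every threshold.",
      class = "tgbcover_error_degenerate"
    )
  }
  best <- p_thr_grid[which.max(r2)]
  structure(
    list(p_thr = best, curve = tibble::tibble(p_thr = p_thr_grid, r_squared = r2)),
    class = "pthr_calibration"
  )
}

lw_at_threshold <- function(clim_list, p_thr) {
  purrr::map_dbl(clim_list, function(mm) {
    r <- sum(mm)
    sum(MONTH_LENGTHS[mm > p_thr * r / 12])
  })
}

#' @export
print.pthr_calibration <- function(x, ...) {
  cat("Wet-month threshold calibration\n")
  cat("  chosen p_thr:", format(x$p_thr), "\n")
  best <- x$curve$r_squared[match(x$p_thr, x$curve$p_thr)]
  if (!is.na(best)) cat("  R^2(l_w, l_w_si) at chosen threshold:", round(best, 4), "\n")
  cat("  candidates:", nrow(x$curve), "\n")
  invisible(x)
}
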