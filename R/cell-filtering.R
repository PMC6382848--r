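#' Mask out shrub-dominated and human-influenced grid cells
#'
#' Drops cells where shrubland covers more than `shrub_max` of the area
#' (MODIS tree cover is biased under shrub), and cells where the combined
#' human-influenced, water and permanent snow/ice fraction exceeds
#' `disturbed_max` (default 1/3).
#'
#' @param cells A data frame with land-cover fraction columns `shrubland`,
#'   `human_water` and `snow_ice` (each in \[0, 1\]).
#' @param shrub_max Maximum tolerated shrubland fraction (strict).
#' @param disturbed_max Maximum tolerated combined human + water + snow/ice
#'   fraction (strict).
#' @param verbose Report the number of cells dropped by each rule.
#' @return The surviving rows, with an attribute `mask_counts` recording how
#'   many cells each rule removed.
#' @export
#' @examples
#' lc <- simulate_landcover(50, seed = 1)
#' nrow(apply_masks(lc))
apply_masks <- function(cells, shrub_max = 0.5, disturbed_max = 1 / 3,
                        verbose = FALSE) {
  need <- c("shrubland", "human_water", "snow_ice")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols) > 0) {
    abort(
      paste0("`cells` is missing land-cover column(s): ",
        paste(missing_cols, collapse = ", ")),
      class = "tgbcover_error_input"
    )
  }
  fr <- cells[need]
  if (any(is.na(fr)) || any(fr < 0) || any(fr > 1)) {
    abort("land-cover fractions must lie in [0, 1].", class = "tgbcover_error_input")
  }
  shrub_drop <- cells$shrubland > shrub_max
  disturbed_drop <- (cells$human_water + cells$snow_ice) > disturbed_max
  counts <- c(
    shrubland = sum(shrub_drop),
    disturbed = sum(disturbed_drop & !shrub_drop),
    kept = sum(!shrub_drop & !disturbed_drop)
  )
  if (verbose) {
    message(
      "masking: dropped ", counts[["shrubland"]], " shrub-dominated and ",
      counts[["disturbed"]], " disturbed cells; ", counts[["kept"]], " kept."
    )
  }
  out <- cells[!shrub_drop & !disturbed_drop, , drop = FALSE]
  attr(out, "mask_counts") <- counts
  out
}

#' Flag tropical grassy biome cells
#'
#' A cell is a tropical grassy biome (TGB) when more than `tgb_min` of its
#' area is mapped as deciduous trees or grassland; African savanna trees are
#' predominantly deciduous, so this land-cover rule identifies the biome
#' without relying on tree-cover discontinuities.
#'
#' @param cells A data frame with column `deciduous_grassland` (fraction).
#' @param tgb_min Fraction above which (strictly) a cell counts as TGB.
#' @return `cells` with an added logical column `tgb`.
#' @export
identify_tgb <- function(cells, tgb_min = 0.5) {
  if (!"deciduous_grassland" %in% names(cells)) {
    abort("`cells` needs a `deciduous_grassland` fraction column.",
      class = "tgbcover_error_input"
    )
  }
  dplyr::mutate(cells, tgb = .data$deciduous_grassland > tgb_min)
}

#' Assign mean-annual-rainfall range labels
#'
#' Classifies cells into the three MAR ranges used throughout the analysis:
#' R1 (MAR <= 630 mm y^-1), R2 (630 < MAR < 1200) and R3
#' (1200 <= MAR <= `mar_cap`). Cells wetter than `mar_cap` (default
#' 2500 mm y^-1) are labelled `excluded`.
#'
#' @param mar Numeric vector of mean annual rainfall (mm y^-1), non-negative.
#' @param r1_max,r2_max,mar_cap Range boundaries (mm y^-1), increasing.
#' @return A factor with levels `R1`, `R2`, `R3`, `excluded`.
#' @export
#' @examples
#' assign_mar_range(c(630, 631, 1200, 2501))
assign_mar_range <- function(mar, r1_max = 630, r2_max = 1200, mar_cap = 2500) {
  if (!is.numeric(mar) || any(is.na(mar)) || any(mar < 0)) {
    abort("`mar` must be non-negative.", class = "tgbcover_error_input")
  }
  if (!(r1_max < r2_max && r2_max < mar_cap)) {
    abort("range bounds must be increasing.", class = "tgbcover_error_param")
  }
  lab <- dplyr::case_when(
    mar <= r1_max ~ "R1",
    mar < r2_max ~ "R2",
    mar <= mar_cap ~ "R3",
    TRUE ~ "excluded"
  )
  factor(lab, levels = c("R1", "R2", "R3", "excluded"))
}

#' Build the filtered analysis table
#'
#' Applies the land-cover masks, keeps tropical grassy biome cells only,
#' labels MAR ranges and drops cells above the MAR cap. The result is the
#' per-cell table the cover models are fitted on.
#'
#' @param cells A data frame with land-cover fraction columns (see
#'   [apply_masks()] and [identify_tgb()]) and a `mar` column; vegetation and
#'   rainfall metric columns are carried through.
#' @inheritParams apply_masks
#' @inheritParams identify_tgb
#' @inheritParams assign_mar_range
#' @return A tibble of surviving cells with a `mar_range` factor column
#'   (levels R1/R2/R3) and attribute `filter_counts`.
#' @export
build_cell_table <- function(cells, shrub_max = 0.5, disturbed_max = 1 / 3,
                             tgb_min = 0.5, r1_max = 630, r2_max = 1200,
                             mar_cap = 2500, verbose = FALSE) {
  n0 <- nrow(cells)
  masked <- apply_masks(cells,
    shrub_max = shrub_max,
    disturbed_max = disturbed_max, verbose = verbose
  )
  tgb <- dplyr::filter(identify_tgb(masked, tgb_min = tgb_min), .data$tgb)
  out <- tgb |>
    dplyr::mutate(mar_range = assign_mar_range(.data$mar, r1_max, r2_max, mar_cap)) |>
    dplyr::filter(.data$mar_range != "excluded") |>
    dplyr::mutate(mar_range = droplevels(.data$mar_range)) |>
    tibble::as_tibble()
  attr(out, "filter_counts") <- c(
    input = n0, after_masks = nrow(masked), tgb = nrow(tgb), final = nrow(out)
  )
  if (verbose) {
    message("cell table: ", nrow(out), " of ", n0, " cells retained.")
  }
  out
}

#' Pairwise rank-sum comparison of distributions across MAR ranges
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum tests of each variable between
#' every pair of groups, as used to check that the per-range distributions
#' differ in median.
#'
#' @param data A data frame.
#' @param vars Character vector of numeric columns to compare.
#' @param group Name of the grouping column (default `"mar_range"`).
#' @return A tibble with one row per (variable, group pair): `statistic`
#'   (the rank-sum W), `p_value`, and group sizes `n1`, `n2`.
#' @export
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 5), x = c(1:5, 11:15))
#' compare_medians(df, "x", group = "g")
compare_medians <- function(data, vars, group = "mar_range") {
  if (!group %in% names(data)) {
    abort(paste0("grouping column `", group, "` not found."),
      class = "tgbcover_error_input"
    )
  }
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("variable(s) not found: ", paste(missing_cols, collapse = ", ")),
      class = "tgbcover_error_input"
    )
  }
  g <- factor(data[[group]])
  g <- droplevels(g)
  lv <- levels(g)
  if (any(table(g) < 2)) {
    abort("every group needs at least 2 observations.", class = "tgbcover_error_input")
  }
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  purrr::map(vars, function(v) {
    purrr::map(pairs, function(p) {
      x <- data[[v]][g == p[1]]
      y <- data[[v]][g == p[2]]
      wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
      tibble::tibble(
        variable = v, group1 = p[1], group2 = p[2],
        statistic = unname(wt$statistic), p_value = wt$p.value,
        n1 = length(x), n2 = length(y)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}
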