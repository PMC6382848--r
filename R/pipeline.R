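#' Run the full tree/grass cover analysis
#'
#' Orchestrates the whole analysis on a per-cell table (or on a freshly
#' generated synthetic study): filtering to tropical grassy biome cells and
#' MAR-range labelling, per-range summary statistics with pairwise rank-sum
#' tests, AIC selection over the 34 candidate binomial-logit models for each
#' response in each range (and optionally for the pooled table), and the
#' deviance-residual collinearity analysis wherever a best model contains an
#' intra-seasonal rainfall variable.
#'
#' @param cells A per-cell data frame with cover fractions `tree`, `grass`,
#'   rainfall metrics `mar`, `si`, `lambda_w`, `alpha_w`, fire `log_afi` and
#'   land-cover fraction columns; or `NULL` to simulate one from `scenario`.
#' @param scenario Scenario for [make_dataset()] when `cells` is `NULL`.
#' @param seed Seed used when simulating.
#' @param n_trials Binomial denominator for the cover GLMs.
#' @param include_overall Also analyse the pooled (unranged) table.
#' @param verbose Log per-stage cell counts.
#' @return An object of class `tgb_analysis`: a list with `cell_table`,
#'   `range_summary`, `median_tests`, `selections` (named
#'   `<response>_<range>` list of [select_models()] results), `best_models`
#'   (a per-case table of best model, AIC and explained deviance) and
#'   `residual_report` (tidied [residual_r2()] rows).
#' @export
#' @examples
#' an <- run_tgb_analysis(scenario = small_scenario(), seed = 1)
#' an$best_models
run_tgb_analysis <- function(cells = NULL, scenario = default_scenario(),
                             seed = 1, n_trials = 100,
                             include_overall = TRUE, verbose = FALSE) {
  if (is.null(cells)) {
    cells <- make_dataset(scenario, seed = seed)$cells
  }
  if (nrow(cells) == 0) {
    warn("empty input: returning empty analysis.")
    return(structure(
      list(
        cell_table = tibble::tibble(), range_summary = tibble::tibble(),
        median_tests = tibble::tibble(), selections = list(),
        best_models = tibble::tibble(), residual_report = tibble::tibble()
      ),
      class = "tgb_analysis"
    ))
  }
  tab <- build_cell_table(cells, verbose = verbose)
  predictors <- c("mar", "si", "lambda_w", "alpha_w", "log_afi")
  vars <- c("tree", "grass", predictors)

  range_summary <- tab |>
    tidyr::pivot_longer(dplyr::all_of(vars),
      names_to = "variable",
      values_to = "value"
    ) |>
    dplyr::group_by(.data$mar_range, .data$variable) |>
    dplyr::summarise(
      n = dplyr::n(), median = stats::median(.data$value),
      q25 = stats::quantile(.data$value, 0.25),
      q75 = stats::quantile(.data$value, 0.75),
      .groups = "drop"
    )

  median_tests <- if (length(unique(tab$mar_range)) >= 2 &&
    min(table(tab$mar_range)) >= 2) {
    compare_medians(tab, vars)
  } else {
    tibble::tibble()
  }

  cases <- tidyr::expand_grid(
    response = c("tree", "grass"),
    range = levels(droplevels(tab$mar_range))
  )
  if (include_overall) {
    cases <- dplyr::bind_rows(
      cases,
      tidyr::expand_grid(response = c("tree", "grass"), range = "all")
    )
  }
  specs <- enumerate_models(predictors)
  selections <- list()
  best_rows <- list()
  residual_rows <- list()
  for (i in seq_len(nrow(cases))) {
    rng <- cases$range[i]
    resp <- cases$response[i]
    sub <- if (rng == "all") tab else dplyr::filter(tab, .data$mar_range == rng)
    if (nrow(sub) < 10) next
    sub_std <- standardize_predictors(sub, predictors)
    sel <- select_models(sub_std, resp, specs = specs, n_trials = n_trials)
    key <- paste(resp, rng, sep = "_")
    selections[[key]] <- sel
    bf <- best_fit(sel)
    best_rows[[key]] <- tibble::tibble(
      range = rng, response = resp, best_model = sel$label[1],
      aic = sel$aic[1], pseudo_r2 = sel$pseudo_r2[1],
      retained = sel$retained[1], n = nrow(sub)
    )
    intra <- intersect(unique(bf$terms$predictor), c("alpha_w", "lambda_w"))
    for (v in intra) {
      rr <- residual_r2(sub_std, resp, v, n_trials = n_trials)
      residual_rows[[paste(key, v)]] <- dplyr::mutate(tidy(rr), range = rng)
    }
    if (verbose) {
      message(
        "fit ", key, ": best = ", sel$label[1],
        " (R2 = ", round(sel$pseudo_r2[1], 2), ")"
      )
    }
  }
  structure(
    list(
      cell_table = tab,
      range_summary = range_summary,
      median_tests = median_tests,
      selections = selections,
      best_models = purrr::list_rbind(unname(best_rows)),
      residual_report = purrr::list_rbind(unname(residual_rows))
    ),
    class = "tgb_analysis"
  )
}

#' @export
print.tgb_analysis <- function(x, ...) {
  cat("Tree/grass cover analysis\n")
  if (nrow(x$cell_table) == 0) {
    cat("  (empty)\n")
    return(invisible(x))
  }
  cat("  cells:", nrow(x$cell_table), "by range:",
    paste(names(table(x$cell_table$mar_range)),
      table(x$cell_table$mar_range),
      sep = "=", collapse = " "
    ), "\n")
  cat("  best models:\n")
  print(x$best_models)
  if (nrow(x$residual_report) > 0) {
    cat("  residual analysis (direct-effect R2):\n")
    print(x$residual_report)
  }
  invisible(x)
}

#' Best-model summary table of an analysis
#'
#' @param analysis A `tgb_analysis` from [run_tgb_analysis()].
#' @return A tibble with one row per (range, response): the selected model
#'   label, its explained deviance and whether it beat the intercept-only
#'   model.
#' @export
best_model_table <- function(analysis) {
  stopifnot(inherits(analysis, "tgb_analysis"))
  analysis$best_models
}
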