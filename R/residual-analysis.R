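#' Deviance residuals of a fitted cover model
#'
#' Signed square roots of the per-observation deviance contributions; their
#' sum of squares equals the residual deviance.
#'
#' @param fit A `cover_glm` object.
#' @return Numeric vector, one residual per cell.
#' @export
deviance_residuals <- function(fit) {
  stopifnot(inherits(fit, "cover_glm"))
  unname(residuals(fit$fit, type = "deviance"))
}

#' Residual correlation between cover and an intra-seasonal rainfall variable
#'
#' Tests whether the association of cover with wet-season rainfall intensity
#' (`alpha_w`) or frequency (`lambda_w`) is direct, or only mediated by the
#' bulk climate and fire variables. Both sides are regressed on the same
#' covariates (by default MAR, SI and log10(AFI)): cover with a
#' binomial-logit GLM, the intra-seasonal variable with an ordinary
#' (normal-identity) linear model, for which deviance residuals are the raw
#' residuals. The squared correlation of the two residual vectors measures
#' the direct association: near 0 when the apparent effect is collinearity,
#' growing with a genuine direct effect.
#'
#' @param data A data frame with the response fraction, the intra-seasonal
#'   variable and the covariate columns.
#' @param response Cover-fraction column name.
#' @param intra_var `"alpha_w"` or `"lambda_w"` (any numeric column works).
#' @param covariates Columns removed from both sides.
#' @param n_trials Binomial denominator for the cover GLM.
#' @return An object of class `residual_pair`: `veg_residuals`,
#'   `pred_residuals`, `r2`, `n`, `degenerate` (TRUE when the intra-seasonal
#'   variable is fully determined by the covariates, in which case `r2` is
#'   reported as 0). Has [generics::tidy()] and `autoplot()` methods.
#' @export
#' @examples
#' cells <- make_dataset(small_scenario(), seed = 1)$cells
#' r1 <- dplyr::filter(build_cell_table(cells), mar_range == "R1")
#' residual_r2(r1, "grass", "lambda_w")
residual_r2 <- function(data, response, intra_var,
                        covariates = c("mar", "si", "log_afi"),
                        n_trials = 100) {
  missing_cols <- setdiff(c(response, intra_var, covariates), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("column(s) not found: ", paste(missing_cols, collapse = ", ")),
      class = "tgbcover_error_input"
    )
  }
  if (nrow(data) < 10) {
    abort("need at least 10 rows for the residual analysis.",
      class = "tgbcover_error_input"
    )
  }
  sds <- purrr::map_dbl(covariates, ~ sd(data[[.x]]))
  if (any(sds == 0)) {
    abort("degenerate covariate(s) with zero variance.",
      class = "tgbcover_error_degenerate"
    )
  }
  veg_fit <- fit_cover_glm(data, response, terms = covariates, n_trials = n_trials)
  veg_res <- deviance_residuals(veg_fit)
  fml <- as.formula(paste(intra_var, "~", paste(covariates, collapse = " + ")))
  pred_fit <- lm(fml, data = data)
  pred_res <- unname(residuals(pred_fit))
  degenerate <- sd(pred_res) < 1e-10 * max(sd(data[[intra_var]]), 1e-300)
  r2 <- if (degenerate) {
    warn(paste0("`", intra_var, "` is fully determined by the covariates; r2 reported as 0."))
    0
  } else {
    cor(veg_res, pred_res)^2
  }
  structure(
    list(
      response = response, intra_var = intra_var, covariates = covariates,
      veg_residuals = veg_res, pred_residuals = pred_res,
      r2 = r2, n = length(veg_res), degenerate = degenerate
    ),
    class = "residual_pair"
  )
}

#' @export
print.residual_pair <- function(x, ...) {
  cat("Residual analysis: ", x$response, " vs ", x$intra_var,
    " | removed: ", paste(x$covariates, collapse = ", "), "\n",
    sep = ""
  )
  cat("  n =", x$n, " R2 of residual-residual linear fit =", round(x$r2, 4), "\n")
  if (x$degenerate) cat("  (degenerate: no residual variance in the predictor)\n")
  invisible(x)
}

#' @export
tidy.residual_pair <- function(x, ...) {
  tibble::tibble(
    response = x$response, intra_var = x$intra_var,
    r2 = x$r2, n = x$n, degenerate = x$degenerate
  )
}
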