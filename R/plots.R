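#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.cover_selection <- function(object, n = 15, ...) {
  d <- tibble::as_tibble(object)[seq_len(min(n, nrow(object))), ]
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_aic, y = .data$label)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$retained), width = 0.7) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70"),
      name = "AIC < intercept-only"
    ) +
    ggplot2::labs(
      x = expression(Delta * "AIC"), y = NULL,
      title = paste0(
        "Model ranking for ", attr(object, "response"),
        " (top ", nrow(d), ")"
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cover_glm <- function(object, data = NULL, ...) {
  pred <- unique(object$terms$predictor)
  if (length(pred) == 1) {
    df <- object$fit$data
    x <- df[[pred]]
    grid <- data.frame(x = seq(min(x), max(x), length.out = 200))
    names(grid) <- pred
    grid$fit <- stats::predict(object$fit, newdata = grid, type = "response")
    obs <- data.frame(x = x, y = df$.k / df$.n)
    ggplot2::ggplot() +
      ggplot2::geom_point(
        data = obs, ggplot2::aes(.data$x, .data$y),
        alpha = 0.3, size = 0.8
      ) +
      ggplot2::geom_line(
        data = grid,
        ggplot2::aes(.data[[pred]], .data$fit),
        colour = "#d95f02", linewidth = 1
      ) +
      ggplot2::labs(
        x = paste0(pred, " (standardized)"),
        y = paste0(object$response, " cover fraction"),
        title = paste0("logit(", object$response, ") ~ ", object$label)
      ) +
      ggplot2::theme_minimal()
  } else {
    obs <- data.frame(
      fitted = stats::fitted(object$fit),
      observed = object$fit$data$.k / object$fit$data$.n
    )
    ggplot2::ggplot(obs, ggplot2::aes(.data$fitted, .data$observed)) +
      ggplot2::geom_point(alpha = 0.3, size = 0.8) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::labs(
        x = "fitted cover", y = "observed cover",
        title = paste0("logit(", object$response, ") ~ ", object$label)
      ) +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.residual_pair <- function(object, ...) {
  d <- data.frame(x = object$pred_residuals, y = object$veg_residuals)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      colour = "#d95f02") +
    ggplot2::labs(
      x = paste0(object$intra_var, " residuals"),
      y = paste0(object$response, " deviance residuals"),
      title = sprintf("Residual-residual fit, R2 = %.3f", object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pthr_calibration <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$p_thr, .data$r_squared)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$p_thr, linetype = 2) +
    ggplot2::labs(
      x = "wet-month threshold p_thr",
      y = expression(R^2 * "(l_w, l_w_si)"),
      title = "Wet-month threshold calibration"
    ) +
    ggplot2::theme_minimal()
}

#' Per-range distribution boxplots
#'
#' Box plots of cover and climate/fire variables split by MAR range,
#' mirroring the per-range descriptive view of the analysis table.
#'
#' @param cell_table A filtered cell table with a `mar_range` column.
#' @param vars Variables to plot.
#' @return A ggplot object.
#' @export
plot_range_distributions <- function(cell_table,
                                     vars = c(
                                       "tree", "grass", "mar", "si",
                                       "log_afi", "alpha_w", "lambda_w"
                                     )) {
  d <- cell_table |>
    tidyr::pivot_longer(dplyr::all_of(vars),
      names_to = "variable",
      values_to = "value"
    )
  ggplot2::ggplot(d, ggplot2::aes(.data$mar_range, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "MAR range", y = NULL) +
    ggplot2::theme_minimal()
}
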