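#' Standardize predictor columns
#'
#' Centres and scales each predictor to mean 0 and sample (n-1) standard
#' deviation 1, so that the magnitudes of fitted GLM coefficients are
#' comparable measures of predictor importance. The transform parameters are
#' kept for back-conversion to natural units.
#'
#' @param data A data frame.
#' @param vars Character vector of columns to standardize.
#' @return `data` with the named columns standardized and an attribute
#'   `standardization`: a tibble of (`predictor`, `mean`, `sd`), retrievable
#'   with [standardization()].
#' @export
#' @examples
#' standardize_predictors(data.frame(x = c(1, 2, 3)), "x")$x
standardize_predictors <- function(data, vars) {
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("column(s) not found: ", paste(missing_cols, collapse = ", ")),
      class = "tgbcover_error_input"
    )
  }
  mu <- purrr::map_dbl(vars, ~ mean(data[[.x]]))
  sds <- purrr::map_dbl(vars, ~ sd(data[[.x]]))
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    bad <- vars[!is.finite(sds) | sds <= 0]
    abort(paste0("degenerate predictor(s) with zero or undefined spread: ",
      paste(bad, collapse = ", ")), class = "tgbcover_error_degenerate")
  }
  for (i in seq_along(vars)) {
    data[[vars[i]]] <- (data[[vars[i]]] - mu[i]) / sds[i]
  }
  attr(data, "standardization") <- tibble::tibble(
    predictor = vars, mean = mu, sd = sds
  )
  data
}

#' Retrieve standardization parameters
#'
#' @param x An object produced by [standardize_predictors()] (or a fitted
#'   model that carries the attribute).
#' @return A tibble of (`predictor`, `mean`, `sd`), or `NULL` if absent.
#' @export
standardization <- function(x) {
  if (inherits(x, "cover_glm")) {
    return(x$standardization)
  }
  attr(x, "standardization")
}

#' Enumerate the candidate cover models
#'
#' Builds the full candidate set for one response: for every predictor the
#' nested polynomials of degree 1 to `max_power` (linear, quadratic, cubic);
#' every subset of two or more predictors with linear terms only; and the
#' intercept-only model. Subsets containing both members of `exclude` (by
#' default the intensity/frequency pair `alpha_w`, `lambda_w`, which are
#' linked through the wet-season water balance) are removed. With the five
#' standard predictors this yields exactly 34 models
#' (15 polynomial + 18 combinations + 1 intercept-only).
#'
#' @param predictors Character vector of predictor column names.
#' @param exclude Length-2 character vector: no model may contain both; or
#'   `NULL` for no exclusion.
#' @param max_power Highest polynomial degree for single-predictor models.
#' @return A tibble with one row per candidate: `model_id`, `label`, `type`
#'   (`intercept`, `polynomial` or `combination`), `n_terms`, and `terms`, a
#'   list column of tibbles (`predictor`, `power`). Order is deterministic.
#' @export
#' @examples
#' nrow(enumerate_models()) # 34
enumerate_models <- function(predictors = c("mar", "si", "lambda_w", "alpha_w", "log_afi"),
                             exclude = c("alpha_w", "lambda_w"),
                             max_power = 3) {
  if (length(predictors) < 1 || anyDuplicated(predictors)) {
    abort("`predictors` must be a non-empty set of distinct names.",
      class = "tgbcover_error_param"
    )
  }
  if (!is.null(exclude)) {
    if (length(exclude) != 2 || !all(exclude %in% predictors)) {
      abort("`exclude` must name two of the predictors.",
        class = "tgbcover_error_param"
      )
    }
  }
  specs <- list(tibble::tibble(predictor = character(0), power = integer(0)))
  types <- "intercept"
  for (p in predictors) {
    for (k in seq_len(max_power)) {
      specs <- c(specs, list(tibble::tibble(predictor = p, power = seq_len(k))))
      types <- c(types, "polynomial")
    }
  }
  np <- length(predictors)
  if (np >= 2) {
    for (size in 2:np) {
      sets <- utils::combn(seq_len(np), size, simplify = FALSE)
      for (s in sets) {
        nm <- predictors[s]
        if (!is.null(exclude) && all(exclude %in% nm)) next
        specs <- c(specs, list(tibble::tibble(predictor = nm, power = 1L)))
        types <- c(types, "combination")
      }
    }
  }
  tibble::tibble(
    model_id = seq_along(specs),
    label = purrr::map_chr(specs, spec_label),
    type = types,
    n_terms = purrr::map_int(specs, nrow),
    terms = specs
  )
}

spec_label <- function(terms) {
  if (nrow(terms) == 0) {
    return("1")
  }
  paste(term_names(terms), collapse = " + ")
}

term_names <- function(terms) {
  ifelse(terms$power == 1, terms$predictor,
    paste0(terms$predictor, "^", terms$power)
  )
}

# normalize terms input: NULL, character ("mar", "mar^2") or tibble
as_terms <- function(terms) {
  if (is.null(terms)) {
    return(tibble::tibble(predictor = character(0), power = integer(0)))
  }
  if (is.character(terms)) {
    m <- regmatches(terms, regexec("^([^\\^]+)(\\^([0-9]+))?$", terms))
    return(tibble::tibble(
      predictor = purrr::map_chr(m, 2),
      power = purrr::map_int(m, ~ if (.x[4] == "") 1L else as.integer(.x[4]))
    ))
  }
  if (is.data.frame(terms) && all(c("predictor", "power") %in% names(terms))) {
    return(tibble::tibble(
      predictor = terms$predictor,
      power = as.integer(terms$power)
    ))
  }
  abort("`terms` must be NULL, a character vector or a (predictor, power) data frame.",
    class = "tgbcover_error_param"
  )
}

#' Fit a binomial-logit cover model
#'
#' Fits fractional cover (tree or grass) against the requested terms with a
#' binomial error distribution and logit link, by iteratively reweighted
#' least squares (`stats::glm`). Cover fractions are converted to binomial
#' counts out of `n_trials` (default 100, i.e. percent-cover resolution),
#' which defines the likelihood and hence the AIC.
#'
#' @param data A data frame containing the response fraction column and
#'   (typically standardized) predictor columns; a `standardization`
#'   attribute, if present, is carried into the fit.
#' @param response Name of the cover-fraction column (values in \[0, 1\]).
#' @param terms Model terms: `NULL` for intercept-only, a character vector
#'   such as `c("mar", "mar^2")`, or a tibble of (`predictor`, `power`).
#' @param n_trials Binomial denominator per cell.
#' @return An object of class `cover_glm`, with [generics::tidy()] and
#'   [generics::glance()] methods. `glance()` reports the residual and null
#'   deviance, AIC and the explained deviance
#'   `pseudo_r2 = 1 - deviance / null_deviance`.
#' @export
#' @examples
#' d <- data.frame(x = rnorm(200))
#' d$cov <- rbinom(200, 100, plogis(-1 + 0.5 * d$x)) / 100
#' fit <- fit_cover_glm(d, "cov", "x")
#' generics::glance(fit)
fit_cover_glm <- function(data, response, terms = NULL, n_trials = 100) {
  terms <- as_terms(terms)
  if (!response %in% names(data)) {
    abort(paste0("response column `", response, "` not found."),
      class = "tgbcover_error_input"
    )
  }
  y <- data[[response]]
  if (any(is.na(y)) || any(y < 0) || any(y > 1)) {
    abort("response fractions must lie in [0, 1].", class = "tgbcover_error_input")
  }
  if (n_trials < 1) {
    abort("`n_trials` must be at least 1.", class = "tgbcover_error_param")
  }
  missing_cols <- setdiff(unique(terms$predictor), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("predictor column(s) not found: ",
      paste(missing_cols, collapse = ", ")), class = "tgbcover_error_input")
  }
  if (nrow(data) < nrow(terms) + 2) {
    abort("too few rows for the requested model.", class = "tgbcover_error_input")
  }
  k <- round(y * n_trials)
  rhs <- if (nrow(terms) == 0) {
    "1"
  } else {
    paste(
      ifelse(terms$power == 1, terms$predictor,
        paste0("I(", terms$predictor, "^", terms$power, ")")
      ),
      collapse = " + "
    )
  }
  df <- data.frame(data[, unique(terms$predictor), drop = FALSE],
    .k = k, .n = n_trials, check.names = FALSE
  )
  fml <- as.formula(paste("cbind(.k, .n - .k) ~", rhs))
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(fml,
      family = binomial(link = "logit"), data = df,
      control = stats::glm.control(maxit = 100)
    ),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) {
    abort("binomial GLM did not converge.", class = "tgbcover_error_convergence")
  }
  structure(
    list(
      fit = fit, response = response, terms = terms, label = spec_label(terms),
      n_trials = n_trials, n = nrow(df), separation = separation,
      standardization = attr(data, "standardization")
    ),
    class = "cover_glm"
  )
}

#' Explained deviance of a fitted cover model
#'
#' @param fit A `cover_glm` object.
#' @return `1 - deviance / null_deviance`, in \[0, 1\].
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "cover_glm"))
  if (fit$fit$null.deviance <= 0) {
    return(0)
  }
  max(0, 1 - fit$fit$deviance / fit$fit$null.deviance)
}

#' @export
print.cover_glm <- function(x, ...) {
  cat("Binomial-logit cover model: logit(", x$response, ") ~ ", x$label,
    "\n",
    sep = ""
  )
  cat("  n =", x$n, " trials/cell =", x$n_trials, "\n")
  cat(
    "  AIC =", round(stats::AIC(x$fit), 2),
    " pseudo-R2 =", round(pseudo_r2(x), 3), "\n"
  )
  print(round(coef(x$fit), 4))
  if (x$separation) cat("  note: fitted probabilities numerically 0/1 (separation).\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cover_glm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  nm <- rownames(s)
  nm <- gsub("^I\\(([^)]+)\\)$", "\\1", nm)
  nm[nm == "(Intercept)"] <- "intercept"
  tibble::tibble(
    term = nm, estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @export
glance.cover_glm <- function(x, ...) {
  tibble::tibble(
    null_deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    pseudo_r2 = pseudo_r2(x),
    aic = stats::AIC(x$fit),
    df = length(coef(x$fit)),
    n = x$n,
    converged = x$fit$converged,
    separation = x$separation
  )
}

#' Fit and rank all candidate cover models by AIC
#'
#' Fits every candidate in `specs` to the data, ranks by AIC (ties broken
#' toward fewer terms, then label order), and reports the AIC difference from
#' the best model and the explained deviance. Models with AIC below the
#' intercept-only model are flagged as `retained`; only those carry evidence
#' beyond a constant cover level.
#'
#' @inheritParams fit_cover_glm
#' @param specs Candidate models from [enumerate_models()].
#' @return A `cover_selection` tibble, one row per candidate, ordered by AIC:
#'   `rank`, `label`, `type`, `n_terms`, `aic`, `delta_aic`, `pseudo_r2`,
#'   `retained`, and a `coefficients` list column. The fitted `cover_glm`
#'   objects are kept in attribute `fits` (in candidate order); the best fit
#'   is accessible via [best_fit()].
#' @export
#' @examples
#' d <- data.frame(x = rnorm(300), z = rnorm(300))
#' d$cov <- rbinom(300, 100, plogis(0.3 + 0.6 * d$x)) / 100
#' sel <- select_models(d, "cov", enumerate_models(c("x", "z"), exclude = NULL))
#' sel[1:3, c("label", "aic", "delta_aic", "pseudo_r2")]
select_models <- function(data, response, specs = enumerate_models(),
                          n_trials = 100) {
  fits <- purrr::map(specs$terms, function(tt) {
    fit_cover_glm(data, response, terms = tt, n_trials = n_trials)
  })
  g <- purrr::map(fits, glance) |> purrr::list_rbind()
  out <- specs |>
    dplyr::select("model_id", "label", "type", "n_terms") |>
    dplyr::mutate(
      aic = g$aic, pseudo_r2 = g$pseudo_r2,
      separation = g$separation,
      coefficients = purrr::map(fits, ~ coef(.x$fit))
    )
  aic0 <- out$aic[specs$n_terms == 0][1]
  out <- out |>
    dplyr::mutate(
      delta_aic = .data$aic - min(.data$aic),
      retained = .data$aic < aic0
    ) |>
    dplyr::arrange(.data$aic, .data$n_terms, .data$label) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::relocate("rank")
  attr(out, "fits") <- fits
  attr(out, "response") <- response
  attr(out, "aic_intercept_only") <- aic0
  class(out) <- c("cover_selection", class(out))
  out
}

#' Best fitted model of a selection
#'
#' @param selection A `cover_selection` from [select_models()].
#' @return The `cover_glm` with the lowest AIC (ties toward parsimony).
#' @export
best_fit <- function(selection) {
  stopifnot(inherits(selection, "cover_selection"))
  attr(selection, "fits")[[selection$model_id[1]]]
}

#' @export
print.cover_selection <- function(x, n = 5, ...) {
  cat(
    "Cover model selection for `", attr(x, "response"), "` (",
    nrow(x), " candidates)\n",
    sep = ""
  )
  cat("  retained (AIC < intercept-only):", sum(x$retained), "\n")
  print(tibble::as_tibble(x)[
    seq_len(min(n, nrow(x))),
    c("rank", "label", "aic", "delta_aic", "pseudo_r2", "retained")
  ])
  invisible(x)
}

#' Extremum of a quadratic (parabolic) logit fit
#'
#' For a single-predictor quadratic model `logit(p) = a + b z + c z^2` on the
#' standardized predictor `z`, the extremum sits at `z* = -b / (2 c)`: a
#' minimum when `c > 0`, a maximum when `c < 0`. When standardization
#' parameters are available the location is also given in natural units
#' (`mean + sd * z*`), e.g. the rainfall-frequency turning point of tree
#' cover at intermediate MAR.
#'
#' @param fit A `cover_glm` whose terms are a single predictor with powers
#'   1..2 (degree exactly 2).
#' @return A one-row tibble: `predictor`, `vertex_std`, `vertex_natural`
#'   (`NA` when no standardization is attached) and `kind`
#'   (`"minimum"`/`"maximum"`).
#' @export
parabola_extremum <- function(fit) {
  stopifnot(inherits(fit, "cover_glm"))
  tt <- fit$terms
  pred <- unique(tt$predictor)
  if (length(pred) != 1 || max(tt$power) != 2) {
    abort("`parabola_extremum()` needs a single-predictor quadratic fit.",
      class = "tgbcover_error_param"
    )
  }
  cf <- coef(fit$fit)
  b <- unname(cf[pred])
  c2 <- unname(cf[paste0("I(", pred, "^2)")])
  if (is.na(c2) || c2 == 0) {
    abort("quadratic coefficient is zero: no extremum.",
      class = "tgbcover_error_degenerate"
    )
  }
  vz <- -b / (2 * c2)
  vn <- NA_real_
  st <- fit$standardization
  if (!is.null(st) && pred %in% st$predictor) {
    i <- match(pred, st$predictor)
    vn <- st$mean[i] + st$sd[i] * vz
  }
  tibble::tibble(
    predictor = pred, vertex_std = vz, vertex_natural = vn,
    kind = if (c2 > 0) "minimum" else "maximum"
  )
}
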