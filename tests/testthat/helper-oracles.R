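# Independent oracles used to cross-check the implementation.

# General-purpose numerical maximizer of the binomial log-likelihood with
# logit link (BFGS with analytic gradient), independent of the IRLS path.
oracle_binomial_fit <- function(X, k, n_trials) {
  X <- cbind(1, as.matrix(X))
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n_trials - k) * log(1 - p))
  }
  grad <- function(beta) {
    p <- plogis(drop(X %*% beta))
    -drop(crossprod(X, k - n_trials * p))
  }
  fit <- optim(rep(0, ncol(X)), nll, grad,
    method = "BFGS",
    control = list(maxit = 1000, reltol = 1e-16)
  )
  fit$par
}

# Day-by-day loop implementation of the wet-day statistics.
naive_wet_stats <- function(daily, wet_months, threshold = 0.1) {
  l_w <- 0
  for (m in wet_months) l_w <- l_w + c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[m]
  years <- unique(daily$year)
  total_wet_rain <- 0
  n_wet_days <- 0
  above_sum <- 0
  for (i in seq_len(nrow(daily))) {
    m <- tgbcover::doy_month(daily$doy[i])
    if (m %in% wet_months) {
      total_wet_rain <- total_wet_rain + daily$depth[i]
      if (daily$depth[i] > threshold) {
        n_wet_days <- n_wet_days + 1
        above_sum <- above_sum + daily$depth[i]
      }
    }
  }
  ny <- length(years)
  mar_w <- total_wet_rain / ny
  alpha_w <- if (n_wet_days > 0) above_sum / n_wet_days else NA_real_
  lambda_w <- if (n_wet_days > 0) (n_wet_days / ny) / l_w else 0
  c_term <- mar_w - ifelse(is.na(alpha_w), 0, alpha_w) * lambda_w * l_w
  list(mar_w = mar_w, alpha_w = alpha_w, lambda_w = lambda_w, c = c_term, l_w = l_w)
}

# Per-observation binomial deviance terms evaluated from the formula.
oracle_deviance_residuals <- function(k, n_trials, p_hat) {
  y <- k / n_trials
  term <- function(obs, exp) {
    out <- numeric(length(obs))
    nz <- obs > 0
    out[nz] <- obs[nz] * log(obs[nz] / exp[nz])
    out
  }
  d <- 2 * (term(k, n_trials * p_hat) + term(n_trials - k, n_trials * (1 - p_hat)))
  sign(y - p_hat) * sqrt(pmax(d, 0))
}

# Deterministic single-cell daily series from a monthly rainfall vector
# (each day of a month carries an equal share), one year.
block_daily <- function(monthly, cell_id = NULL) {
  lens <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  out <- tibble::tibble(
    year = 1L,
    doy = 1:365,
    depth = rep(monthly / lens, times = lens)
  )
  if (!is.null(cell_id)) out$cell_id <- cell_id
  out
}

# constant-depth daily series
constant_daily <- function(depth, n_years = 1) {
  tibble::tibble(
    year = rep(seq_len(n_years), each = 365),
    doy = rep(1:365, n_years),
    depth = depth
  )
}
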