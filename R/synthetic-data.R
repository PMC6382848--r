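#' Simulate a daily rainfall series for one grid cell
#'
#' Marked-Bernoulli daily rainfall: on each wet-season day an event occurs
#' with probability `event_prob` and, when it does, its depth is exponential
#' with mean `mean_depth` (the single-parameter law whose mean matches the
#' wet-day intensity definition). Dry-season days carry occasional light
#' drizzle, which exercises the 0.1 mm wet-day threshold and the
#' water-balance closing term without contributing much to the annual total.
#' Years are 365 days (no leap days) on the civil calendar.
#'
#' @param n_years Number of years to simulate (>= 1).
#' @param wet_months Integer months (1-12) forming the wet season.
#' @param event_prob Daily rain probability in the wet season (the target
#'   frequency `lambda_w`, d^-1).
#' @param mean_depth Mean event depth in the wet season (the target intensity
#'   `alpha_w`, mm d^-1); must exceed the 0.1 mm wet-day threshold.
#' @param dry_drizzle_prob Daily rain probability outside the wet season.
#' @param dry_mean_depth Mean drizzle depth (mm d^-1).
#' @param seed Optional integer; when given, the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return A tibble with columns `year`, `doy`, `month`, `depth` (mm d^-1).
#' @export
#' @examples
#' daily <- simulate_daily_rainfall(n_years = 2, seed = 1)
#' mean_annual_rainfall(daily)
simulate_daily_rainfall <- function(n_years = 11,
                                    wet_months = c(11, 12, 1, 2, 3),
                                    event_prob = 0.4,
                                    mean_depth = 10,
                                    dry_drizzle_prob = 0.05,
                                    dry_mean_depth = 0.5,
                                    seed = NULL) {
  if (!is.numeric(n_years) || length(n_years) != 1 || n_years < 1) {
    abort("`n_years` must be a single integer >= 1.", class = "tgbcover_error_param")
  }
  wet_months <- as.integer(wet_months)
  if (length(wet_months) < 1 || length(wet_months) > 12 ||
    any(is.na(wet_months)) || any(wet_months < 1L | wet_months > 12L) ||
    anyDuplicated(wet_months)) {
    abort("`wet_months` must be 1 to 12 distinct month indices in 1..12.",
      class = "tgbcover_error_param"
    )
  }
  check_probability(event_prob, "event_prob")
  check_probability(dry_drizzle_prob, "dry_drizzle_prob")
  if (!is.numeric(mean_depth) || mean_depth <= 0.1) {
    abort("`mean_depth` must exceed the 0.1 mm wet-day threshold.",
      class = "tgbcover_error_param"
    )
  }
  if (!is.numeric(dry_mean_depth) || dry_mean_depth < 0) {
    abort("`dry_mean_depth` must be non-negative.", class = "tgbcover_error_param")
  }
  n_years <- as.integer(n_years)
  is_wet <- MONTH_OF_DOY %in% wet_months
  p <- rep.int(ifelse(is_wet, event_prob, dry_drizzle_prob), n_years)
  mu <- rep.int(ifelse(is_wet, mean_depth, dry_mean_depth), n_years)
  n <- length(p)
  depth <- with_seed_or_rng(seed, {
    occ <- rbinom(n, 1L, p)
    occ * mu * rexp(n, rate = 1)
  })
  tibble::tibble(
    year = rep(seq_len(n_years), each = DAYS_PER_YEAR),
    doy = rep.int(seq_len(DAYS_PER_YEAR), n_years),
    month = rep.int(MONTH_OF_DOY, n_years),
    depth = depth
  )
}

#' Simulate per-cell burnt-area fractions
#'
#' Draws log10 fire intervals uniformly over `log_afi_range` and inverts the
#' regularized fire-interval relation, `ba = 10^(-log_afi) - epsilon`, so the
#' derived intervals span the requested orders of magnitude exactly. When the
#' upper bound reaches 4 (the 10,000-year interval cap), a fixed fraction of
#' cells (default 5%) is drawn as truly unburnt (`ba = 0`), as commonly seen
#' in burned-area records.
#'
#' @param n_cells Number of cells (>= 0).
#' @param log_afi_range Length-2 interval within \[-0.1, 4\].
#' @param epsilon Fire-interval regularization constant (y^-1).
#' @param zero_ba_frac Fraction of unburnt cells when the range top is 4.
#' @param seed Optional integer seed.
#' @return A tibble with columns `cell_id` and `ba` (annual burnt fraction).
#' @export
#' @examples
#' ba <- simulate_burnt_area(100, c(0, 4), seed = 1)
#' range(fire_interval(ba$ba)$log_afi)
simulate_burnt_area <- function(n_cells, log_afi_range = c(0, 4),
                                epsilon = 1e-4, zero_ba_frac = 0.05,
                                seed = NULL) {
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 0) {
    abort("`n_cells` must be a single non-negative integer.",
      class = "tgbcover_error_param"
    )
  }
  if (!is.numeric(log_afi_range) || length(log_afi_range) != 2 ||
    any(is.na(log_afi_range)) || log_afi_range[1] > log_afi_range[2] ||
    log_afi_range[1] < -0.1 || log_afi_range[2] > 4) {
    abort("`log_afi_range` must be an ordered interval within [-0.1, 4].",
      class = "tgbcover_error_param"
    )
  }
  n_cells <- as.integer(n_cells)
  if (n_cells == 0) {
    return(tibble::tibble(cell_id = integer(0), ba = numeric(0)))
  }
  ba <- with_seed_or_rng(seed, {
    l <- runif(n_cells, log_afi_range[1], log_afi_range[2])
    b <- pmax(0, 10^(-l) - epsilon)
    if (log_afi_range[2] >= 4 && zero_ba_frac > 0) {
      n0 <- min(n_cells, ceiling(zero_ba_frac * n_cells))
      b[sample.int(n_cells, n0)] <- 0
    }
    b
  })
  tibble::tibble(cell_id = seq_len(n_cells), ba = ba)
}

#' Simulate per-cell land-cover class fractions
#'
#' Draws cells from a mixture of archetypes -- grassy-biome, shrub-dominated,
#' human/water-dominated, snow/ice and mixed "other" -- so that every
#' filtering rule has cells it accepts and cells it rejects. Each cell's
#' dominant class gets a fraction between 0.55 and 0.95 and the remainder is
#' split randomly over the other classes; fractions sum to 1 exactly.
#' Archetype counts are deterministic (largest-remainder rounding of the
#' mixture weights), so the mixture composition is guaranteed, not sampled.
#'
#' @param n_cells Number of cells (>= 0).
#' @param mixture Named non-negative weights for archetypes `tgb`,
#'   `shrubland`, `human_water`, `snow_ice`, `other`; normalized internally.
#' @param seed Optional integer seed.
#' @return A tibble with columns `cell_id`, `shrubland`, `human_water`,
#'   `snow_ice`, `deciduous_grassland`, `other` (fractions summing to 1).
#' @export
#' @examples
#' lc <- simulate_landcover(20, seed = 1)
#' all(abs(rowSums(lc[, -1]) - 1) < 1e-12)
simulate_landcover <- function(n_cells,
                               mixture = c(
                                 tgb = 0.74, shrubland = 0.10,
                                 human_water = 0.10, snow_ice = 0.02,
                                 other = 0.04
                               ),
                               seed = NULL) {
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 0) {
    abort("`n_cells` must be a single non-negative integer.",
      class = "tgbcover_error_param"
    )
  }
  archetypes <- c("tgb", "shrubland", "human_water", "snow_ice", "other")
  if (!all(archetypes %in% names(mixture)) || any(mixture < 0) || sum(mixture) <= 0) {
    abort("`mixture` must give non-negative weights for all five archetypes.",
      class = "tgbcover_error_param"
    )
  }
  n_cells <- as.integer(n_cells)
  classes <- c("shrubland", "human_water", "snow_ice", "deciduous_grassland", "other")
  if (n_cells == 0) {
    out <- tibble::as_tibble(setNames(
      c(list(integer(0)), rep(list(numeric(0)), 5)), c("cell_id", classes)
    ))
    return(out)
  }
  w <- mixture[archetypes] / sum(mixture[archetypes])
  # largest-remainder apportionment
  raw <- w * n_cells
  counts <- floor(raw)
  rem <- n_cells - sum(counts)
  if (rem > 0) {
    top <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  dominant_class <- c(
    tgb = "deciduous_grassland", shrubland = "shrubland",
    human_water = "human_water", snow_ice = "snow_ice", other = "other"
  )
  with_seed_or_rng(seed, {
    arche <- rep(archetypes, times = counts)
    fr <- matrix(0, nrow = n_cells, ncol = 5, dimnames = list(NULL, classes))
    dom <- runif(n_cells, 0.55, 0.95)
    for (i in seq_len(n_cells)) {
      d <- dominant_class[[arche[i]]]
      others <- setdiff(classes, d)
      if (arche[i] == "other") {
        # mixed cells: no class clearly dominant
        dom[i] <- runif(1, 0.25, 0.45)
      }
      fr[i, d] <- dom[i]
      if (arche[i] == "tgb") {
        # grassy-biome cells stay under the shrub and disturbance masks
        split <- runif(3)
        minor <- 0.4 * (1 - dom[i]) * split / sum(split)
        fr[i, c("shrubland", "human_water", "snow_ice")] <- minor
        fr[i, "other"] <- 1 - dom[i] - sum(minor)
      } else {
        split <- runif(4)
        fr[i, others] <- (1 - dom[i]) * split / sum(split)
      }
    }
    out <- tibble::as_tibble(fr)
    out$cell_id <- seq_len(n_cells)
    dplyr::relocate(out, "cell_id")
  })
}

#' Simulate fractional cover from a logit-linear generating model
#'
#' Given (standardized) predictor columns and a named coefficient vector on
#' the logit scale, draws per-cell cover as a binomial fraction:
#' `Binomial(n_trials, logistic(eta)) / n_trials`, with `eta` the linear (or
#' quadratic) predictor. Coefficient names are `"intercept"` plus predictor
#' column names, with squared terms written `"name^2"` (cubes `"name^3"`).
#'
#' @param predictors A data frame of predictor columns.
#' @param coefficients Named numeric vector including `"intercept"`.
#' @param n_trials Binomial denominator per cell (>= 1).
#' @param seed Optional integer seed.
#' @return A numeric vector of cover fractions in \[0, 1\].
#' @export
#' @examples
#' z <- data.frame(mar = rnorm(5))
#' simulate_cover(z, c(intercept = -3.85, mar = 0.55), seed = 1)
simulate_cover <- function(predictors, coefficients, n_trials = 100,
                           seed = NULL) {
  if (is.null(names(coefficients)) || !"intercept" %in% names(coefficients)) {
    abort("`coefficients` must be named and include an `intercept` term.",
      class = "tgbcover_error_param"
    )
  }
  if (!is.numeric(n_trials) || n_trials < 1) {
    abort("`n_trials` must be at least 1.", class = "tgbcover_error_param")
  }
  eta <- rep(coefficients[["intercept"]], nrow(predictors))
  for (nm in setdiff(names(coefficients), "intercept")) {
    tt <- as_terms(nm)
    if (!tt$predictor %in% names(predictors)) {
      abort(paste0("coefficient term `", nm, "` names no predictor column."),
        class = "tgbcover_error_param"
      )
    }
    eta <- eta + coefficients[[nm]] * predictors[[tt$predictor]]^tt$power
  }
  p <- plogis(eta)
  with_seed_or_rng(seed, rbinom(length(p), as.integer(n_trials), p) / n_trials)
}

#' Default synthetic-study scenario
#'
#' The study conditions the generator emulates: 694, 783 and 215 grid cells
#' in the low, intermediate and high MAR ranges (1692 in total), an 11-year
#' daily rainfall record, percent-resolution cover (100 binomial trials per
#' cell), and generating cover models taken from the best per-range
#' binomial-logit fits (on the standardized-predictor scale). Per-range
#' rainfall regimes (wet-season length, event frequency, target MAR) and
#' fire-interval ranges are set to values typical of dry, mesic and humid
#' African grassy biomes; target MAR is drawn away from the range boundaries
#' so the realized (stochastic) MAR classifies each cell into its intended
#' range. High-MAR grass cover, for which no predictor model is supported,
#' is generated from an intercept-only model.
#'
#' @param n_cells Named counts of surviving TGB cells per range.
#' @param n_masked Extra cells with shrub/human/water/snow land cover, spread
#'   over the ranges, that the filtering stage must remove.
#' @param n_years Years of daily rainfall per cell.
#' @param n_trials Binomial denominator for cover generation.
#' @return A scenario list understood by [make_dataset()].
#' @export
default_scenario <- function(n_cells = c(R1 = 694, R2 = 783, R3 = 215),
                             n_masked = 40, n_years = 11, n_trials = 100) {
  list(
    n_cells = n_cells,
    n_masked = n_masked,
    n_years = n_years,
    n_trials = n_trials,
    models = list(
      R1 = list(
        tree = c(intercept = -3.85, mar = 0.55),
        grass = c(intercept = 0.22, si = -0.42, lambda_w = 0.38)
      ),
      R2 = list(
        tree = c(intercept = -1.48, lambda_w = 0.49, "lambda_w^2" = 0.14),
        grass = c(intercept = 0.73, log_afi = -0.17, lambda_w = -0.17)
      ),
      R3 = list(
        tree = c(intercept = -1.62, alpha_w = -0.41),
        grass = c(intercept = -0.2)
      )
    ),
    mar_target = list(R1 = c(150, 480), R2 = c(780, 1020), R3 = c(1400, 2250)),
    wet_month_counts = list(R1 = 3:5, R2 = 5:7, R3 = 7:9),
    event_prob = list(R1 = c(0.25, 0.5), R2 = c(0.3, 0.7), R3 = c(0.45, 0.8)),
    alpha_max = list(R1 = 12, R2 = 12, R3 = 15),
    log_afi = list(R1 = c(0.5, 3), R2 = c(0, 1.5), R3 = c(0.5, 2.5)),
    dry_drizzle_prob = 0.05,
    dry_mean_depth = 0.5,
    p_thr = 0.5,
    wet_day_threshold = 0.1,
    epsilon = 1e-4
  )
}

#' Reduced scenario for quick examples and tests
#'
#' Same structure and per-range regimes as [default_scenario()], with fewer
#' cells and years so a full pipeline run takes seconds.
#'
#' @inheritParams default_scenario
#' @export
small_scenario <- function(n_cells = c(R1 = 80, R2 = 90, R3 = 40),
                           n_masked = 12, n_years = 6, n_trials = 100) {
  default_scenario(
    n_cells = n_cells, n_masked = n_masked,
    n_years = n_years, n_trials = n_trials
  )
}

check_scenario <- function(scenario) {
  ranges <- c("R1", "R2", "R3")
  ok <- is.list(scenario) &&
    all(c(
      "n_cells", "n_masked", "n_years", "n_trials", "models", "mar_target",
      "wet_month_counts", "event_prob", "log_afi"
    ) %in% names(scenario)) &&
    all(ranges %in% names(scenario$n_cells)) &&
    all(scenario$n_cells >= 0) && scenario$n_masked >= 0 &&
    scenario$n_years >= 1 && scenario$n_trials >= 1 &&
    all(purrr::map_lgl(
      scenario$models[ranges],
      ~ all(c("tree", "grass") %in% names(.x))
    ))
  if (!ok) {
    abort("inconsistent scenario configuration.", class = "tgbcover_error_param")
  }
  invisible(scenario)
}

# contiguous wet-season months of length m starting at `start` (wraps Dec->Jan)
contiguous_months <- function(start, m) {
  ((start - 1 + seq_len(m) - 1) %% 12) + 1
}

#' Generate a complete synthetic study
#'
#' End-to-end synthetic input set: per-cell daily rainfall (simulated from
#' per-range regimes and summarised into rainfall metrics), burnt-area
#' fractions and fire intervals, land-cover fractions, and tree/grass cover
#' drawn from the scenario's generating logit models on within-range
#' standardized predictors. Cells flagged for masking get shrub-, human/
#' water- or snow-dominated land cover; surviving cells are grassy-biome
#' cells. Output is byte-identical under a fixed seed.
#'
#' @param scenario A scenario list from [default_scenario()] or
#'   [small_scenario()].
#' @param seed Integer seed for the whole study.
#' @param keep_daily Keep the per-cell daily rainfall series (long tibble) in
#'   the result; off by default as it is large.
#' @return An object of class `tgb_dataset`: a list with `cells` (one row per
#'   generated cell: coordinates, land-cover fractions, rainfall metrics,
#'   `ba`/`afi`/`log_afi`, `tree`, `grass`, and the generating-range label
#'   `range_target`), `daily` (`NULL` unless `keep_daily`), `scenario` and
#'   `seed`.
#' @export
#' @examples
#' ds <- make_dataset(small_scenario(), seed = 1)
#' nrow(ds$cells)
make_dataset <- function(scenario = default_scenario(), seed = 1,
                         keep_daily = FALSE) {
  check_scenario(scenario)
  ranges <- c("R1", "R2", "R3")
  n_per <- scenario$n_cells[ranges]
  n_tgb <- sum(n_per)
  n_masked <- scenario$n_masked
  n_total <- n_tgb + n_masked
  if (n_total == 0) {
    warn("empty scenario: no cells generated.")
    return(structure(
      list(
        cells = tibble::tibble(), daily = NULL,
        scenario = scenario, seed = seed
      ),
      class = "tgb_dataset"
    ))
  }
  withr::with_seed(seed, {
    # masked cells are spread over the ranges proportionally
    range_of <- c(
      rep(ranges, times = n_per),
      if (n_masked > 0) {
        sample(ranges, n_masked,
          replace = TRUE,
          prob = if (n_tgb > 0) n_per / n_tgb else rep(1 / 3, 3)
        )
      } else {
        character(0)
      }
    )
    is_masked <- c(rep(FALSE, n_tgb), rep(TRUE, n_masked))

    metrics <- vector("list", n_total)
    daily_list <- if (keep_daily) vector("list", n_total) else NULL
    for (i in seq_len(n_total)) {
      r <- range_of[i]
      m <- if (length(scenario$wet_month_counts[[r]]) == 1) {
        scenario$wet_month_counts[[r]]
      } else {
        sample(scenario$wet_month_counts[[r]], 1)
      }
      wet <- contiguous_months(sample.int(12, 1), m)
      l_w <- sum(MONTH_LENGTHS[wet])
      lam <- runif(1, scenario$event_prob[[r]][1], scenario$event_prob[[r]][2])
      mar_target <- runif(1, scenario$mar_target[[r]][1], scenario$mar_target[[r]][2])
      drizzle <- (DAYS_PER_YEAR - l_w) * scenario$dry_drizzle_prob *
        scenario$dry_mean_depth
      # keep event intensity realistic: if the drawn frequency would demand
      # a mean depth above the range cap, raise the frequency instead
      a_max <- scenario$alpha_max[[r]] %||% Inf
      lam <- min(max(lam, (mar_target - drizzle) / (a_max * l_w)), 0.95)
      alpha <- max(0.5, (mar_target - drizzle) / (lam * l_w))
      is_wet <- MONTH_OF_DOY %in% wet
      n_days <- DAYS_PER_YEAR * scenario$n_years
      p <- rep.int(
        ifelse(is_wet, lam, scenario$dry_drizzle_prob),
        scenario$n_years
      )
      mu <- rep.int(
        ifelse(is_wet, alpha, scenario$dry_mean_depth),
        scenario$n_years
      )
      depth <- rbinom(n_days, 1L, p) * mu * rexp(n_days, rate = 1)
      mat <- matrix(depth, nrow = DAYS_PER_YEAR, ncol = scenario$n_years)
      metrics[[i]] <- metrics_from_matrix(
        mat, scenario$p_thr, scenario$wet_day_threshold
      )
      if (keep_daily) {
        daily_list[[i]] <- tibble::tibble(
          cell_id = i,
          year = rep(seq_len(scenario$n_years), each = DAYS_PER_YEAR),
          doy = rep.int(seq_len(DAYS_PER_YEAR), scenario$n_years),
          depth = depth
        )
      }
    }
    cells <- tibble::tibble(
      cell_id = seq_len(n_total),
      lon = runif(n_total, -15, 45),
      lat = runif(n_total, -35, 15),
      range_target = range_of,
      mar = purrr::map_dbl(metrics, "mar"),
      mar_w = purrr::map_dbl(metrics, "mar_w"),
      si = purrr::map_dbl(metrics, "si"),
      l_w = purrr::map_dbl(metrics, "l_w"),
      l_w_si = purrr::map_dbl(metrics, "l_w_si"),
      alpha_w = purrr::map_dbl(metrics, "alpha_w"),
      lambda_w = purrr::map_dbl(metrics, "lambda_w"),
      c = purrr::map_dbl(metrics, "c")
    )

    # fire: per-range log-AFI regimes, inverted through the regularization
    ba <- numeric(n_total)
    for (r in ranges) {
      idx <- which(range_of == r)
      if (length(idx) == 0) next
      l <- runif(length(idx), scenario$log_afi[[r]][1], scenario$log_afi[[r]][2])
      ba[idx] <- pmax(0, 10^(-l) - scenario$epsilon)
    }
    cells <- dplyr::bind_cols(cells[, setdiff(names(cells), "ba")],
      fire_interval(ba, epsilon = scenario$epsilon)[, c("ba", "afi", "log_afi")]
    )

    # land cover: TGB archetype for survivors, rejected archetypes for the rest
    classes <- c("shrubland", "human_water", "snow_ice", "deciduous_grassland", "other")
    fr <- matrix(0, nrow = n_total, ncol = 5, dimnames = list(NULL, classes))
    masked_arche <- if (n_masked > 0) {
      sample(c("shrubland", "human_water", "snow_ice", "low_tgb"), n_masked,
        replace = TRUE, prob = c(0.4, 0.35, 0.05, 0.2)
      )
    } else {
      character(0)
    }
    j <- 0
    for (i in seq_len(n_total)) {
      if (!is_masked[i]) {
        # grassy-biome cell: keep disturbance and shrub well under the mask
        # thresholds (remainder <= 0.45; at most 0.4 of it leaves "other")
        dom <- runif(1, 0.55, 0.95)
        fr[i, "deciduous_grassland"] <- dom
        split <- runif(3)
        minor <- 0.4 * (1 - dom) * split / sum(split)
        fr[i, c("shrubland", "human_water", "snow_ice")] <- minor
        fr[i, "other"] <- 1 - dom - sum(minor)
      } else {
        j <- j + 1
        a <- masked_arche[j]
        dcl <- switch(a,
          shrubland = "shrubland", human_water = "human_water",
          snow_ice = "snow_ice", low_tgb = "other"
        )
        dom <- runif(1, 0.55, 0.95)
        fr[i, dcl] <- dom
        split <- runif(4)
        fr[i, setdiff(classes, dcl)] <- (1 - dom) * split / sum(split)
      }
    }
    cells <- dplyr::bind_cols(cells, tibble::as_tibble(fr))

    # cover from the per-range generating models, standardized within the
    # surviving cells of each range
    cells$tree <- NA_real_
    cells$grass <- NA_real_
    pred_vars <- c("mar", "si", "lambda_w", "alpha_w", "log_afi")
    for (r in ranges) {
      idx <- which(range_of == r & !is_masked)
      idx_all <- which(range_of == r)
      if (length(idx_all) == 0) next
      ref <- cells[idx, pred_vars, drop = FALSE]
      z <- cells[idx_all, pred_vars, drop = FALSE]
      for (v in pred_vars) {
        s <- sd(ref[[v]])
        z[[v]] <- if (length(idx) >= 2 && is.finite(s) && s > 0) {
          (z[[v]] - mean(ref[[v]])) / s
        } else {
          z[[v]] * 0
        }
      }
      cells$tree[idx_all] <- simulate_cover(
        z, scenario$models[[r]]$tree,
        n_trials = scenario$n_trials
      )
      cells$grass[idx_all] <- simulate_cover(
        z, scenario$models[[r]]$grass,
        n_trials = scenario$n_trials
      )
    }
    structure(
      list(
        cells = cells,
        daily = if (keep_daily) purrr::list_rbind(daily_list) else NULL,
        scenario = scenario, seed = seed
      ),
      class = "tgb_dataset"
    )
  })
}

#' @export
print.tgb_dataset <- function(x, ...) {
  cat("Synthetic grassy-biome study (seed ", x$seed, ")\n", sep = "")
  if (nrow(x$cells) == 0) {
    cat("  empty scenario\n")
    return(invisible(x))
  }
  cat("  cells:", nrow(x$cells), "\n")
  print(table(x$cells$range_target))
  invisible(x)
}
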