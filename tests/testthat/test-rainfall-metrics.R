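test_that("monthly climatology averages month totals over years", {
  expect_equal(
    monthly_climatology(constant_daily(0, 2))$mean_monthly,
    rep(0, 12)
  )
  clim <- monthly_climatology(constant_daily(1, 1))
  expect_equal(clim$mean_monthly[1], 31)
  expect_equal(sum(clim$mean_monthly), 365)
  two <- dplyr::bind_rows(
    constant_daily(0, 1),
    dplyr::mutate(constant_daily(1, 1), year = 2)
  )
  expect_equal(monthly_climatology(two)$mean_monthly[1], 15.5)
  # incomplete year rejected
  expect_error(
    monthly_climatology(constant_daily(1, 1)[1:100, ]),
    class = "tgbcover_error_input"
  )
})

test_that("mean annual rainfall is the mean of annual totals", {
  expect_equal(mean_annual_rainfall(constant_daily(0, 3))$mar, 0)
  expect_equal(mean_annual_rainfall(constant_daily(2, 4))$mar, 730)
  daily <- simulate_daily_rainfall(n_years = 3, seed = 7)
  expect_equal(
    mean_annual_rainfall(daily)$mar,
    sum(monthly_climatology(daily)$mean_monthly),
    tolerance = 1e-9
  )
})

test_that("seasonality index matches closed forms and stays in bounds", {
  uniform <- tibble::tibble(month = 1:12, mean_monthly = rep(100, 12))
  expect_equal(seasonality_index(uniform)$si, 0)
  single <- tibble::tibble(month = 1:12, mean_monthly = c(1200, rep(0, 11)))
  expect_equal(seasonality_index(single)$si, 22 / 12)
  two <- tibble::tibble(month = 1:12, mean_monthly = c(600, 600, rep(0, 10)))
  expect_equal(seasonality_index(two)$si, 20 / 12)
  expect_error(
    seasonality_index(tibble::tibble(month = 1:12, mean_monthly = rep(0, 12))),
    class = "tgbcover_error_zero_rainfall"
  )
  # bounds hold for arbitrary nonnegative monthly vectors
  withr::with_seed(42, {
    for (i in 1:50) {
      v <- rexp(12) * sample(c(1, 100), 12, replace = TRUE)
      si <- seasonality_index(tibble::tibble(month = 1:12, mean_monthly = v))$si
      expect_gte(si, 0)
      expect_lte(si, 22 / 12)
    }
  })
})

test_that("wet season detection follows the strict monthly threshold", {
  uniform <- tibble::tibble(month = 1:12, mean_monthly = rep(50, 12))
  ws <- wet_season(uniform, p_thr = 0.5)
  expect_equal(ws$wet_months[[1]], 1:12)
  expect_equal(ws$l_w, 365)
  july <- tibble::tibble(month = 1:12, mean_monthly = c(rep(0, 6), 800, rep(0, 5)))
  ws <- wet_season(july, p_thr = 0.5)
  expect_equal(ws$wet_months[[1]], 7L)
  expect_equal(ws$l_w, 31)
  zero <- tibble::tibble(month = 1:12, mean_monthly = rep(0, 12))
  expect_warning(ws0 <- wet_season(zero), "zero annual")
  expect_equal(ws0$l_w, 0)
  # ties (exact equality with the threshold) count as dry
  tied <- tibble::tibble(month = 1:12, mean_monthly = c(rep(100, 6), rep(50 / 6, 6)))
  thr_val <- 0.5 * sum(tied$mean_monthly) / 12
  tied$mean_monthly[7] <- thr_val
  tied$mean_monthly[8:12] <- (650 - 600 - thr_val) / 5
  # rebuild: months 1-6 at 100, month 7 exactly at threshold of the new total
  # solve total R with x7 = 0.5 R / 12 and months 8-12 zero
  r <- 600 / (1 - 0.5 / 12)
  tied <- tibble::tibble(
    month = 1:12,
    mean_monthly = c(rep(100, 6), 0.5 * r / 12, rep(0, 5))
  )
  expect_equal(wet_season(tied, 0.5)$wet_months[[1]], 1:6)
  expect_error(wet_season(uniform, p_thr = 1.2), class = "tgbcover_error_param")
})

test_that("wet-season length is non-increasing in the threshold", {
  withr::with_seed(11, {
    for (i in 1:20) {
      clim <- tibble::tibble(month = 1:12, mean_monthly = rexp(12, 1 / 50))
      lw <- vapply(
        c(0.1, 0.3, 0.5, 0.7, 0.9),
        function(p) wet_season(clim, p)$l_w, numeric(1)
      )
      expect_true(all(diff(lw) <= 0))
    }
  })
})

test_that("SI-implied wet-season length matches endpoints and decreases", {
  expect_equal(lw_from_si(0), 365)
  expect_equal(lw_from_si(1.83), 365 / 12)
  expect_equal(lw_from_si(0.915), 365 / 12 * 6.5)
  grid <- lw_from_si(seq(0, 1.8, by = 0.05))
  expect_true(all(diff(grid) < 0))
  expect_error(lw_from_si(2), class = "tgbcover_error_param")
  expect_error(lw_from_si(-0.1), class = "tgbcover_error_param")
})

test_that("wet-day statistics satisfy definitions and the water balance", {
  wet <- c(11, 12, 1, 2, 3)
  # 5 mm on every wet-season day
  monthly <- ifelse(1:12 %in% wet, 5, 0) * c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  daily <- block_daily(monthly)
  s <- wet_day_stats(daily, wet)
  expect_equal(s$alpha_w, 5)
  expect_equal(s$lambda_w, 1)
  expect_equal(s$c, 0)
  # sub-threshold drizzle only: no wet days
  drizzle <- block_daily(ifelse(1:12 %in% wet, 0.05 * 30, 0))
  drizzle$depth <- ifelse(doy_month(drizzle$doy) %in% wet, 0.05, 0)
  expect_warning(s2 <- wet_day_stats(drizzle, wet), "threshold")
  expect_true(is.na(s2$alpha_w))
  expect_equal(s2$lambda_w, 0)
  expect_equal(s2$c, s2$mar_w)
})

test_that("wet-day statistics agree with a naive day-by-day loop", {
  withr::with_seed(5, {
    for (i in 1:5) {
      wet <- sort(sample(1:12, sample(2:6, 1)))
      daily <- simulate_daily_rainfall(
        n_years = 2, wet_months = wet,
        event_prob = runif(1, 0.2, 0.8), mean_depth = runif(1, 2, 15)
      )
      got <- wet_day_stats(daily, wet)
      want <- naive_wet_stats(daily, wet)
      expect_equal(got$mar_w, want$mar_w)
      expect_equal(got$alpha_w, want$alpha_w)
      expect_equal(got$lambda_w, want$lambda_w)
      expect_equal(got$c, want$c)
      # water-balance identity
      expect_lte(
        abs(got$mar_w - (got$alpha_w * got$lambda_w * got$l_w + got$c)),
        1e-6 * max(1, got$mar_w)
      )
    }
  })
})

test_that("rainfall_metrics recovers generator targets on long records", {
  daily <- simulate_daily_rainfall(
    n_years = 50, wet_months = c(12, 1, 2, 3, 4),
    event_prob = 0.4, mean_depth = 10,
    dry_drizzle_prob = 0, seed = 31
  )
  m <- rainfall_metrics(daily)
  expect_equal(sort(m$wet_months[[1]]), sort(c(12, 1, 2, 3, 4)))
  expect_equal(m$l_w, 31 + 31 + 28 + 31 + 30)
  expect_equal(m$lambda_w, 0.4, tolerance = 0.05)
  expect_equal(m$alpha_w, 10, tolerance = 0.05)
  expect_lte(abs(m$l_w - 30.4 * 5) / (30.4 * 5), 0.05)
})

test_that("threshold calibration finds the constructed optimum", {
  # four cells whose SI is affine in the wet-season length detected at
  # p_thr = 0.5 (perfect correlation there); medium-level months join the
  # wet season at p_thr = 0.3 and scramble the relation
  r <- 1200
  cells <- list(
    c(1060, rep(2.5, 8), 40, 40, 40), # 1 wet month + 3 medium
    c(546.4, 546.4, rep(107.2 / 10, 10)), # 2 wet months
    c(372.8, 372.8, 372.8, rep(41.6 / 8, 8), 40), # 3 wet + 1 medium
    c(rep(286.6, 4), rep(53.6 / 8, 8)) # 4 wet months
  )
  daily <- purrr::imap(cells, ~ block_daily(.x, cell_id = .y)) |>
    purrr::list_rbind()
  cal <- calibrate_pthr(daily, p_thr_grid = c(0.3, 0.5, 0.7))
  expect_s3_class(cal, "pthr_calibration")
  expect_equal(cal$p_thr, 0.5)
  r2_05 <- cal$curve$r_squared[cal$curve$p_thr == 0.5]
  expect_gt(r2_05, 1 - 1e-10)
  expect_lt(cal$curve$r_squared[cal$curve$p_thr == 0.3], 0.9)
  # single candidate returned unchanged
  one <- calibrate_pthr(daily, p_thr_grid = 0.4)
  expect_equal(one$p_thr, 0.4)
  # aseasonal grid: degenerate correlation
  flat <- purrr::map(1:3, ~ dplyr::mutate(constant_daily(1), cell_id = .x)) |>
    purrr::list_rbind()
  expect_error(
    calibrate_pthr(flat, p_thr_grid = c(0.3, 0.5)),
    class = "tgbcover_error_degenerate"
  )
})

test_that("calibration on a realistic grid is strong at the default threshold", {
  daily <- withr::with_seed(77, {
    purrr::map(1:40, function(i) {
      m <- sample(2:11, 1)
      start <- sample(1:12, 1)
      wet <- ((start - 1 + seq_len(m) - 1) %% 12) + 1
      dplyr::mutate(
        simulate_daily_rainfall(
          n_years = 4, wet_months = wet,
          event_prob = runif(1, 0.3, 0.7),
          mean_depth = runif(1, 5, 15)
        ),
        cell_id = i
      )
    }) |> purrr::list_rbind()
  })
  cal <- calibrate_pthr(daily, p_thr_grid = c(0.3, 0.5, 0.7))
  expect_gte(cal$curve$r_squared[cal$curve$p_thr == 0.5], 0.9)
})
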