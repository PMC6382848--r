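test_that("standardization centres and scales with the n-1 convention", {
  out <- standardize_predictors(data.frame(x = c(1, 2, 3)), "x")
  expect_equal(out$x, c(-1, 0, 1))
  st <- standardization(out)
  expect_equal(st$mean, 2)
  expect_equal(st$sd, 1)
  # idempotent on an already standardized column
  again <- standardize_predictors(out, "x")
  expect_equal(again$x, out$x)
  withr::with_seed(1, {
    d <- data.frame(a = rnorm(50, 10, 3), b = runif(50))
    z <- standardize_predictors(d, c("a", "b"))
    expect_lt(abs(mean(z$a)), 1e-10)
    expect_equal(sd(z$a), 1, tolerance = 1e-10)
  })
  expect_error(
    standardize_predictors(data.frame(x = rep(1, 5)), "x"),
    class = "tgbcover_error_degenerate"
  )
})

test_that("model enumeration produces the full candidate set", {
  specs <- enumerate_models()
  expect_equal(nrow(specs), 34)
  expect_equal(sum(specs$type == "polynomial"), 15)
  expect_equal(sum(specs$type == "combination"), 18)
  expect_equal(sum(specs$type == "intercept"), 1)
  # no candidate contains both intensity and frequency
  both <- purrr::map_lgl(
    specs$terms,
    ~ all(c("alpha_w", "lambda_w") %in% .x$predictor)
  )
  expect_false(any(both))
  # polynomials are nested: powers 1..k
  polys <- specs$terms[specs$type == "polynomial"]
  expect_true(all(purrr::map_lgl(polys, ~ identical(.x$power, seq_len(max(.x$power))))))
  # combinations are linear only, with >= 2 distinct predictors
  combos <- specs$terms[specs$type == "combination"]
  expect_true(all(purrr::map_lgl(combos, ~ all(.x$power == 1) && nrow(.x) >= 2)))
  # reduced predictor sets
  expect_equal(nrow(enumerate_models("x", exclude = NULL)), 4)
  expect_equal(nrow(enumerate_models(c("alpha_w", "lambda_w"))), 7)
  expect_error(
    enumerate_models(c("a", "b"), exclude = c("a", "z")),
    class = "tgbcover_error_param"
  )
})

test_that("binomial GLM fits match closed forms and the likelihood oracle", {
  # intercept-only on fractions with mean 0.5
  d <- data.frame(cov = c(0.2, 0.8, 0.4, 0.6))
  fit <- fit_cover_glm(d, "cov", NULL)
  expect_equal(unname(coef(fit$fit)), 0, tolerance = 1e-10)
  expect_equal(pseudo_r2(fit), 0)
  # coefficients match an independent numerical likelihood maximizer
  withr::with_seed(21, {
    x <- rnorm(20)
    z <- rnorm(20)
    k <- rbinom(20, 100, plogis(-0.5 + 0.8 * x - 0.3 * z))
    d <- data.frame(x = x, z = z, cov = k / 100)
    fit <- fit_cover_glm(d, "cov", c("x", "z"))
    want <- oracle_binomial_fit(cbind(x, z), k, 100)
    expect_equal(unname(coef(fit$fit)), want, tolerance = 1e-6)
  })
  expect_error(
    fit_cover_glm(data.frame(cov = c(0.5, 1.2)), "cov", NULL),
    class = "tgbcover_error_input"
  )
})

test_that("coefficient recovery from a known generating model", {
  withr::with_seed(8, {
    z <- rnorm(694)
    d <- data.frame(mar = z)
    d$cov <- simulate_cover(d, c(intercept = -3.85, mar = 0.55))
    fit <- fit_cover_glm(d, "cov", "mar")
    td <- generics::tidy(fit)
    expect_lt(abs(td$estimate[1] - (-3.85)), 3 * td$std.error[1])
    expect_lt(abs(td$estimate[2] - 0.55), 3 * td$std.error[2])
  })
})

test_that("residual deviance never increases when a term is added", {
  withr::with_seed(13, {
    d <- data.frame(a = rnorm(120), b = rnorm(120))
    d$cov <- rbinom(120, 100, plogis(0.2 + 0.4 * d$a)) / 100
    dev1 <- glance(fit_cover_glm(d, "cov", "a"))$deviance
    dev2 <- glance(fit_cover_glm(d, "cov", c("a", "b")))$deviance
    dev3 <- glance(fit_cover_glm(d, "cov", c("a", "a^2")))$deviance
    dev0 <- glance(fit_cover_glm(d, "cov", NULL))$deviance
    expect_lte(dev1, dev0)
    expect_lte(dev2, dev1)
    expect_lte(dev3, dev1)
  })
})

test_that("pseudo-R2 is explained deviance, bounded in [0, 1]", {
  withr::with_seed(14, {
    d <- data.frame(x = rnorm(200))
    d$cov <- rbinom(200, 100, plogis(1.2 * d$x)) / 100
    fit <- fit_cover_glm(d, "cov", "x")
    r2 <- pseudo_r2(fit)
    expect_gte(r2, 0)
    expect_lte(r2, 1)
    expect_equal(r2, 1 - fit$fit$deviance / fit$fit$null.deviance)
    # noise-free fractions at huge trial counts approach full explanation
    d$cov <- plogis(3 * d$x)
    fit_big <- fit_cover_glm(d, "cov", "x", n_trials = 1e6)
    expect_gt(pseudo_r2(fit_big), 0.99)
  })
})

test_that("AIC selection ranks candidates and flags the retained set", {
  specs <- enumerate_models(c("a", "b"), exclude = NULL)
  # constant response: the intercept-only model must win
  withr::with_seed(15, {
    d <- data.frame(a = rnorm(150), b = rnorm(150), cov = 0.5)
    sel <- select_models(d, "cov", specs)
    expect_equal(sel$label[1], "1")
    expect_equal(sel$delta_aic[1], 0)
    expect_false(any(sel$retained))
    # strong signal: the generating term set wins and is retained
    d$cov <- rbinom(150, 100, plogis(0.3 - 0.9 * d$a)) / 100
    sel2 <- select_models(d, "cov", specs)
    expect_true("a" %in% strsplit(sel2$label[1], " \\+ ")[[1]])
    expect_true(sel2$retained[1])
    expect_s3_class(best_fit(sel2), "cover_glm")
    expect_equal(glance(best_fit(sel2))$aic, sel2$aic[1])
  })
})

test_that("parabolic fits locate the extremum on both scales", {
  # fractions generated (noise-free at huge n_trials) from a known parabola
  z <- seq(-3, 3, length.out = 201)
  d <- data.frame(lambda_w = z)
  d$cov <- plogis(-1.48 + 0.49 * z + 0.14 * z^2)
  fit <- fit_cover_glm(d, "cov", c("lambda_w", "lambda_w^2"), n_trials = 1e5)
  ext <- parabola_extremum(fit)
  expect_equal(ext$vertex_std, -0.49 / (2 * 0.14), tolerance = 1e-2)
  expect_equal(ext$kind, "minimum")
  expect_true(is.na(ext$vertex_natural))
  # with standardization attached, the natural-units location is mean + sd * z
  raw <- data.frame(lambda_w = 0.5 + 0.1 * z)
  std <- standardize_predictors(raw, "lambda_w")
  std$cov <- plogis(-1.48 + 0.49 * std$lambda_w + 0.14 * std$lambda_w^2)
  fit2 <- fit_cover_glm(std, "cov", c("lambda_w", "lambda_w^2"), n_trials = 1e5)
  ext2 <- parabola_extremum(fit2)
  st <- standardization(std)
  expect_equal(
    ext2$vertex_natural,
    st$mean + st$sd * ext2$vertex_std
  )
  # symmetric parabola: vertex at the predictor mean
  d$cov <- plogis(-1 + 0.2 * z^2)
  fit3 <- fit_cover_glm(d, "cov", c("lambda_w", "lambda_w^2"), n_trials = 1e5)
  expect_equal(parabola_extremum(fit3)$vertex_std, 0, tolerance = 1e-2)
  # concave parabola labelled as maximum
  d$cov <- plogis(-1 + 0.5 * z - 0.2 * z^2)
  fit4 <- fit_cover_glm(d, "cov", c("lambda_w", "lambda_w^2"), n_trials = 1e5)
  expect_equal(parabola_extremum(fit4)$kind, "maximum")
  # no quadratic term
  expect_error(
    parabola_extremum(fit_cover_glm(d, "cov", "lambda_w")),
    class = "tgbcover_error_param"
  )
})
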