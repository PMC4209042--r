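test_that("fit_lasso matches its analytic limits", {
  d <- toy_xy(n = 50, p = 6, seed = 2)
  grid <- make_penalty_grid(d$X, d$y)

  # strongest grid penalty is lambda_max: all slopes exactly zero
  m0 <- fit_lasso(d$X, d$y, grid[1])
  expect_identical(unname(m0$coefficients), rep(0, 6))
  expect_equal(m0$intercept, mean(d$y))
  m0b <- fit_lasso(d$X, d$y, grid[1] * 10)
  expect_identical(unname(m0b$coefficients), rep(0, 6))

  # zero penalty reproduces ordinary least squares
  mols <- fit_lasso(d$X, d$y, 0)
  ref <- unname(coef(lm(d$y ~ d$X)))
  expect_equal(c(mols$intercept, unname(mols$coefficients)), ref,
               tolerance = 1e-10)

  # constant outcome: intercept-only model
  mc <- fit_lasso(d$X, rep(2, 50), 0.1)
  expect_equal(mc$intercept, 2)
  expect_true(all(mc$coefficients == 0))
})

test_that("fit_lasso solves the convex program (FISTA oracle)", {
  for (i in 1:10) {
    d <- toy_xy(n = 20, p = 5, seed = 100 + i, sparse = FALSE)
    lam <- exp(runif(1, log(0.01), log(0.5)))
    fit <- fit_lasso(d$X, d$y, lam)
    orc <- oracle_lasso_fista(d$X, d$y, lam)
    o_fit <- lasso_objective(d$X, d$y, fit$intercept, fit$coefficients, lam)
    o_orc <- lasso_objective(d$X, d$y, orc$intercept, orc$coefficients, lam)
    expect_lt(abs(o_fit - o_orc), 1e-6)
  }
})

test_that("penalty grid is log-spaced, descending, anchored at lambda_max", {
  d <- toy_xy(n = 60, p = 8, seed = 3)
  g <- make_penalty_grid(d$X, d$y)
  expect_length(g, 40)
  expect_true(all(diff(g) < 0))
  ratios <- g[-1] / g[-length(g)]
  expect_equal(ratios, rep(ratios[1], length(ratios)), tolerance = 1e-10)
  expect_equal(g[length(g)], g[1] * 1e-3, tolerance = 1e-12)
  expect_error(make_penalty_grid(matrix(1, 10, 3), rnorm(10)), "constant")
})

test_that("L1 norm of the solution path is non-increasing in the penalty", {
  d <- toy_xy(n = 80, p = 10, seed = 4)
  g <- make_penalty_grid(d$X, d$y, n_lambda = 12)
  norms <- vapply(g, function(l) {
    sum(abs(fit_lasso(d$X, d$y, l)$coefficients))
  }, numeric(1))
  expect_true(all(diff(norms) >= -1e-8))  # descending grid: norms grow
})

test_that("penalty tuning honors best/tolerance semantics", {
  dd <- toy_dataset(n = 80, p = 8, seed = 5)
  g <- make_penalty_grid(dd, n_lambda = 25)
  tr <- tune_penalty(dd, grid = g, n_boot = 40, seed = 9)

  # exhaustive scan of the stored MSE vector
  expect_equal(tr$best_lambda, g[which.min(tr$mean_boot_mse)])
  expect_gte(tr$tolerance_lambda, tr$best_lambda)
  expect_lte(tr$mean_boot_mse[tr$tolerance_index],
             1.03 * min(tr$mean_boot_mse))
  stronger <- which(g > tr$tolerance_lambda)
  if (length(stronger)) {
    expect_true(all(tr$mean_boot_mse[stronger] >
                      1.03 * min(tr$mean_boot_mse)))
  }

  # deterministic under a seed
  tr2 <- tune_penalty(dd, grid = g, n_boot = 40, seed = 9)
  expect_identical(tr$mean_boot_mse, tr2$mean_boot_mse)

  # single-penalty grid degenerates to best = tolerance
  tr1 <- tune_penalty(dd, grid = g[5], n_boot = 5, seed = 1)
  expect_equal(tr1$best_lambda, g[5])
  expect_equal(tr1$tolerance_lambda, g[5])

  expect_error(tune_penalty(dd, grid = g, n_boot = 0))
})

test_that("pooling averages coefficients with zeros included", {
  mk <- function(v) fixed_model(0, setNames(v, c("x1", "x2")))
  pm <- pool_models(list(mk(c(1, 0)), mk(c(0, 1)), mk(c(1, 1))))
  expect_equal(unname(pm$coefficients), c(2 / 3, 2 / 3))
  expect_equal(unname(pm$selection_counts), c(2, 2))

  # a covariate picked in 1 of 10 sets has its value divided by 10
  mods <- c(list(fixed_model(0, c(x1 = 0.5))),
            replicate(9, fixed_model(0, c(x1 = 0)), simplify = FALSE))
  pm10 <- pool_models(mods)
  expect_equal(unname(pm10$coefficients), 0.05)
  expect_equal(unname(pm10$selection_counts), 1)

  # pooling commutes with scaling
  scaled <- pool_models(list(mk(c(2, 0)), mk(c(0, 2)), mk(c(2, 2))))
  expect_equal(scaled$coefficients, 2 * pm$coefficients)
})

test_that("identical imputed sets pool to the single-set model", {
  dd <- toy_dataset(n = 60, p = 6, seed = 6)
  imp_like <- replicate(4, dd, simplify = FALSE)
  pooled <- fit_pooled(imp_like, mode = "best", n_lambda = 15, n_boot = 20,
                       seed = 13)
  single <- fit_pooled(list(dd), mode = "best", n_lambda = 15, n_boot = 20,
                       seed = 13)
  expect_equal(pooled$coefficients, single$coefficients)
  expect_equal(pooled$intercept, single$intercept)
  expect_equal(unname(pooled$selection_counts),
               4 * unname(single$selection_counts))
})
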