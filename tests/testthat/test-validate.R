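test_that("validation reports satisfy their bookkeeping identities", {
  dd <- toy_dataset(n = 60, p = 5, seed = 11)
  rep <- harrell_validate(dd, B = 8, mode = "best", n_lambda = 10,
                          n_boot_tune = 10, seed = 17)
  expect_equal(rep$boot$optimism_star,
               rep$boot$apparent_star - rep$boot$test_star)
  expect_equal(rep$corrected_performance,
               rep$apparent - mean(rep$boot$optimism_star))
  expect_equal(rep$shrinkage_s, mean(rep$boot$lp_slope))

  # the arithmetic of optimism-corrected MSE
  expect_equal(corrected_performance(0.9047, -0.1162), 1.0209)
  expect_equal(corrected_performance(2, c(-0.5, -1.5)), 3)
  expect_equal(corrected_performance(1.3, c(0, 0, 0)), 1.3)
  expect_error(corrected_performance(1, numeric(0)))
})

test_that("a data-independent perfect model shows zero optimism", {
  # noiseless outcome + builder returning the true coefficients: apparent*
  # and test* are both exactly zero in every bootstrap
  set.seed(12)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  beta <- c(1, -1, 0.5, 0)
  dd <- mi_dataset(cbind(X, y = 2 + drop(X %*% beta)))
  truth <- fixed_model(2, setNames(beta, colnames(X)))
  rep <- harrell_validate(dd, B = 5, mode = "best", seed = 3,
                          builder = function(sets) truth)
  expect_identical(rep$boot$optimism_star, rep(0, 5))
  expect_equal(rep$corrected_performance, rep$apparent)
  expect_equal(rep$boot$lp_slope, rep(1, 5))
})

test_that("shrinkage factor averages bootstrap calibration slopes", {
  expect_equal(shrinkage_factor(c(1.2, 1.2, 1.2)), 1.2)
  expect_warning(s <- shrinkage_factor(c(2, NA, 4)), "non-finite")
  expect_equal(s, 3)

  # noiseless data scored by a halved-coefficient model: every slope is 2
  set.seed(13)
  X <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, paste0("x", 1:3)))
  beta <- c(2, -1, 1)
  dd <- mi_dataset(cbind(X, y = 1 + drop(X %*% beta)))
  halved <- fixed_model(0.5, setNames(beta / 2, colnames(X)))
  rep <- harrell_validate(dd, B = 4, mode = "best", seed = 5,
                          builder = function(sets) halved)
  expect_equal(rep$boot$lp_slope, rep(2, 4), tolerance = 1e-10)
  expect_equal(shrinkage_factor(rep), 2, tolerance = 1e-10)
})

test_that("approach 3 reproduces the standalone Harrell procedure", {
  dd <- toy_dataset(n = 70, p = 6, seed = 14)
  pkg <- bootstrap_optimism(list(dd), approach = 3, B = 6,
                            mode = c("best", "tolerance"), n_lambda = 12,
                            n_boot_tune = 15, seed = 77)
  orc <- oracle_harrell(dd, B = 6, n_boot_tune = 15, n_lambda = 12,
                        seed = 77)
  for (md in c("best", "tolerance")) {
    expect_equal(pkg[[md]]$boot, orc[[md]], tolerance = 1e-12)
  }
})

test_that("approaches 1 and 3 coincide on identical imputed copies", {
  dd <- toy_dataset(n = 60, p = 5, seed = 15)
  copies <- structure(list(sets = replicate(4, dd, simplify = FALSE), m = 4),
                      class = "mi_imputed")
  r1 <- bootstrap_optimism(copies, approach = 1, B = 5, mode = "best",
                           n_lambda = 10, n_boot_tune = 10, seed = 21)
  r3 <- bootstrap_optimism(copies, approach = 3, B = 5, mode = "best",
                           n_lambda = 10, n_boot_tune = 10, seed = 21)
  expect_identical(r1$boot, r3$boot)
  expect_identical(r1$mean_optimism, r3$mean_optimism)
})

test_that("resampling subjects independently per set masks optimism", {
  # ten identical complete copies, mimicking imputed data with nothing to
  # impute: independent per-set resampling (approach 2) averages ten models
  # built on different resamples, so its optimism all but vanishes compared
  # to the shared-resample scheme (approach 1)
  cfg <- sim_config(n_obs = 150)
  d <- simulate_complete(cfg, seed = 16)
  copies <- structure(list(sets = replicate(10, d, simplify = FALSE),
                           m = 10), class = "mi_imputed")
  r1 <- bootstrap_optimism(copies, approach = 1, B = 12, mode = "best",
                           n_lambda = 15, n_boot_tune = 20, seed = 22)
  r2 <- bootstrap_optimism(copies, approach = 2, B = 12, mode = "best",
                           n_lambda = 15, n_boot_tune = 20, seed = 22)
  expect_lt(abs(r2$mean_optimism), abs(r1$mean_optimism))
  expect_lt(abs(r2$mean_optimism), 0.1)
})

test_that("approach 4 replays imputation inside the bootstrap", {
  cfg <- sim_config(n_obs = 120)
  d <- simulate_complete(cfg, seed = 18)
  inc <- apply_mcar(d, seed = 19)
  imp <- suppressWarnings(impute_mi(inc, m = 3, seed = 20))
  r4 <- bootstrap_optimism(imp, approach = 4, B = 3, mode = "best",
                           n_lambda = 10, n_boot_tune = 10, seed = 23,
                           raw = inc, m = 3)
  expect_equal(r4$boot$optimism_star,
               r4$boot$apparent_star - r4$boot$test_star)
  # reproducible under the same seed
  r4b <- bootstrap_optimism(imp, approach = 4, B = 3, mode = "best",
                            n_lambda = 10, n_boot_tune = 10, seed = 23,
                            raw = inc, m = 3)
  expect_identical(r4$boot, r4b$boot)
  expect_error(bootstrap_optimism(imp, approach = 4, B = 2, seed = 1),
               "raw")
  expect_error(bootstrap_optimism(imp, approach = 1, B = 0, seed = 1))
})
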