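small_cfg <- sim_config(n_obs = 100)

test_that("replicates record consistent bookkeeping", {
  rec <- run_replicate(small_cfg, setting = "NM", seed = 301,
                       n_lambda = 10, n_boot_tune = 10, n_boot_validate = 5)
  expect_equal(nrow(rec), 2)
  expect_setequal(rec$mode, c("best", "tolerance"))
  expect_equal(rec$optimism_external,
               rec$mse_apparent - rec$mse_external)
  expect_true(all(is.finite(rec$optimism_internal)))
  expect_true(all(paste0("sel_x", 1:20) %in% names(rec)))
  expect_true(all(unlist(rec[, paste0("sel_x", 1:20)]) %in% 0:1))

  # fit-only replicate skips validation
  rec0 <- run_replicate(small_cfg, setting = "NM", seed = 301,
                        n_lambda = 10, n_boot_tune = 10,
                        n_boot_validate = 0)
  expect_true(all(is.na(rec0$optimism_internal)))
  expect_equal(rec0$mse_apparent, rec$mse_apparent)
})

test_that("WM with zero missingness reduces to the NM replicate", {
  cfg0 <- small_cfg
  cfg0$miss_probs[] <- 0
  nm <- run_replicate(small_cfg, setting = "NM", seed = 777,
                      n_lambda = 10, n_boot_tune = 10, n_boot_validate = 0)
  wm <- suppressWarnings(
    run_replicate(cfg0, setting = "WM", seed = 777, m = 3,
                  n_lambda = 10, n_boot_tune = 10, n_boot_validate = 0))
  shared <- c("mse_apparent", "mse_external", "optimism_external",
              "lp_slope")
  expect_equal(unlist(wm[, shared]), unlist(nm[, shared]),
               tolerance = 1e-12)
  # selection counts scale with the number of (identical) imputed sets
  expect_equal(unname(unlist(wm[, paste0("sel_x", 1:20)])),
               3 * unname(unlist(nm[, paste0("sel_x", 1:20)])))
})

test_that("WM replicates carry approach-specific optimism", {
  rec <- suppressWarnings(
    run_replicate(small_cfg, setting = "WM", approaches = c(2, 3),
                  seed = 302, n_lambda = 8, n_boot_tune = 8,
                  n_boot_validate = 3, m = 2))
  expect_true(all(is.finite(rec$optimism_appr2)))
  expect_true(all(is.finite(rec$optimism_appr3)))
  expect_true(all(is.na(rec$optimism_appr1)))
  expect_true(all(is.na(rec$optimism_appr4)))
})

test_that("batches are reproducible and order-invariant by seeding", {
  r1 <- run_simstudy(small_cfg, "NM", n_reps = 3, seed = 99,
                     n_lambda = 8, n_boot_tune = 8, n_boot_validate = 0)
  r2 <- run_simstudy(small_cfg, "NM", n_reps = 3, seed = 99,
                     n_lambda = 8, n_boot_tune = 8, n_boot_validate = 0)
  expect_identical(r1, r2)
  expect_equal(sort(unique(r1$replicate)), 1:3)
})

test_that("selection frequencies and model rates count correctly", {
  # hand-made records: 5 replicates, 2 covariates tracked via a tiny schema
  mk <- function(sel, m = 1) {
    as.data.frame(c(list(setting = "NM", mode = "best", m = m),
                    setNames(as.list(sel), paste0("sel_x", 1:20))))
  }
  full <- rep(1, 20)
  miss6 <- full; miss6[6] <- 0          # one relevant covariate off
  miss1 <- full; miss1[1] <- 0          # an irrelevant covariate off
  recs <- rbind(mk(full), mk(full), mk(miss6), mk(miss1), mk(full))
  sf <- selection_frequencies(recs)
  freq <- sf$frequencies
  expect_equal(freq$frequency[freq$covariate == "x6"], 80)
  expect_equal(freq$frequency[freq$covariate == "x1"], 80)
  expect_equal(freq$frequency[freq$covariate == "x20"], 100)
  expect_equal(sf$model_rates$correct_model, 80)
  expect_equal(sf$model_rates$one_off, 20)

  # all-selected records give 100% everywhere
  all5 <- rbind(mk(full), mk(full))
  expect_true(all(selection_frequencies(all5)$frequencies$frequency == 100))

  # WM retention rule: >= 50% of m imputations
  wm <- rbind(mk(rep(5, 20), m = 10), mk(rep(4, 20), m = 10))
  sfwm <- selection_frequencies(wm)
  expect_true(all(sfwm$frequencies$frequency == 50))
})

test_that("summaries give means bracketed by order-statistic percentiles", {
  recs <- run_simstudy(small_cfg, "NM", n_reps = 4, seed = 50,
                       n_lambda = 8, n_boot_tune = 8, n_boot_validate = 0)
  sm <- summarize_records(recs)
  expect_true(all(sm$p2.5 <= sm$p97.5))
  expect_true(all(sm$p2.5 <= sm$mean & sm$mean <= sm$p97.5 |
                    abs(sm$p97.5 - sm$p2.5) < 1e-12))

  # identical records collapse mean and percentiles
  one <- recs[recs$replicate == 1 & recs$mode == "best", ]
  dup <- rbind(one, one, one)
  smd <- summarize_records(dup)
  expect_equal(smd$mean, smd$p2.5)
  expect_equal(smd$mean, smd$p97.5)

  # percentiles agree with a sort-and-interpolate oracle
  v <- recs$mse_apparent[recs$mode == "best"]
  expect_equal(sm$p2.5[sm$mode == "best" & sm$quantity == "mse_apparent"],
               unname(quantile(v, 0.025, type = 7)))
})
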