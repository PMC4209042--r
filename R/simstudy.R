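# Monte Carlo experiments contrasting internal (bootstrap) and external
# optimism of the pooled lasso, in a no-missing-data (NM) and a
# with-missing-data (WM) setting, plus covariate-selection summaries.

#' Run one simulation replicate
#'
#' Simulates a training data set from `config`; in the WM setting applies
#' MCAR deletion and multiple imputation before fitting. Both the best- and
#' tolerance-penalty models are built, their apparent MSE, external MSE (on a
#' fresh independent complete data set of size `external_n`), external
#' optimism (`apparent - external`) and calibration slope recorded, together
#' with per-covariate selection counts. Internal validation is run when
#' `n_boot_validate > 0`: the plain Harrell bootstrap in the NM setting, and
#' each requested approach of [bootstrap_optimism()] in the WM setting.
#'
#' @param config a [sim_config()].
#' @param setting `"NM"` (complete data) or `"WM"` (MCAR + imputation).
#' @param approaches integer subset of 1:4 to validate with (WM only).
#' @param seed master seed for the replicate; spawns independent substreams
#'   for data, missingness, imputation, fitting, the external draw and
#'   validation.
#' @param n_lambda,n_boot_tune,tol_frac model-building settings.
#' @param n_boot_validate bootstrap count for internal validation; 0 skips
#'   validation (fit-only replicate).
#' @param m,n_cycles,pmm_donors imputation settings (WM).
#' @param m_boot within-bootstrap imputation count for approach 4; defaults
#'   to `m`, and may be reduced for desk-scale runs (fewer re-imputations
#'   per bootstrap, at the cost of extra upward bias in its optimism).
#' @param external_n size of the independent evaluation draw; defaults to
#'   the training size.
#' @return data frame with one row per model mode (`best`, `tolerance`).
#' @export
run_replicate <- function(config, setting = c("NM", "WM"),
                          approaches = integer(0), seed = NULL,
                          n_lambda = 40L, n_boot_tune = 100L,
                          n_boot_validate = 100L, m = 10L, n_cycles = 5L,
                          pmm_donors = 5L, tol_frac = 0.03,
                          external_n = NULL, m_boot = NULL) {
  setting <- match.arg(setting)
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  ss <- derive_seeds(seed, 6L)  # data, mcar, impute, fit, external, validate
  train <- simulate_complete(config, seed = ss[1])
  ext_cfg <- config
  if (!is.null(external_n)) ext_cfg$n_obs <- as.integer(external_n)
  external <- simulate_complete(ext_cfg, seed = ss[5])

  if (setting == "NM") {
    sets <- list(train)
    imp <- NULL
  } else {
    incomplete <- apply_mcar(train, config$miss_probs, seed = ss[2])
    imp <- impute_mi(incomplete, m = m, n_cycles = n_cycles,
                     pmm_donors = pmm_donors, seed = ss[3])
    sets <- imp$sets
  }
  fits <- fit_modes(sets, n_lambda = n_lambda, n_boot = n_boot_tune,
                    seed = ss[4], tol_frac = tol_frac)

  vrep <- list()
  if (n_boot_validate > 0) {
    if (setting == "NM") {
      vrep$internal <- harrell_validate(
        train, B = n_boot_validate, mode = c("best", "tolerance"),
        n_lambda = n_lambda, n_boot_tune = n_boot_tune, seed = ss[6],
        tol_frac = tol_frac)
    } else {
      va_seeds <- derive_seeds(ss[6], 4L)
      for (a in approaches) {
        vrep[[paste0("appr", a)]] <- bootstrap_optimism(
          imp, approach = a, B = n_boot_validate,
          mode = c("best", "tolerance"), n_lambda = n_lambda,
          n_boot_tune = n_boot_tune, seed = va_seeds[a],
          raw = if (a == 4) incomplete else NULL,
          m = if (is.null(m_boot)) m else m_boot,
          n_cycles = n_cycles, pmm_donors = pmm_donors,
          tol_frac = tol_frac)
      }
    }
  }

  rows <- lapply(c("best", "tolerance"), function(md) {
    mdl <- fits[[md]]
    apparent <- apparent_performance(mdl, sets)
    ext_mse <- model_mse(mdl, external)
    row <- data.frame(
      setting = setting, mode = md, seed = seed, n = config$n_obs, m = if (setting == "WM") m else 1L,
      mse_apparent = apparent, mse_external = ext_mse,
      optimism_external = apparent - ext_mse,
      lp_slope = lp_slope_on(mdl, sets),
      optimism_internal = NA_real_, shrinkage_internal = NA_real_)
    for (a in 1:4) {
      row[[paste0("optimism_appr", a)]] <- NA_real_
      row[[paste0("s_appr", a)]] <- NA_real_
    }
    for (nm in names(vrep)) {
      rep_md <- vrep[[nm]][[md]]
      if (nm == "internal") {
        row$optimism_internal <- rep_md$mean_optimism
        row$shrinkage_internal <- rep_md$shrinkage_s
      } else {
        row[[paste0("optimism_", nm)]] <- rep_md$mean_optimism
        row[[paste0("s_", nm)]] <- rep_md$shrinkage_s
      }
    }
    sel <- mdl$selection_counts
    names(sel) <- paste0("sel_", names(sel))
    cbind(row, as.data.frame(as.list(sel)))
  })
  do.call(rbind, rows)
}

#' Run a batch of simulation replicates
#'
#' @inheritParams run_replicate
#' @param n_reps number of replicates.
#' @param seed master seed; each replicate receives an independent child
#'   seed, so results are invariant to execution order.
#' @return data frame of stacked [run_replicate()] records with a
#'   `replicate` id column.
#' @export
run_simstudy <- function(config, setting = c("NM", "WM"), n_reps,
                         approaches = integer(0), seed = NULL, ...) {
  setting <- match.arg(setting)
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  rep_seeds <- derive_seeds(seed, n_reps)
  recs <- lapply(seq_len(n_reps), function(r) {
    out <- run_replicate(config, setting = setting,
                         approaches = approaches, seed = rep_seeds[r], ...)
    out$replicate <- r
    out
  })
  do.call(rbind, recs)
}

#' Covariate selection frequencies and correct-model rates
#'
#' A covariate counts as selected in a replicate when its selection count
#' reaches `ceiling(wm_rule * m)` of the `m` imputed sets (for NM records,
#' `m = 1`, so this reduces to "nonzero coefficient"). The correct-model rate
#' is the percentage of replicates in which all truly relevant covariates are
#' selected simultaneously; the one-off rate counts replicates missing
#' exactly one relevant covariate.
#'
#' @param records data frame from [run_simstudy()].
#' @param wm_rule minimum fraction of imputed sets a covariate must be
#'   retained in (default 0.5).
#' @param relevant indices of the truly nonzero covariates (default
#'   x6-x10 and x16-x20 of the reference design).
#' @return list with `frequencies` (percent selected per covariate, by
#'   setting and mode) and `model_rates` (correct-model and one-off percent).
#' @export
selection_frequencies <- function(records, wm_rule = 0.5,
                                  relevant = c(6:10, 16:20)) {
  stopifnot(nrow(records) >= 1)
  sel_cols <- grep("^sel_", names(records), value = TRUE)
  p <- length(sel_cols)
  rel_cols <- paste0("sel_x", relevant)
  groups <- split(records, interaction(records$setting, records$mode,
                                       drop = TRUE))
  freq <- do.call(rbind, lapply(groups, function(g) {
    need <- pmax(1L, ceiling(wm_rule * g$m))
    selected <- sweep(as.matrix(g[, sel_cols]), 1L, need, `>=`)
    data.frame(setting = g$setting[1], mode = g$mode[1],
               covariate = sub("^sel_", "", sel_cols),
               frequency = 100 * colMeans(selected), row.names = NULL)
  }))
  rates <- do.call(rbind, lapply(groups, function(g) {
    need <- pmax(1L, ceiling(wm_rule * g$m))
    sel_rel <- sweep(as.matrix(g[, rel_cols]), 1L, need, `>=`)
    n_hit <- rowSums(sel_rel)
    data.frame(setting = g$setting[1], mode = g$mode[1],
               correct_model = 100 * mean(n_hit == length(relevant)),
               one_off = 100 * mean(n_hit == length(relevant) - 1L),
               row.names = NULL)
  }))
  list(frequencies = freq, model_rates = rates)
}

#' Summarize simulation records
#'
#' Mean and empirical 2.5th/97.5th percentiles (linear interpolation between
#' order statistics) of every numeric quantity, by setting and model mode.
#'
#' @param records data frame from [run_simstudy()].
#' @param quantities character vector of columns to summarize; defaults to
#'   the performance/optimism/slope columns present.
#' @return long data frame: setting, mode, quantity, mean, p2.5, p97.5.
#' @export
summarize_records <- function(records, quantities = NULL) {
  stopifnot(nrow(records) >= 1)
  if (is.null(quantities)) {
    cand <- c("mse_apparent", "mse_external", "optimism_external",
              "lp_slope", "optimism_internal", "shrinkage_internal",
              paste0("optimism_appr", 1:4), paste0("s_appr", 1:4))
    quantities <- intersect(cand, names(records))
  }
  groups <- split(records, interaction(records$setting, records$mode,
                                       drop = TRUE))
  out <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(quantities, function(q) {
      v <- g[[q]]
      v <- v[is.finite(v)]
      if (!length(v)) return(NULL)
      data.frame(setting = g$setting[1], mode = g$mode[1], quantity = q,
                 mean = mean(v),
                 p2.5 = unname(stats::quantile(v, 0.025, type = 7)),
                 p97.5 = unname(stats::quantile(v, 0.975, type = 7)),
                 n_reps = length(v), row.names = NULL)
    }))
  }))
  rownames(out) <- NULL
  out
}
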