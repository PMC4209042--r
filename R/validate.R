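# Internal validation of (pooled) lasso models by Harrell's optimism
# bootstrap, with four schemes for handling multiply imputed data:
#   1 - one shared row resample applied to every imputed set,
#   2 - an independent row resample per imputed set,
#   3 - the plain no-missing-data procedure on a single imputed set,
#   4 - resample the incomplete data, then re-impute inside the bootstrap.
# Every model-building step (grid construction, penalty tuning, per-set
# fitting, pooling) is redone inside each bootstrap sample.

#' Bootstrap estimation of optimism and shrinkage under multiple imputation
#'
#' Runs `B` bootstrap iterations. In each, a resample is drawn according to
#' the chosen approach, the whole model-building pipeline is replayed on the
#' resample, and the resulting model is scored on its own bootstrap data
#' (`apparent*`, averaged over sets) and on the original data (`test*`);
#' `optimism* = apparent* - test*`. The report carries the mean optimism, the
#' optimism-corrected performance (overall apparent MSE minus mean optimism)
#' and the uniform shrinkage factor `s` (mean of the per-bootstrap
#' calibration slopes of the original outcome on the bootstrap model's linear
#' predictor).
#'
#' @param imputed an `mi_imputed` object (approaches 1-3 resample its
#'   completed sets; approach 4 uses it only for the original-sample
#'   apparent/test performance).
#' @param approach integer 1-4 (see above).
#' @param B number of bootstrap iterations (default 100).
#' @param mode `"best"`, `"tolerance"`, or both (then a named list of
#'   reports is returned; the expensive rebuilds are shared).
#' @param n_lambda,n_boot_tune,tol_frac model-building settings replayed in
#'   every bootstrap (defaults 40, 100, 0.03).
#' @param seed integer seed, or `NULL`.
#' @param raw the incomplete `mi_dataset` (approach 4 only).
#' @param m within-bootstrap imputation count for approach 4; defaults to
#'   the outer number of imputations.
#' @param set_index which imputed set approach 3 uses (default 1).
#' @param n_cycles,pmm_donors imputation settings replayed by approach 4.
#' @param builder optional replacement model builder
#'   `function(list_of_sets) -> model`; intended for diagnostics and tests
#'   (e.g. a data-independent builder must give zero optimism).
#' @return a `validation_report`, or a named list of them when both modes
#'   are requested.
#' @export
bootstrap_optimism <- function(imputed, approach, B = 100L,
                               mode = c("best", "tolerance"),
                               n_lambda = 40L, n_boot_tune = 100L,
                               seed = NULL, raw = NULL, m = NULL,
                               set_index = 1L, n_cycles = 5L,
                               pmm_donors = 5L, tol_frac = 0.03,
                               builder = NULL) {
  stopifnot(B >= 1, approach %in% 1:4)
  modes <- match.arg(mode, several.ok = TRUE)
  maybe_seed(seed)
  all_sets <- if (inherits(imputed, "mi_imputed")) imputed$sets else imputed
  orig_sets <- if (approach == 3) all_sets[set_index] else all_sets
  if (approach == 4) {
    if (is.null(raw)) stop("approach 4 needs the incomplete data set (raw=)")
    if (is.null(m)) m <- length(all_sets)
  }
  build <- function(bsets) {
    if (is.null(builder)) {
      fit_modes(bsets, n_lambda = n_lambda, n_boot = n_boot_tune,
                tol_frac = tol_frac)
    } else {
      mdl <- builder(bsets)
      stats::setNames(rep(list(mdl), length(modes)), modes)
    }
  }
  orig_fit <- build(orig_sets)
  n <- nrow(orig_sets[[1]]$values)
  boot_seeds <- sample.int(2147483646L, B)
  n_impute_warnings <- 0L
  rec <- lapply(modes, function(x)
    data.frame(apparent_star = numeric(B), test_star = numeric(B),
               optimism_star = numeric(B), lp_slope = numeric(B)))
  names(rec) <- modes
  for (b in seq_len(B)) {
    set.seed(boot_seeds[b])
    bsets <- switch(as.character(approach),
      "1" = {
        idx <- sample.int(n, n, replace = TRUE)
        lapply(orig_sets, subset_rows, idx = idx)
      },
      "2" = lapply(orig_sets, function(s)
        subset_rows(s, sample.int(n, n, replace = TRUE))),
      "3" = list(subset_rows(orig_sets[[1]],
                             sample.int(n, n, replace = TRUE))),
      "4" = {
        idx <- sample.int(n, n, replace = TRUE)
        ci <- count_impute_warnings(
          impute_mi(subset_rows(raw, idx), m = m, n_cycles = n_cycles,
                    pmm_donors = pmm_donors))
        n_impute_warnings <- n_impute_warnings + ci$n_warnings
        ci$value$sets
      })
    fits <- build(bsets)
    for (md in modes) {
      mdl <- fits[[md]]
      app <- apparent_performance(mdl, bsets)
      tst <- apparent_performance(mdl, orig_sets)
      rec[[md]][b, ] <- c(app, tst, app - tst, lp_slope_on(mdl, orig_sets))
    }
  }
  reports <- lapply(modes, function(md) {
    r <- rec[[md]]
    apparent <- apparent_performance(orig_fit[[md]], orig_sets)
    structure(
      list(approach = approach, mode = md, n_boot = B, boot = r,
           apparent = apparent,
           mean_optimism = mean(r$optimism_star),
           corrected_performance = apparent - mean(r$optimism_star),
           shrinkage_s = mean_finite_slope(r$lp_slope),
           model = orig_fit[[md]],
           settings = list(n_lambda = n_lambda, n_boot_tune = n_boot_tune,
                           tol_frac = tol_frac, m = m,
                           set_index = set_index, seed = seed,
                           n_impute_warnings = n_impute_warnings)),
      class = "validation_report")
  })
  names(reports) <- modes
  if (length(reports) == 1L) reports[[1L]] else reports
}

# calibration slope of the original outcome on the model's linear predictor,
# averaged over the original completed sets
lp_slope_on <- function(model, sets) {
  mean(vapply(sets, function(s) {
    lp <- stats::predict(model, s)
    if (stats::sd(lp) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(outcome_of(s) ~ lp))[2])
  }, numeric(1)))
}

mean_finite_slope <- function(slopes) {
  bad <- !is.finite(slopes)
  if (any(bad)) {
    warning(sum(bad), " non-finite bootstrap calibration slope(s) excluded")
  }
  mean(slopes[!bad])
}

#' Harrell optimism bootstrap for a single complete data set
#'
#' The classical procedure with no multiple imputation: resample rows, replay
#' tuning and fitting, and contrast bootstrap (`apparent*`) with original
#' (`test*`) performance. Identical to [bootstrap_optimism()] approach 3 run
#' on that data set.
#'
#' @inheritParams bootstrap_optimism
#' @param data a complete `mi_dataset`.
#' @return a `validation_report` (or named list for both modes).
#' @export
harrell_validate <- function(data, B = 100L, mode = c("best", "tolerance"),
                             n_lambda = 40L, n_boot_tune = 100L, seed = NULL,
                             tol_frac = 0.03, builder = NULL) {
  bootstrap_optimism(list(data), approach = 3, B = B, mode = mode,
                     n_lambda = n_lambda, n_boot_tune = n_boot_tune,
                     seed = seed, tol_frac = tol_frac, builder = builder)
}

#' Uniform shrinkage factor from a validation report
#'
#' The mean of the per-bootstrap calibration slopes; non-finite slopes are
#' excluded with a warning.
#'
#' @param report a `validation_report` (or a numeric vector of slopes).
#' @return scalar shrinkage factor `s`.
#' @export
shrinkage_factor <- function(report) {
  slopes <- if (inherits(report, "validation_report")) report$boot$lp_slope
            else report
  mean_finite_slope(slopes)
}

#' Optimism-corrected performance
#'
#' `apparent - mean(optimisms)`; with MSE the optimism values are typically
#' negative, so the correction increases the MSE estimate.
#'
#' @param apparent apparent performance of the final model.
#' @param optimisms vector of per-bootstrap optimism values.
#' @return scalar corrected performance.
#' @export
corrected_performance <- function(apparent, optimisms) {
  stopifnot(length(optimisms) >= 1)
  apparent - mean(optimisms)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "validation_report (approach %d, %s model, B = %d)\n  apparent MSE %.4f, mean optimism %.4f, corrected MSE %.4f, s = %.4f\n",
    x$approach, x$mode, x$n_boot, x$apparent, x$mean_optimism,
    x$corrected_performance, x$shrinkage_s))
  invisible(x)
}
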