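# Penalized linear regression core: single-penalty fits, penalty-grid
# construction, bootstrap-corrected penalty tuning (best and 3%-tolerance
# choices), per-imputation fitting and cross-imputation pooling.
#
# The solver is glmnet; its objective 1/(2n) * RSS + lambda * ||b||_1 on
# internally standardized covariates (unpenalized intercept, coefficients
# reported on the original scale) is the convention adopted throughout, so
# penalty magnitudes are directly comparable across data sets.

as_xy <- function(data, y = NULL) {
  if (inherits(data, "mi_dataset")) {
    if (any(!data$mask)) stop("complete (no-missing) data required")
    list(X = covariates(data), y = outcome_of(data))
  } else {
    if (is.null(y)) stop("y required when data is a plain matrix")
    list(X = as.matrix(data), y = y)
  }
}

# standardized-scale lambda_max: the smallest penalty shrinking every slope
# to zero, max_j |x_j^T (y - ybar)| / n with x_j scaled to unit 1/n-variance
lambda_max <- function(X, y) {
  n <- nrow(X)
  ctr <- colMeans(X)
  sx <- sqrt(colMeans(X^2) - ctr^2)
  ok <- sx > 0
  if (!any(ok)) stop("all covariates are constant")
  Xs <- scale(X[, ok, drop = FALSE], center = ctr[ok], scale = sx[ok])
  max(abs(crossprod(Xs, y - mean(y)))) / n
}

# glmnet path fit returning intercepts and original-scale coefficients at
# exactly the requested (descending) lambda sequence
glmnet_path <- function(X, y, lambda, thresh = 1e-7) {
  lam <- lambda
  single <- length(lam) == 1L
  if (single) lam <- c(lam * 100, lam * 10, lam)
  f <- glmnet::glmnet(X, y, family = "gaussian", lambda = lam,
                      standardize = TRUE, type.gaussian = "covariance",
                      thresh = thresh)
  B <- as.matrix(f$beta)
  a0 <- f$a0
  if (single) {
    B <- B[, ncol(B), drop = FALSE]
    a0 <- a0[length(a0)]
  }
  list(a0 = unname(a0), beta = B)
}

new_lasso_model <- function(intercept, coefficients, lambda) {
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients, lambda = lambda),
            class = "lasso_model")
}

#' Fit a lasso linear model at a fixed penalty
#'
#' Minimizes `1/(2n) * sum((y - b0 - X b)^2) + lambda * ||b||_1` with
#' covariates standardized internally to unit variance (the intercept is
#' never penalized); coefficients are returned on the original scale.
#' `lambda = 0` gives the ordinary least-squares fit; any
#' `lambda >= lambda_max` gives exactly zero slopes with intercept `mean(y)`.
#'
#' @param X covariate matrix (no missing values) or a complete `mi_dataset`.
#' @param y outcome vector (ignored when `X` is an `mi_dataset`).
#' @param lambda non-negative penalty.
#' @param thresh solver convergence threshold.
#' @return An object of class `lasso_model` with elements `intercept`,
#'   `coefficients` (named, original scale) and `lambda`.
#' @export
fit_lasso <- function(X, y = NULL, lambda, thresh = 1e-10) {
  d <- as_xy(X, y)
  X <- d$X; y <- d$y
  stopifnot(lambda >= 0, nrow(X) >= 2)
  cf <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (stats::sd(y) == 0) {                      # constant outcome
    return(new_lasso_model(mean(y), cf, lambda))
  }
  if (lambda == 0) {                            # unpenalized limit: OLS
    fit <- stats::lm.fit(cbind(1, X), y)
    b <- fit$coefficients
    b[is.na(b)] <- 0
    cf[] <- b[-1]
    return(new_lasso_model(b[1], cf, lambda))
  }
  lmax <- lambda_max(X, y)
  if (lambda >= lmax) {                         # full-shrinkage limit
    return(new_lasso_model(mean(y), cf, lambda))
  }
  lam_seq <- exp(seq(log(lmax), log(lambda), length.out = 15L))
  lam_seq[length(lam_seq)] <- lambda
  p <- glmnet_path(X, y, lam_seq, thresh = thresh)
  cf[] <- p$beta[, ncol(p$beta)]
  new_lasso_model(p$a0[length(p$a0)], cf, lambda)
}

#' @export
predict.lasso_model <- function(object, newdata, ...) {
  X <- covariates(newdata)
  drop(object$intercept + X %*% object$coefficients)
}

#' @export
print.lasso_model <- function(x, ...) {
  cat(sprintf("lasso_model: lambda = %.6g, %d of %d nonzero slopes\n",
              x$lambda, sum(x$coefficients != 0), length(x$coefficients)))
  invisible(x)
}

#' Build a descending penalty grid
#'
#' The grid starts at the data-driven `lambda_max` (the smallest penalty that
#' shrinks every slope to zero) and is log-spaced down three decades to
#' `lambda_max / 1000`.
#'
#' @param X covariate matrix or complete `mi_dataset`.
#' @param y outcome vector (ignored for `mi_dataset` input).
#' @param n_lambda grid length (default 40).
#' @param decades number of log10 decades spanned (default 3).
#' @return strictly decreasing numeric vector of length `n_lambda`.
#' @export
make_penalty_grid <- function(X, y = NULL, n_lambda = 40L, decades = 3) {
  d <- as_xy(X, y)
  lmax <- lambda_max(d$X, d$y)
  exp(seq(log(lmax), log(lmax * 10^(-decades)), length.out = n_lambda))
}

#' Tune the lasso penalty by bootstrap-corrected MSE
#'
#' For each penalty in the grid, models are fit on `n_boot` bootstrap
#' resamples (with replacement, original size) and scored by MSE on the
#' original data; the same resamples are reused across the whole grid so the
#' MSE profile is not blurred by resampling noise. The "best" penalty
#' minimizes the mean bootstrap MSE (ties broken toward the stronger
#' penalty); the "tolerance" penalty is the strongest penalty whose mean MSE
#' stays within `tol_frac` (3% by default) of that minimum.
#'
#' @param data complete `mi_dataset` or covariate matrix.
#' @param grid descending penalty vector; default [make_penalty_grid()].
#' @param n_boot number of bootstrap resamples (default 100).
#' @param seed integer seed, or `NULL` to continue the current stream.
#' @param y outcome vector for matrix input.
#' @param tol_frac tolerance fraction for the parsimonious choice.
#' @param n_lambda grid length when `grid` is not supplied.
#' @param thresh solver threshold used inside tuning.
#' @return An object of class `tuning_result`: `grid`, `mean_boot_mse`,
#'   `best_lambda`, `tolerance_lambda`, their indices, and `n_boot`.
#' @export
tune_penalty <- function(data, grid = NULL, n_boot = 100L, seed = NULL,
                         y = NULL, tol_frac = 0.03, n_lambda = 40L,
                         thresh = 1e-7) {
  stopifnot(n_boot >= 1)
  d <- as_xy(data, y)
  maybe_seed(seed)
  if (is.null(grid)) grid <- make_penalty_grid(d$X, d$y, n_lambda = n_lambda)
  if (is.unsorted(rev(grid))) stop("penalty grid must be descending")
  X <- d$X; yv <- d$y; n <- nrow(X)
  L <- length(grid)
  acc <- numeric(L)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- yv[idx]
    if (stats::sd(yb) == 0) {
      acc <- acc + mean((yv - mean(yb))^2)
      next
    }
    p <- glmnet_path(X[idx, , drop = FALSE], yb, grid, thresh = thresh)
    pred <- X %*% p$beta + rep(p$a0, each = n)
    acc <- acc + colMeans((yv - pred)^2)
  }
  mean_mse <- acc / n_boot
  best <- which.min(mean_mse)                 # first index = strongest lambda
  tol <- which(mean_mse <= (1 + tol_frac) * mean_mse[best])[1L]
  structure(
    list(grid = grid, mean_boot_mse = mean_mse,
         best_lambda = grid[best], tolerance_lambda = grid[tol],
         best_index = best, tolerance_index = tol,
         n_boot = n_boot, tol_frac = tol_frac),
    class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf(
    "tuning_result: %d penalties, %d bootstraps\n  best %.5g (MSE %.4f), tolerance %.5g (MSE %.4f)\n",
    length(x$grid), x$n_boot, x$best_lambda,
    x$mean_boot_mse[x$best_index], x$tolerance_lambda,
    x$mean_boot_mse[x$tolerance_index]))
  invisible(x)
}

#' Average component models into a pooled model
#'
#' Pooled intercept and coefficients are the arithmetic means over the
#' component models (zeros included), mirroring how a covariate picked in
#' only one of M imputations ends up with its value divided by M. Selection
#' counts record in how many components each coefficient is nonzero.
#'
#' @param models list of `lasso_model` objects sharing a coefficient schema.
#' @param mode optional label (`"best"`/`"tolerance"`).
#' @return An object of class `pooled_lasso`.
#' @export
pool_models <- function(models, mode = NULL) {
  stopifnot(length(models) >= 1)
  cf <- sapply(models, function(m) m$coefficients)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
  structure(
    list(intercept = mean(vapply(models, `[[`, numeric(1), "intercept")),
         coefficients = rowMeans(cf),
         selection_counts = rowSums(cf != 0),
         lambdas = vapply(models, `[[`, numeric(1), "lambda"),
         models = models, mode = mode, m = length(models)),
    class = "pooled_lasso")
}

#' @export
predict.pooled_lasso <- function(object, newdata, ...) {
  X <- covariates(newdata)
  drop(object$intercept + X %*% object$coefficients)
}

#' @export
print.pooled_lasso <- function(x, ...) {
  cat(sprintf(
    "pooled_lasso (%s): %d imputations, %d covariates ever selected\n",
    if (is.null(x$mode)) "?" else x$mode, x$m, sum(x$selection_counts > 0)))
  invisible(x)
}

# Tune and fit per imputed set for both penalty choices in one pass.
# One shared tuning seed is used for every set, so the bootstrap row indices
# agree across imputations (and M identical sets yield M identical models).
fit_modes <- function(sets, n_lambda = 40L, n_boot = 100L, seed = NULL,
                      tol_frac = 0.03, thresh = 1e-7) {
  if (inherits(sets, "mi_imputed")) sets <- sets$sets
  tune_seed <- if (is.null(seed)) sample.int(2147483646L, 1L) else seed
  best <- tol <- vector("list", length(sets))
  tunings <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    d <- as_xy(sets[[i]])
    grid <- make_penalty_grid(d$X, d$y, n_lambda = n_lambda)
    tr <- tune_penalty(d$X, grid = grid, n_boot = n_boot, seed = tune_seed,
                       y = d$y, tol_frac = tol_frac, thresh = thresh)
    p <- glmnet_path(d$X, d$y, grid, thresh = 1e-9)
    cf_b <- stats::setNames(p$beta[, tr$best_index], colnames(d$X))
    cf_t <- stats::setNames(p$beta[, tr$tolerance_index], colnames(d$X))
    best[[i]] <- new_lasso_model(p$a0[tr$best_index], cf_b, tr$best_lambda)
    tol[[i]] <- new_lasso_model(p$a0[tr$tolerance_index], cf_t,
                                tr$tolerance_lambda)
    tunings[[i]] <- tr
  }
  list(best = pool_models(best, "best"),
       tolerance = pool_models(tol, "tolerance"),
       tunings = tunings)
}

#' Fit a pooled lasso model across multiply imputed data sets
#'
#' Penalty tuning and model fitting run independently in every imputed set
#' (each set gets its own grid and chosen penalty); the per-set coefficient
#' vectors are then averaged into one final model via [pool_models()].
#'
#' @param imputed an `mi_imputed` object (or plain list of complete
#'   `mi_dataset`s).
#' @param mode `"best"` (penalty minimizing mean bootstrap MSE) or
#'   `"tolerance"` (strongest penalty within 3% of the optimum).
#' @param n_lambda penalty-grid length per set (default 40).
#' @param n_boot tuning bootstraps per set (default 100).
#' @param seed integer seed, or `NULL`.
#' @param tol_frac tolerance fraction (default 0.03).
#' @return a `pooled_lasso` model.
#' @export
fit_pooled <- function(imputed, mode = c("best", "tolerance"),
                       n_lambda = 40L, n_boot = 100L, seed = NULL,
                       tol_frac = 0.03) {
  mode <- match.arg(mode)
  fit_modes(imputed, n_lambda = n_lambda, n_boot = n_boot, seed = seed,
            tol_frac = tol_frac)[[mode]]
}
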