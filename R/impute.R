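# Chained-equations multiple imputation with the conventions used for the
# COPD prognostic models: predictive mean matching (PMM) for continuous
# variables, logistic-model draws for binary variables, and every other
# column -- including the outcome -- as predictor in each imputation model.

#' Predictive-mean-matching draw
#'
#' For every missing case, locates the `k` observed cases whose predicted
#' values are closest to the missing case's prediction and copies the observed
#' outcome of one donor picked uniformly at random (type-1 matching: observed
#' predictions come from the fitted coefficients, missing predictions from a
#' perturbed coefficient draw).
#'
#' @param observed_outcome observed values of the variable being imputed.
#' @param observed_predictions model predictions for the observed cases.
#' @param missing_predictions model predictions for the missing cases.
#' @param k donor-pool size; if fewer observed cases exist, all are used.
#' @return numeric vector, one imputed value per missing case, each a member
#'   of `observed_outcome`.
#' @export
pmm_draw <- function(observed_outcome, observed_predictions,
                     missing_predictions, k = 5L) {
  stopifnot(k >= 1, length(observed_outcome) == length(observed_predictions))
  k <- min(k, length(observed_outcome))
  vapply(missing_predictions, function(ph) {
    donors <- order(abs(observed_predictions - ph))[seq_len(k)]
    observed_outcome[donors[sample.int(k, 1L)]]
  }, numeric(1))
}

#' Logistic-regression imputation draw for a binary variable
#'
#' Fits a logistic model on the observed cases, perturbs the coefficients by
#' one draw from their asymptotic normal distribution, and imputes each
#' missing case as Bernoulli with its perturbed fitted probability. Perfect
#' separation (or other instability) triggers a ridge-stabilized refit with a
#' warning; a single observed class falls back to constant fill.
#'
#' @param observed_binary 0/1 vector of observed values.
#' @param predictors_observed design matrix (no intercept column) for the
#'   observed cases.
#' @param predictors_missing design matrix for the missing cases.
#' @return 0/1 vector, one value per missing case.
#' @export
logistic_draw <- function(observed_binary, predictors_observed,
                          predictors_missing) {
  n_mis <- nrow(predictors_missing)
  lev <- unique(observed_binary)
  if (length(lev) < 2L) {
    impute_warn("binary variable with a single observed level; constant fill")
    return(rep(lev, n_mis))
  }
  Xo <- cbind(1, as.matrix(predictors_observed))
  Xm <- cbind(1, as.matrix(predictors_missing))
  keep <- qr_keep(Xo)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(Xo[, keep, drop = FALSE], observed_binary,
                                    family = stats::binomial())),
    error = function(e) NULL)
  unstable <- is.null(fit) || !fit$converged ||
    any(abs(fit$coefficients) > 25, na.rm = TRUE)
  if (unstable) {
    impute_warn("unstable logistic fit (possible separation); ridge-stabilized")
    fit <- ridge_logistic(Xo[, keep, drop = FALSE], observed_binary)
    beta <- fit$coef
    V <- fit$vcov
  } else {
    beta <- fit$coefficients
    w <- fit$weights
    A <- crossprod(Xo[, keep, drop = FALSE] * sqrt(w))
    V <- tryCatch(chol2inv(chol(A)), error = function(e) {
      chol2inv(chol(A + diag(1e-6, ncol(A))))
    })
  }
  beta_star <- beta + drop(t(chol(sym(V))) %*% stats::rnorm(length(beta)))
  p <- stats::plogis(drop(Xm[, keep, drop = FALSE] %*% beta_star))
  as.numeric(stats::runif(n_mis) < p)
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of an incomplete data set. Each imputation
#' runs an independent chained-equations sweep: incomplete columns are visited
#' in order of increasing missingness for `n_cycles` cycles; continuous
#' columns are filled by [pmm_draw()] after a Bayesian linear-model
#' coefficient draw, binary columns by [logistic_draw()]. All other columns,
#' the outcome included, act as predictors.
#'
#' @param data an `mi_dataset`.
#' @param m number of imputations (default 10).
#' @param n_cycles chained-equations cycles per imputation (default 5).
#' @param pmm_donors PMM donor-pool size (default 5).
#' @param seed integer seed, or `NULL`.
#' @param drop_imputed_outcome_rows if `TRUE`, rows whose outcome was itself
#'   imputed are removed from every completed set (imputed outcomes add noise
#'   to the conditional model of outcome given covariates); inert when the
#'   outcome is complete.
#' @return An object of class `mi_imputed`: list with `sets` (list of `m`
#'   complete `mi_dataset`s), `m`, `source_mask`, `var_types`.
#' @export
impute_mi <- function(data, m = 10L, n_cycles = 5L, pmm_donors = 5L,
                      seed = NULL, drop_imputed_outcome_rows = FALSE) {
  stopifnot(m >= 1, n_cycles >= 1)
  maybe_seed(seed)
  vals <- data$values
  mask <- data$mask
  none_observed <- colSums(mask) == 0L
  if (any(none_observed)) {
    stop("column(s) with no observed values: ",
         paste(colnames(vals)[none_observed], collapse = ", "))
  }
  mis_frac <- colMeans(!mask)
  visit <- order(mis_frac[mis_frac > 0])
  visit_cols <- which(mis_frac > 0)[visit]
  set_seeds <- sample.int(2147483646L, m)
  sets <- vector("list", m)
  counted <- count_impute_warnings(for (i in seq_len(m)) {
    set.seed(set_seeds[i])
    filled <- vals
    for (j in visit_cols) {  # initial fill: random draws from observed values
      nm <- sum(!mask[, j])
      filled[!mask[, j], j] <- sample(vals[mask[, j], j], nm, replace = TRUE)
    }
    for (cycle in seq_len(n_cycles)) {
      for (j in visit_cols) {
        obs <- mask[, j]
        Xp <- filled[, -j, drop = FALSE]
        if (data$var_types[j] == "binary") {
          filled[!obs, j] <- logistic_draw(
            filled[obs, j], Xp[obs, , drop = FALSE], Xp[!obs, , drop = FALSE])
        } else {
          filled[!obs, j] <- impute_continuous(
            filled[obs, j], Xp[obs, , drop = FALSE], Xp[!obs, , drop = FALSE],
            k = pmm_donors)
        }
      }
    }
    sets[[i]] <- mi_dataset(filled, var_types = data$var_types,
                            outcome = data$outcome)
  })
  if (counted$n_warnings > 0L) {
    impute_warn(sprintf(
      "%d imputation-model instabilit%s handled (ridge fallback or constant fill)",
      counted$n_warnings, if (counted$n_warnings == 1L) "y" else "ies"))
  }
  ycol <- which(colnames(vals) == data$outcome)
  imputed_y <- which(!mask[, ycol])
  if (drop_imputed_outcome_rows && length(imputed_y)) {
    keep <- setdiff(seq_len(nrow(vals)), imputed_y)
    sets <- lapply(sets, subset_rows, idx = keep)
  }
  structure(
    list(sets = sets, m = m, source_mask = mask, var_types = data$var_types,
         outcome = data$outcome, imputed_outcome_rows = imputed_y),
    class = "mi_imputed")
}

#' @export
print.mi_imputed <- function(x, ...) {
  cat(sprintf("mi_imputed: %d completed sets of %d rows (%d cells imputed per set)\n",
              x$m, nrow(x$source_mask), sum(!x$source_mask)))
  invisible(x)
}

# one chained-equations update of a continuous column: Bayesian linear draw
# (normal-inverse-gamma) feeding type-1 PMM
impute_continuous <- function(yobs, Xobs, Xmis, k) {
  Xo <- cbind(1, Xobs)
  Xm <- cbind(1, Xmis)
  keep <- qr_keep(Xo)
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- Xm[, keep, drop = FALSE]
  qx <- qr(Xo)
  betahat <- qr.coef(qx, yobs)
  res <- yobs - drop(Xo %*% betahat)
  df <- max(length(yobs) - ncol(Xo), 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  XtXinv <- tryCatch(chol2inv(qr.R(qx)), error = function(e) {
    chol2inv(chol(crossprod(Xo) + diag(1e-8, ncol(Xo))))
  })
  beta_star <- betahat +
    drop(t(chol(sym(XtXinv))) %*% stats::rnorm(ncol(Xo))) * sqrt(sigma2)
  pmm_draw(yobs, drop(Xo %*% betahat), drop(Xm %*% beta_star), k = k)
}

# columns retained by a pivoted QR (rank-deficiency guard)
qr_keep <- function(X) {
  qx <- qr(X)
  sort(qx$pivot[seq_len(qx$rank)])
}

sym <- function(V) (V + t(V)) / 2 + diag(1e-12, nrow(V))

# classed warning so bulk callers (the validation bootstrap) can count and
# summarize imputation-model instabilities instead of emitting one warning
# per column update
impute_warn <- function(msg) {
  warning(warningCondition(msg, class = "lassomi_impute_warning"))
}

# run `expr`, muffling classed imputation warnings and returning their count
# alongside the result
count_impute_warnings <- function(expr) {
  n <- 0L
  value <- withCallingHandlers(expr, lassomi_impute_warning = function(w) {
    n <<- n + 1L
    invokeRestart("muffleWarning")
  })
  list(value = value, n_warnings = n)
}

# ridge-stabilized IRLS logistic fit, used when plain ML is unstable
ridge_logistic <- function(X, y, lambda = 1e-2, iter = 30L) {
  b <- rep(0, ncol(X))
  A <- diag(ncol(X))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    A <- crossprod(X * sqrt(w)) + diag(lambda, ncol(X))
    b_new <- drop(solve(A, crossprod(X, w * z)))
    if (max(abs(b_new - b)) < 1e-8) { b <- b_new; break }
    b <- b_new
  }
  list(coef = b, vcov = solve(A))
}
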