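# Independent oracles used across the suite.

# Objective value of the penalized least-squares problem in the package's
# convention: 1/(2n) RSS + lambda * sum_j sd_j |beta_j| (sd with 1/n), i.e.
# the L1 penalty acts on unit-variance standardized covariates.
lasso_objective <- function(X, y, intercept, beta, lambda) {
  n <- nrow(X)
  sx <- sqrt(colMeans(X^2) - colMeans(X)^2)
  mean((y - intercept - drop(X %*% beta))^2) / 2 + lambda * sum(sx * abs(beta))
}

# Proximal-gradient (FISTA) solver for the same problem: an independent
# first-order convex-programming route, no coordinate descent involved.
oracle_lasso_fista <- function(X, y, lambda, max_iter = 50000L, tol = 1e-13) {
  n <- nrow(X)
  ctr <- colMeans(X)
  sx <- sqrt(colMeans(X^2) - ctr^2)
  Xs <- scale(X, center = ctr, scale = sx)
  yc <- y - mean(y)
  L <- max(eigen(crossprod(Xs) / n, symmetric = TRUE,
                 only.values = TRUE)$values)
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  b <- z <- numeric(ncol(X))
  tk <- 1
  for (i in seq_len(max_iter)) {
    g <- drop(crossprod(Xs, Xs %*% z - yc)) / n
    b_new <- soft(z - g / L, lambda / L)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- b_new + ((tk - 1) / t_new) * (b_new - b)
    done <- max(abs(b_new - b)) < tol
    b <- b_new
    tk <- t_new
    if (done) break
  }
  beta <- b / sx
  list(intercept = mean(y) - sum(ctr * beta), coefficients = beta)
}

# Standalone Harrell optimism bootstrap on one complete data set, written as
# its own loop over the package's fitting primitives; mirrors the seeding
# protocol (one tuning seed per model build, one seed per bootstrap draw).
oracle_harrell <- function(data, B, n_boot_tune, n_lambda, seed,
                           tol_frac = 0.03) {
  set.seed(seed)
  X <- covariates(data)
  y <- outcome_of(data)
  n <- nrow(X)
  build <- function(Xb, yb) {
    ts <- sample.int(2147483646L, 1L)
    grid <- make_penalty_grid(Xb, yb, n_lambda = n_lambda)
    tr <- tune_penalty(Xb, grid = grid, n_boot = n_boot_tune, seed = ts,
                       y = yb, tol_frac = tol_frac)
    p <- lassomi:::glmnet_path(Xb, yb, grid, thresh = 1e-9)
    list(best = list(a0 = p$a0[tr$best_index],
                     beta = p$beta[, tr$best_index]),
         tolerance = list(a0 = p$a0[tr$tolerance_index],
                          beta = p$beta[, tr$tolerance_index]))
  }
  mse_of <- function(mdl, Xe, ye) mean((ye - mdl$a0 - Xe %*% mdl$beta)^2)
  build(X, y)  # original model build (consumes the same RNG as the package)
  boot_seeds <- sample.int(2147483646L, B)
  out <- lapply(c("best", "tolerance"), function(md) {
    data.frame(apparent_star = numeric(B), test_star = numeric(B),
               optimism_star = numeric(B), lp_slope = numeric(B))
  })
  names(out) <- c("best", "tolerance")
  for (b in seq_len(B)) {
    set.seed(boot_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    fits <- build(X[idx, , drop = FALSE], y[idx])
    for (md in names(out)) {
      mdl <- fits[[md]]
      app <- mse_of(mdl, X[idx, , drop = FALSE], y[idx])
      tst <- mse_of(mdl, X, y)
      lp <- drop(mdl$a0 + X %*% mdl$beta)
      slope <- unname(coef(lm(y ~ lp))[2])
      out[[md]][b, ] <- c(app, tst, app - tst, slope)
    }
  }
  out
}
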