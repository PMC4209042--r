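#' Simulation configuration for the COPD-style prognostic setting
#'
#' Defines the data-generating process used throughout the simulation study:
#' 20 standard-normal covariates with a sparse correlation structure, the
#' first ten dichotomized at fixed percentiles, a linear outcome with Gaussian
#' noise, and per-cell missing-completely-at-random (MCAR) deletion on a
#' subset of covariates.
#'
#' Defaults encode the reference design: correlations
#' R(1,5)=0.72, R(1,6)=-0.52, R(2,8)=0.74, R(4,12)=-0.82, R(6,16)=-0.34,
#' R(10,20)=-0.38, R(11,19)=0.37, R(19,20)=0.65; covariates 1,2,6,7 cut at the
#' 50th percentile, 3,4,8,9 at the 30th, 5,10 at the 20th; intercept 1.14;
#' slopes 0 for x1-x5 and x11-x15, (-0.839, 1.131, -1.540, 1.426, 0.854) for
#' x6-x10 and (0.457, -0.494, -0.738, 1.589, 0.845) for x16-x20; noise sd
#' 1.74; 20% MCAR on x2,x7,x12,x17 and 50% on x3,x8,x13,x18.
#'
#' @param n_obs number of rows to simulate.
#' @param corr_entries list of `c(j, k, r)` triples for the latent
#'   multivariate-normal correlation matrix.
#' @param dichotomize_percentiles named numeric vector, covariate index ->
#'   percentile in (0,100) at which that covariate is dichotomized.
#' @param beta0 intercept of the outcome model.
#' @param beta numeric vector of 20 slopes.
#' @param noise_sd standard deviation of the Gaussian outcome noise.
#' @param miss_probs named numeric vector, covariate index -> per-cell MCAR
#'   probability.
#' @param n_cov number of covariates (fixed at 20 in the reference design).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_obs = 250,
                       corr_entries = list(
                         c(1, 5, 0.72), c(1, 6, -0.52), c(2, 8, 0.74),
                         c(4, 12, -0.82), c(6, 16, -0.34), c(10, 20, -0.38),
                         c(11, 19, 0.37), c(19, 20, 0.65)),
                       dichotomize_percentiles = c(
                         "1" = 50, "2" = 50, "6" = 50, "7" = 50,
                         "3" = 30, "4" = 30, "8" = 30, "9" = 30,
                         "5" = 20, "10" = 20),
                       beta0 = 1.14,
                       beta = c(rep(0, 5), -0.839, 1.131, -1.540, 1.426,
                                0.854, rep(0, 5), 0.457, -0.494, -0.738,
                                1.589, 0.845),
                       noise_sd = 1.74,
                       miss_probs = c("2" = 0.2, "7" = 0.2, "12" = 0.2,
                                      "17" = 0.2, "3" = 0.5, "8" = 0.5,
                                      "13" = 0.5, "18" = 0.5),
                       n_cov = 20L) {
  stopifnot(n_obs >= 2, length(beta) == n_cov, noise_sd >= 0)
  if (any(miss_probs < 0 | miss_probs > 1)) {
    stop("miss_probs must lie in [0,1]")
  }
  if (any(as.integer(names(miss_probs)) > n_cov)) {
    stop("miss_probs may only address covariate columns, never the outcome")
  }
  cfg <- structure(
    list(n_obs = as.integer(n_obs), n_cov = as.integer(n_cov),
         corr_entries = corr_entries,
         dichotomize_percentiles = dichotomize_percentiles,
         beta0 = beta0, beta = beta, noise_sd = noise_sd,
         miss_probs = miss_probs),
    class = "sim_config")
  # fail fast on an invalid correlation structure
  build_correlation_matrix(corr_entries, n_cov)
  cfg
}

#' Build the latent correlation matrix from sparse entries
#'
#' Places each `(j, k, r)` triple symmetrically into an identity matrix and
#' verifies positive definiteness by eigendecomposition.
#'
#' @param corr_entries list of `c(j, k, r)` triples with `j != k`,
#'   `r` in (-1, 1).
#' @param n_cov matrix dimension.
#' @return `n_cov` x `n_cov` correlation matrix.
#' @export
build_correlation_matrix <- function(corr_entries, n_cov = 20L) {
  R <- diag(n_cov)
  for (e in corr_entries) {
    j <- as.integer(e[1]); k <- as.integer(e[2]); r <- e[3]
    if (j < 1 || k < 1 || j > n_cov || k > n_cov || j == k) {
      stop("correlation entry indices must be distinct and in 1..", n_cov)
    }
    if (abs(r) >= 1) stop("correlation values must lie strictly in (-1, 1)")
    R[j, k] <- r
    R[k, j] <- r
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf(
      "correlation matrix is not positive definite (smallest eigenvalue %.6g)",
      min(ev)))
  }
  R
}

#' Simulate a complete data set
#'
#' Draws the latent covariates from MVN(0, R), dichotomizes the configured
#' columns at the theoretical N(0,1) quantile of their percentile (indicator =
#' 1 when the latent value exceeds the cut, so e.g. a 20th-percentile cut
#' yields about 80% ones), and generates the outcome
#' `y = beta0 + X beta + eps`, `eps ~ N(0, noise_sd)` from the dichotomized
#' design matrix. Fully observed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @return an `mi_dataset` with columns `x1..x20, y`; the configuration is
#'   attached as attribute `"sim_config"`.
#' @export
simulate_complete <- function(config, seed = NULL) {
  maybe_seed(seed)
  n <- config$n_obs
  p <- config$n_cov
  R <- build_correlation_matrix(config$corr_entries, p)
  Z <- matrix(stats::rnorm(n * p), n, p) %*% chol(R)
  X <- Z
  dp <- config$dichotomize_percentiles
  for (nm in names(dp)) {
    j <- as.integer(nm)
    X[, j] <- as.numeric(Z[, j] > stats::qnorm(dp[[nm]] / 100))
  }
  y <- config$beta0 + drop(X %*% config$beta) +
    stats::rnorm(n, sd = config$noise_sd)
  vals <- cbind(X, y)
  colnames(vals) <- c(paste0("x", seq_len(p)), "y")
  types <- c(ifelse(seq_len(p) %in% as.integer(names(dp)),
                    "binary", "continuous"), "continuous")
  out <- mi_dataset(vals, var_types = types)
  attr(out, "sim_config") <- config
  out
}

#' Delete covariate cells completely at random
#'
#' Each cell of a listed covariate column is set unobserved independently with
#' its configured probability. The outcome is never deleted. The pre-deletion
#' matrix is retained in attribute `"complete"` so simulation truth stays
#' available; only `values` (NA-filled) and `mask` change.
#'
#' @param data a complete `mi_dataset`.
#' @param miss_probs named numeric vector, covariate index -> per-cell
#'   probability; defaults to the generating configuration's.
#' @param seed integer seed, or `NULL`.
#' @return an `mi_dataset` with MCAR missingness.
#' @export
apply_mcar <- function(data, miss_probs = NULL, seed = NULL) {
  maybe_seed(seed)
  if (is.null(miss_probs)) {
    cfg <- attr(data, "sim_config")
    if (is.null(cfg)) stop("miss_probs required when data has no sim_config")
    miss_probs <- cfg$miss_probs
  }
  ycol <- which(colnames(data$values) == data$outcome)
  if (any(as.integer(names(miss_probs)) == ycol)) {
    stop("missingness may not be applied to the outcome column")
  }
  out <- data
  attr(out, "complete") <- data$values
  for (nm in names(miss_probs)) {
    j <- as.integer(nm)
    drop_cell <- stats::runif(nrow(data$values)) < miss_probs[[nm]]
    out$mask[drop_cell, j] <- FALSE
    out$values[drop_cell, j] <- NA
  }
  out
}
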