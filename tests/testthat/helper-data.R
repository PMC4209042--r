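# Small fixtures built in code.

# a modest random regression problem
toy_xy <- function(n = 40, p = 6, seed = 1, sparse = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- if (sparse) c(1.5, -2, 0.8, rep(0, p - 3)) else rnorm(p)
  y <- 0.5 + drop(X %*% beta) + rnorm(n)
  list(X = X, y = y)
}

toy_dataset <- function(n = 40, p = 6, seed = 1) {
  d <- toy_xy(n, p, seed)
  mi_dataset(cbind(d$X, y = d$y))
}

# a fixed-coefficient model, convenient for bookkeeping tests
fixed_model <- function(intercept, coefficients) {
  structure(list(intercept = intercept, coefficients = coefficients,
                 lambda = NA_real_),
            class = "lasso_model")
}
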