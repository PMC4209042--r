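# Discrimination and calibration of a (pooled) linear prediction model:
# mean squared error, apparent performance averaged over imputed sets, the
# calibration line of observed outcome on linear predictor, a decile
# calibration table with a +/-0.5 clinical band, and uniform-shrinkage
# recalibration.

#' Mean squared prediction error of a model on a data set
#'
#' @param model a `lasso_model`/`pooled_lasso` (anything with a `predict`
#'   method for the data).
#' @param data a complete `mi_dataset`.
#' @return non-negative scalar, `mean((observed - predicted)^2)`.
#' @export
model_mse <- function(model, data) {
  mean((outcome_of(data) - stats::predict(model, data))^2)
}

#' Apparent performance of a pooled model over multiply imputed data
#'
#' The single pooled model is scored by MSE on each completed set and the M
#' values are averaged.
#'
#' @param model the pooled model.
#' @param imputed an `mi_imputed` object or list of complete `mi_dataset`s.
#' @return scalar averaged apparent MSE.
#' @export
apparent_performance <- function(model, imputed) {
  sets <- if (inherits(imputed, "mi_imputed")) imputed$sets else imputed
  mean(vapply(sets, function(s) model_mse(model, s), numeric(1)))
}

#' Calibration of predictions against observed outcomes
#'
#' Regresses the observed outcome on the model's linear predictor (LP):
#' `y = alpha_lp + beta_lp * LP`. `beta_lp` is the calibration slope (1 =
#' perfect calibration; > 1 indicates over-shrunk predictions). Rows are also
#' grouped into deciles of predicted value and the mean predicted and mean
#' observed outcome per decile are tabulated, each decile flagged when its
#' means differ by no more than the +/-0.5 minimal clinically important
#' difference.
#'
#' @param model the model to calibrate.
#' @param data a complete `mi_dataset`.
#' @param n_bins number of prediction-quantile bins (default 10).
#' @param band half-width of the clinical band (default 0.5).
#' @return An object of class `calibration_result`: `intercept_lp`,
#'   `slope_lp`, `decile_table` (bin, n, mean_predicted, mean_observed,
#'   within_band).
#' @export
calibration <- function(model, data, n_bins = 10L, band = 0.5) {
  lp <- stats::predict(model, data)
  y <- outcome_of(data)
  if (stats::sd(lp) == 0) {
    stop("constant linear predictor: calibration slope undefined")
  }
  cf <- stats::coef(stats::lm(y ~ lp))
  # decile edges from sample quantiles of the predictions; ties fall to the
  # lower bin via findInterval on the interior edges
  edges <- stats::quantile(lp, probs = seq_len(n_bins - 1L) / n_bins,
                           type = 7, names = FALSE)
  bin <- findInterval(lp, edges, left.open = TRUE) + 1L
  tab <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    data.frame(bin = b, n = sum(sel),
               mean_predicted = if (any(sel)) mean(lp[sel]) else NA_real_,
               mean_observed = if (any(sel)) mean(y[sel]) else NA_real_)
  }))
  tab$within_band <- abs(tab$mean_predicted - tab$mean_observed) <= band
  structure(
    list(intercept_lp = unname(cf[1]), slope_lp = unname(cf[2]),
         decile_table = tab, band = band),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration: alpha_lp = %.4f, beta_lp = %.4f; %d/%d deciles within +/-%.1f\n",
              x$intercept_lp, x$slope_lp,
              sum(x$decile_table$within_band, na.rm = TRUE),
              nrow(x$decile_table), x$band))
  invisible(x)
}

#' Recalibrate a model by a uniform shrinkage factor
#'
#' Every slope coefficient is multiplied by `s`; the intercept is then
#' re-estimated so that the mean prediction matches the mean observed outcome,
#' averaged over the imputed sets (equivalently, the OLS intercept with the
#' slope fixed at 1 on the s-scaled predictor). `s` is typically the mean of
#' bootstrap calibration slopes ([shrinkage_factor()]); `s > 1` "unshrinks"
#' over-shrunk coefficients.
#'
#' @param model a `pooled_lasso` (or `lasso_model`).
#' @param s positive finite shrinkage factor.
#' @param data an `mi_imputed`, list of complete sets, or single
#'   `mi_dataset`, used to re-estimate the intercept.
#' @return a model of the same class with scaled slopes and new intercept.
#' @export
recalibrate <- function(model, s, data) {
  stopifnot(is.finite(s), s > 0)
  sets <- if (inherits(data, "mi_imputed")) data$sets
          else if (inherits(data, "mi_dataset")) list(data)
          else data
  out <- model
  out$coefficients <- model$coefficients * s
  shifts <- vapply(sets, function(d) {
    mean(outcome_of(d)) - mean(drop(covariates(d) %*% out$coefficients))
  }, numeric(1))
  out$intercept <- mean(shifts)
  out$recalibrated_s <- s
  out
}
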