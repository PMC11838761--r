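# Residual-based model-fit assessment: bias (mean residual), imprecision
# (residual standard deviation), inaccuracy (mean absolute residual), and
# the percentage of observations captured by their 95% credible intervals.

#' Model residuals
#'
#' Observed minus predicted posterior mean, on the model (log) scale.
#'
#' @param observed,predicted aligned numeric vectors; pairs with missing
#'   observations are excluded.
#' @return numeric residual vector.
#' @export
model_residuals <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  keep <- is.finite(observed) & is.finite(predicted)
  observed[keep] - predicted[keep]
}

#' Calibration metrics from residuals and credible intervals
#'
#' Bias is the mean residual; imprecision the sample standard deviation of
#' the residuals (n - 1 denominator); inaccuracy the mean absolute residual
#' (so inaccuracy >= |bias| always); capture the percentage of observations
#' lying inside their 95\% interval, endpoints included. Capture is
#' evaluated on whichever scale the intervals are supplied on; the
#' back-transform to relative mobility is monotone and leaves the flag
#' unchanged.
#'
#' @param residuals residual vector.
#' @param lower,upper per-observation interval bounds (same order as
#'   \code{observed}); optional — without them capture is NA.
#' @param observed observed values matched to the intervals.
#' @return list of class \code{mob_calibration_metrics}: bias, imprecision,
#'   inaccuracy, capture_95, n.
#' @export
compute_metrics <- function(residuals, lower = NULL, upper = NULL,
                            observed = NULL) {
  n <- length(residuals)
  bias <- mean(residuals)
  imprecision <- if (n >= 2L) stats::sd(residuals) else NA_real_
  inaccuracy <- mean(abs(residuals))
  capture <- NA_real_
  if (!is.null(lower) && !is.null(upper)) {
    if (is.null(observed))
      stop("`observed` is required to evaluate capture", call. = FALSE)
    if (length(lower) != length(observed) || length(upper) != length(observed))
      stop("interval bounds must align with `observed`", call. = FALSE)
    capture <- 100 * mean(observed >= lower & observed <= upper)
  }
  structure(list(bias = bias, imprecision = imprecision,
                 inaccuracy = inaccuracy, capture_95 = capture, n = n),
            class = "mob_calibration_metrics")
}

#' @exportS3Method base::print
print.mob_calibration_metrics <- function(x, ...) {
  cat(sprintf("<calibration> n=%d bias=%.3g imprecision=%.3g inaccuracy=%.3g capture95=%.1f%%\n",
              x$n, x$bias, x$imprecision, x$inaccuracy, x$capture_95))
  invisible(x)
}

#' Plot-ready calibration table for a fitted model
#'
#' One row per observed cell: observed value, predicted posterior mean, the
#' posterior predictive 95\% bounds (observation noise included — these are
#' the intervals a new observation should fall in), and the captured flag.
#' Rows are sorted by observed value for direct plotting.
#'
#' @param fit a \code{mob_fit_result}.
#' @return data.frame (unit, year, month, observed, predicted, lower,
#'   upper, captured).
#' @export
calibration_table <- function(fit) {
  p <- fit$predictions[fit$predictions$observed, ]
  out <- data.frame(unit = p$unit, year = p$year, month = p$month,
                    observed = p$logR_obs, predicted = p$logR_mean,
                    lower = p$pred_lower, upper = p$pred_upper,
                    stringsAsFactors = FALSE)
  out$captured <- out$observed >= out$lower & out$observed <= out$upper
  out <- out[order(out$observed), ]
  rownames(out) <- NULL
  out
}

#' Calibration metrics of a fitted model
#'
#' Convenience wrapper: residuals and capture from the fit's own
#' predictions at observed cells.
#'
#' @param fit a \code{mob_fit_result}.
#' @return a \code{mob_calibration_metrics}.
#' @export
calibrate_fit <- function(fit) {
  tab <- calibration_table(fit)
  compute_metrics(model_residuals(tab$observed, tab$predicted),
                  lower = tab$lower, upper = tab$upper,
                  observed = tab$observed)
}
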