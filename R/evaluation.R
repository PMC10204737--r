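#' Accuracy metrics for trait estimates
#'
#' Computes the standard agreement indices between observed and
#' predicted trait values: the determination coefficient R2 (squared
#' Pearson correlation of obs and pred), the mean absolute error (MAE),
#' the root-mean-squared error (RMSE), and the slope/intercept of the
#' OLS regression of predictions on observations (the scatter-plot
#' convention: pred on the y axis).
#'
#' @param obs Observed values, length >= 2, nonzero variance.
#' @param pred Predicted values, same length.
#' @return An `eval_metrics` object: list with `r2`, `mae`, `rmse`,
#'   `slope`, `intercept`, `n`.
#' @details R2 is the squared correlation, not 1 - SSres/SStot against
#'   the 1:1 line; a high R2 therefore indicates tight linear
#'   association, not agreement by itself — read it together with the
#'   slope and MAE/RMSE. RMSE >= MAE always (Jensen's inequality).
#' @examples
#' evaluate(c(0, 1, 2, 3), c(1, 2, 3, 4))   # r2 = 1, mae = rmse = 1
#' @export
evaluate <- function(obs, pred) {
  if (length(obs) != length(pred)) {
    stop("obs and pred must have equal length", call. = FALSE)
  }
  keep <- stats::complete.cases(obs, pred)
  obs <- obs[keep]; pred <- pred[keep]
  if (length(obs) < 2) stop("need at least 2 paired samples", call. = FALSE)
  if (stats::var(obs) == 0) {
    stop("obs has zero variance; R2 and regression undefined",
         call. = FALSE)
  }
  err <- pred - obs
  r2 <- if (stats::var(pred) == 0) 0 else stats::cor(obs, pred)^2
  fit <- stats::lm(pred ~ obs)
  structure(list(r2 = r2,
                 mae = mean(abs(err)),
                 rmse = sqrt(mean(err^2)),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(obs)),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "n = %d  R2 = %.3f  MAE = %.4g  RMSE = %.4g  slope = %.3f  intercept = %.4g\n",
    x$n, x$r2, x$mae, x$rmse, x$slope, x$intercept))
  invisible(x)
}

#' Accuracy improvement of one model over a baseline
#'
#' Percentage reduction of the mean absolute error relative to the
#' baseline: 100 * (MAE_baseline - MAE_model) / MAE_baseline. Positive
#' values mean the model improves on the baseline.
#'
#' @param mae_baseline Baseline MAE, > 0, trait units.
#' @param mae_model Model MAE, same units.
#' @return Improvement percentage.
#' @examples
#' improvement_percent(19.02, 11.29)   # ~40.6
#' @export
improvement_percent <- function(mae_baseline, mae_model) {
  if (any(mae_baseline <= 0)) {
    stop("mae_baseline must be > 0", call. = FALSE)
  }
  100 * (mae_baseline - mae_model) / mae_baseline
}
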