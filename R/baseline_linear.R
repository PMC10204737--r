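#' Fit the linear SIF-Vcmax baseline
#'
#' The simple empirical alternative to the mechanistic chain: ordinary
#' least squares of observed Vcmax on SIF, pooled across all samples,
#' with an intercept.
#'
#' @param sif SIF observations, mW m-2 nm-1 sr-1.
#' @param vcmax_obs Observed Vcmax, umol m-2 s-1, same length.
#' @return A `linear_model` object: list with `slope`, `intercept`, `n`
#'   and the underlying `lm` fit.
#' @examples
#' fit_linear(c(1, 2, 3), c(10, 20, 30))
#' @export
fit_linear <- function(sif, vcmax_obs) {
  if (length(sif) != length(vcmax_obs)) {
    stop("sif and vcmax_obs must have equal length", call. = FALSE)
  }
  keep <- stats::complete.cases(sif, vcmax_obs)
  sif <- sif[keep]; vcmax_obs <- vcmax_obs[keep]
  if (length(sif) < 2) stop("need at least 2 samples", call. = FALSE)
  if (length(unique(sif)) < 2) {
    stop("degenerate input: SIF has no variation", call. = FALSE)
  }
  fit <- stats::lm(vcmax_obs ~ sif)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(sif),
                 fit = fit),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("Linear SIF-Vcmax baseline: Vcmax = %.4g * SIF + %.4g (n = %d)\n",
              x$slope, x$intercept, x$n))
  invisible(x)
}

#' Predict Vcmax with the linear baseline
#'
#' Evaluates slope * SIF + intercept. Negative predictions are floored
#' at zero (Vcmax is nonnegative) with a message reporting how many.
#'
#' @param model A `linear_model` from [fit_linear()].
#' @param sif SIF values (vectorised).
#' @return Vcmax estimates, umol m-2 s-1, >= 0.
#' @export
predict_linear <- function(model, sif) {
  stopifnot(inherits(model, "linear_model"))
  pred <- model$slope * sif + model$intercept
  n_neg <- sum(pred < 0)
  if (n_neg > 0) {
    message("predict_linear: floored ", n_neg,
            " negative prediction(s) at 0")
  }
  pmax(pred, 0)
}
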