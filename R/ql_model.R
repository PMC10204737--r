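#' Exponential qL-PAR model
#'
#' The fraction of open PSII reaction centers (qL, "lake" model
#' convention) decreases nonlinearly with irradiance. The retrieval uses
#' the empirical law qL = a * exp(b * PAR) with amplitude `a` > 0 and
#' rate coefficient `b` <= 0 (per W m-2), so that qL is non-increasing
#' in PAR.
#'
#' @param a Amplitude, unitless, > 0.
#' @param b Rate coefficient, per (W m-2), <= 0.
#' @param r2 Coefficient of determination of the fit on the original
#'   (not log) scale; `NA` for a model set directly from parameters.
#' @param n Number of (qL, PAR) pairs used in the fit; `NA` if not fitted.
#' @return An object of class `ql_model`.
#' @seealso [fit_ql_par()], [predict_ql()]
#' @export
ql_model <- function(a, b, r2 = NA_real_, n = NA_integer_) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 1 || !is.finite(a) || a <= 0) {
    stop("ql_model: a must be a single positive number", call. = FALSE)
  }
  if (length(b) != 1 || !is.finite(b) || b > 0) {
    stop("ql_model: b must be <= 0 (qL cannot increase with PAR)",
         call. = FALSE)
  }
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) {
    stop("ql_model: r2 must lie in [0, 1]", call. = FALSE)
  }
  structure(list(a = a, b = b, r2 = as.numeric(r2), n = as.integer(n)),
            class = "ql_model")
}

#' @export
print.ql_model <- function(x, ...) {
  cat(sprintf("qL-PAR exponential model: qL = %.6g * exp(%.6g * PAR)\n",
              x$a, x$b))
  if (!is.na(x$r2)) cat(sprintf("  fit: R2 = %.4f on n = %d pairs\n",
                                x$r2, x$n))
  invisible(x)
}

#' Fit the qL-PAR exponential law
#'
#' Least-squares fit of qL = a * exp(b * PAR) to a table of (qL, PAR)
#' pairs. The fit is nonlinear on the original scale (log-transforming
#' would reweight the errors); the log-linear regression of ln(qL) on
#' PAR serves only as the starting point.
#'
#' @param pairs Data frame with numeric columns `par` (W m-2, >= 0) and
#'   `ql` (fraction in (0, 1]). At least 3 rows with at least 2 distinct
#'   PAR values.
#' @param max_iter Iteration cap for the Levenberg-Marquardt optimiser.
#' @return A [ql_model()] with fitted `a`, `b`, the original-scale `r2`
#'   (1 - SSres/SStot) and `n`.
#' @details The optimised residual sum of squares is never worse than
#'   that of the log-linear start evaluated on the original scale; if
#'   the optimiser fails to converge within `max_iter` iterations an
#'   error is raised.
#' @examples
#' pairs <- data.frame(par = seq(0, 2000, by = 250))
#' pairs$ql <- 0.9 * exp(-0.001 * pairs$par)
#' fit_ql_par(pairs)
#' @export
fit_ql_par <- function(pairs, max_iter = 200) {
  pairs <- as.data.frame(pairs)
  if (!all(c("par", "ql") %in% names(pairs))) {
    stop("pairs must have columns 'par' and 'ql'", call. = FALSE)
  }
  pairs <- pairs[stats::complete.cases(pairs[, c("par", "ql")]), ]
  if (nrow(pairs) < 3) {
    stop("need at least 3 (qL, PAR) pairs, got ", nrow(pairs),
         call. = FALSE)
  }
  if (length(unique(pairs$par)) < 2) {
    stop("PAR column is degenerate (fewer than 2 distinct values)",
         call. = FALSE)
  }
  if (any(pairs$par < 0)) stop("PAR must be >= 0", call. = FALSE)
  if (any(pairs$ql <= 0 | pairs$ql > 1)) {
    stop("qL values must lie in (0, 1]", call. = FALSE)
  }

  # log-linear initialisation: ln(qL) = ln(a) + b * PAR
  init <- stats::lm(log(ql) ~ par, data = pairs)
  start <- list(a = exp(stats::coef(init)[[1]]),
                b = min(stats::coef(init)[[2]], 0))

  fit <- minpack.lm::nlsLM(
    ql ~ a * exp(b * par),
    data = pairs,
    start = start,
    control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                         ftol = 1e-14, ptol = 1e-14)
  )
  if (!fit$convInfo$isConv) {
    stop("qL-PAR fit did not converge within ", max_iter, " iterations",
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  resid <- pairs$ql - cf[["a"]] * exp(cf[["b"]] * pairs$par)
  ss_res <- sum(resid^2)
  ss_tot <- sum((pairs$ql - mean(pairs$ql))^2)
  r2 <- max(0, min(1, 1 - ss_res / ss_tot))
  ql_model(a = cf[["a"]], b = cf[["b"]], r2 = r2, n = nrow(pairs))
}

#' Predict qL from PAR
#'
#' Evaluates qL = a * exp(b * PAR), clamped into (0, 1] since qL is a
#' fraction; a warning reports how many values were clamped.
#'
#' @param model A [ql_model()].
#' @param par PAR values, W m-2, >= 0 (vectorised).
#' @return Predicted qL fraction(s) in (0, 1].
#' @examples
#' m <- ql_model(a = 0.9, b = -0.001)
#' predict_ql(m, 0)      # 0.9
#' predict_ql(m, 1000)   # 0.9 * exp(-1)
#' @export
predict_ql <- function(model, par) {
  stopifnot(inherits(model, "ql_model"))
  if (any(par < 0)) stop("PAR must be >= 0", call. = FALSE)
  ql <- model$a * exp(model$b * par)
  n_clamped <- sum(ql > 1)
  if (n_clamped > 0) {
    warning("predict_ql: clamped ", n_clamped,
            " prediction(s) above 1 to the physical range (0, 1]",
            call. = FALSE)
  }
  pmin(ql, 1)
}
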