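#' Photosynthetic parameter set
#'
#' Bundle of the physiological and biochemical constants used by the
#' SIF-to-trait retrieval chain. Defaults describe an unstressed C3 crop
#' canopy at its typical operating point; every value can be overridden
#' here or through a configuration file (see [load_config()]).
#'
#' @param phi_psii_max Maximum photochemical quantum yield of PSII
#'   (dark-adapted Fv/Fm analogue), unitless, in (0, 1). Default 0.83,
#'   the converged value for unstressed C3 leaves.
#' @param k_df Ratio kD/kF of the rate constants of constitutive thermal
#'   dissipation and fluorescence emission, unitless, > 0. Default 19.
#' @param ci Intercellular CO2 mole fraction, umol mol-1. Default 280
#'   (0.7 x Ca, the standard C3 operating point).
#' @param ca Ambient CO2 mole fraction, umol mol-1. Default 400.
#' @param gamma_star CO2 compensation point in the absence of
#'   mitochondrial respiration, umol mol-1. Default 42.75 (25 C value
#'   for C3 leaves).
#' @param km Effective Michaelis-Menten constant of Rubisco for CO2 in
#'   the presence of O2, umol mol-1. Default 711 (25 C value).
#' @param diffusivity_ratio Water-to-CO2 diffusivity ratio entering
#'   Fick's law for stomatal conductance, unitless. Default 1.6.
#' @param sif_scale Optional multiplicative unit-scaling factor applied
#'   to SIF before entering the ETR relation (radiance-to-photon-flux
#'   conversions can be folded in here). Default 1, i.e. SIF is used as
#'   observed and the conversion is absorbed into the proportionality.
#'
#' @details
#' CO2 quantities are treated as mole fractions (umol mol-1); only their
#' differences and ratios enter the equations, so users supplying partial
#' pressures in consistent units obtain identical results. No temperature
#' adjustment of `gamma_star`, `km` or `phi_psii_max` is applied.
#'
#' @return An object of class `photo_params` (a validated named list).
#' @examples
#' p <- photo_params()
#' p$phi_psii_max
#' photo_params(ca = 420)
#' @seealso [retrieve_series()], [load_config()]
#' @export
photo_params <- function(phi_psii_max = 0.83,
                         k_df = 19,
                         ci = 280,
                         ca = 400,
                         gamma_star = 42.75,
                         km = 711,
                         diffusivity_ratio = 1.6,
                         sif_scale = 1.0) {
  p <- list(
    phi_psii_max = as.numeric(phi_psii_max),
    k_df = as.numeric(k_df),
    ci = as.numeric(ci),
    ca = as.numeric(ca),
    gamma_star = as.numeric(gamma_star),
    km = as.numeric(km),
    diffusivity_ratio = as.numeric(diffusivity_ratio),
    sif_scale = as.numeric(sif_scale)
  )
  class(p) <- "photo_params"
  validate_photo_params(p)
  p
}

validate_photo_params <- function(p) {
  stopifnot(inherits(p, "photo_params"))
  for (f in names(p)) {
    if (length(p[[f]]) != 1L || !is.finite(p[[f]])) {
      stop("photo_params field '", f, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (p$phi_psii_max <= 0 || p$phi_psii_max >= 1) {
    stop("phi_psii_max must lie in (0, 1), got ", p$phi_psii_max,
         call. = FALSE)
  }
  if (p$k_df <= 0) stop("k_df must be > 0", call. = FALSE)
  if (p$gamma_star <= 0) stop("gamma_star must be > 0", call. = FALSE)
  if (p$ci <= p$gamma_star) {
    stop("ci must exceed gamma_star (ci = ", p$ci, ", gamma_star = ",
         p$gamma_star, ")", call. = FALSE)
  }
  if (p$ca <= p$ci) {
    stop("ca must exceed ci (ca = ", p$ca, ", ci = ", p$ci, ")",
         call. = FALSE)
  }
  if (p$km <= 0) stop("km must be > 0", call. = FALSE)
  if (p$diffusivity_ratio <= 0) {
    stop("diffusivity_ratio must be > 0", call. = FALSE)
  }
  if (p$sif_scale <= 0) stop("sif_scale must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.photo_params <- function(x, ...) {
  cat("Photosynthetic parameters:\n")
  cat(sprintf("  phi_psii_max      %-8g (max PSII quantum yield)\n",
              x$phi_psii_max))
  cat(sprintf("  k_df              %-8g (kD/kF)\n", x$k_df))
  cat(sprintf("  ci                %-8g umol mol-1\n", x$ci))
  cat(sprintf("  ca                %-8g umol mol-1\n", x$ca))
  cat(sprintf("  gamma_star        %-8g umol mol-1\n", x$gamma_star))
  cat(sprintf("  km                %-8g umol mol-1\n", x$km))
  cat(sprintf("  diffusivity_ratio %-8g\n", x$diffusivity_ratio))
  cat(sprintf("  sif_scale         %-8g\n", x$sif_scale))
  invisible(x)
}
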