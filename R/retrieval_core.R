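#' Canopy fluorescence escape probability
#'
#' Approximates the probability that a fluorescence photon emitted in
#' the canopy escapes toward the sensor as epsilon = NIRv / FPAR, where
#' NIRv is the near-infrared reflectance of vegetation and FPAR the
#' fraction of absorbed PAR.
#'
#' @param nirv NIRv, unitless, >= 0 (vectorised).
#' @param fpar FPAR, fraction in (0, 1] (vectorised).
#' @return epsilon, unitless.
#' @examples
#' escape_ratio(0.3, 0.9)   # 1/3
#' @export
escape_ratio <- function(nirv, fpar) {
  if (any(nirv < 0)) stop("nirv must be >= 0", call. = FALSE)
  if (any(fpar <= 0)) stop("fpar must be > 0", call. = FALSE)
  nirv / fpar
}

# Mechanistic scaling constant of the SIF -> ETR relation:
# C = phi_psii_max * (1 + k_df) / (1 - phi_psii_max).
# With the defaults (0.83, 19): C = 0.83 * 20 / 0.17 = 97.647059.
etr_scaling_constant <- function(p) {
  p$phi_psii_max * (1 + p$k_df) / (1 - p$phi_psii_max)
}

#' Electron transport rate from SIF
#'
#' The nonlinear mechanistic SIF-ETR relation:
#' \deqn{ETR = qL(PAR) \cdot \frac{\Phi_{PSIImax}(1 + k_{DF})}
#'   {(1 - \Phi_{PSIImax})\,\varepsilon} \cdot SIF}
#' where qL comes from the exponential qL-PAR law and epsilon is the
#' canopy escape probability. The relation is linear in SIF at fixed
#' qL and epsilon; the nonlinearity enters through qL(PAR).
#'
#' @param sif Canopy SIF, mW m-2 nm-1 sr-1, >= 0 (vectorised).
#' @param par PAR, W m-2, >= 0 (vectorised).
#' @param epsilon Escape probability from [escape_ratio()], > 0
#'   (vectorised).
#' @param ql_model A fitted or constructed [ql_model()].
#' @param p A [photo_params()] object.
#' @return ETR, umol m-2 s-1.
#' @details SIF is multiplied by `p$sif_scale` (default 1) before the
#'   relation is applied, so a radiometric-to-photon-flux conversion can
#'   be supplied for physically calibrated use.
#' @examples
#' m <- ql_model(0.9, -0.001)
#' etr_from_sif(1.0, par = 0, epsilon = 1, ql_model = m, p = photo_params())
#' @export
etr_from_sif <- function(sif, par, epsilon, ql_model, p = photo_params()) {
  validate_photo_params(p)
  if (any(sif < 0)) stop("sif must be >= 0", call. = FALSE)
  if (any(epsilon <= 0)) {
    stop("epsilon must be > 0 (degenerate NIRv/FPAR record)",
         call. = FALSE)
  }
  ql <- predict_ql(ql_model, par)
  ql * etr_scaling_constant(p) / epsilon * (p$sif_scale * sif)
}

#' Electron-transport CO2 factor m
#'
#' m = (Ci - Gamma*) / (Ci + 2 Gamma*), the CO2-dependent factor of
#' RuBP-regeneration-limited assimilation Aj = (ETR/4) m. Lies in (0, 1)
#' and also equals 4x the electron-use efficiency of C3 photosynthesis.
#'
#' @param p A [photo_params()] object.
#' @return m, unitless in (0, 1).
#' @export
m_factor <- function(p = photo_params()) {
  validate_photo_params(p)
  (p$ci - p$gamma_star) / (p$ci + 2 * p$gamma_star)
}

#' Rubisco-limited CO2 factor mc
#'
#' mc = (Ci - Gamma*) / (Ci + Km), the CO2-dependent factor of
#' Rubisco-limited assimilation Ac = Vcmax mc. Lies in (0, 1).
#'
#' @param p A [photo_params()] object.
#' @return mc, unitless in (0, 1).
#' @export
mc_factor <- function(p = photo_params()) {
  validate_photo_params(p)
  (p$ci - p$gamma_star) / (p$ci + p$km)
}

#' Maximum carboxylation rate from ETR
#'
#' Under the evolutionary-optimality coordination Ac = Aj, with
#' Ac = Vcmax mc and Aj = (ETR/4) m, the maximum carboxylation rate is
#' \deqn{V_{cmax} = \frac{ETR \cdot m}{4\, m_c}.}
#'
#' @param etr ETR, umol m-2 s-1, >= 0 (vectorised).
#' @param p A [photo_params()] object.
#' @return Vcmax, umol m-2 s-1.
#' @examples
#' vcmax_from_etr(100, photo_params(ci = 280, gamma_star = 43, km = 711))
#' @export
vcmax_from_etr <- function(etr, p = photo_params()) {
  validate_photo_params(p)
  if (any(etr < 0)) stop("etr must be >= 0", call. = FALSE)
  etr * m_factor(p) / (4 * mc_factor(p))
}

#' Stomatal conductance from ETR
#'
#' Net assimilation is A = (ETR/4) m (electron-use efficiency times
#' ETR); Fick's law A = gs (Ca - Ci) / r with diffusivity ratio r gives
#' \deqn{g_s = \frac{r}{4} \cdot \frac{m \cdot ETR}{C_a - C_i},}
#' the familiar 0.4 m ETR / (Ca - Ci) at r = 1.6. Units are
#' mol m-2 s-1 when ETR is in umol m-2 s-1 and (Ca - Ci) in umol mol-1.
#'
#' @param etr ETR, umol m-2 s-1, >= 0 (vectorised).
#' @param p A [photo_params()] object (requires `ca > ci`).
#' @return gs, mol m-2 s-1.
#' @export
gs_from_etr <- function(etr, p = photo_params()) {
  validate_photo_params(p)
  if (any(etr < 0)) stop("etr must be >= 0", call. = FALSE)
  (p$diffusivity_ratio / 4) * m_factor(p) * etr / (p$ca - p$ci)
}

#' Run the full SIF-to-trait retrieval over a series
#'
#' Applies, per timestamp: escape probability (NIRv/FPAR), qL(PAR),
#' SIF -> ETR, ETR -> Vcmax, and (unless disabled) ETR -> gs. Records
#' with a degenerate escape probability (NIRv = 0) are skipped with a
#' message rather than propagating NaN; output rows + skipped rows equal
#' input rows.
#'
#' @param series A [trait_series()].
#' @param ql_model A [ql_model()].
#' @param p A [photo_params()] object.
#' @param gs Logical; set `FALSE` for an ETR/Vcmax-only run (the gs
#'   column is then `NA`).
#' @return A `retrieval_series`: a data frame with columns
#'   `year, doy, epsilon, ql, etr, vcmax, gs`, attributes `params_used`,
#'   `ql_model_used`, `n_skipped`.
#' @examples
#' ts <- trait_series(data.frame(year = 2017, doy = 200, sif = 1,
#'                               par = 450, nirv = 0.3, fpar = 0.9))
#' retrieve_series(ts, ql_model(0.9, -0.001))
#' @export
retrieve_series <- function(series, ql_model, p = photo_params(),
                            gs = TRUE) {
  stopifnot(inherits(series, "trait_series"))
  validate_photo_params(p)
  df <- as.data.frame(series)

  ok <- df$nirv > 0 & df$fpar > 0 & df$sif >= 0
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    message("retrieve_series: skipped ", n_skipped,
            " record(s) with degenerate NIRv/FPAR or negative SIF")
  }
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) {
    stop("all records skipped: no retrievable timestamps", call. = FALSE)
  }

  epsilon <- escape_ratio(df$nirv, df$fpar)
  ql <- predict_ql(ql_model, df$par)
  etr <- ql * etr_scaling_constant(p) / epsilon * (p$sif_scale * df$sif)
  vcmax <- vcmax_from_etr(etr, p)
  gs_val <- if (gs) gs_from_etr(etr, p) else rep(NA_real_, length(etr))

  out <- data.frame(year = df$year, doy = df$doy, epsilon = epsilon,
                    ql = ql, etr = etr, vcmax = vcmax, gs = gs_val)
  structure(out,
            class = c("retrieval_series", "data.frame"),
            params_used = p,
            ql_model_used = ql_model,
            n_skipped = n_skipped)
}
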