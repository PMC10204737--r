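#' Configuration for the synthetic forward simulator
#'
#' The simulator generates a synthetic growing season from known trait
#' trajectories by running the retrieval equations in reverse: a smooth
#' seasonal Vcmax truth is converted to ETR (via the co-limitation
#' factors), ETR to noise-free SIF (inverting the SIF-ETR mechanism at
#' the day's PAR, NIRv and FPAR), and gs follows from ETR. Multiplicative
#' mean-one lognormal noise is then applied to the observables, so the
#' noise-free run is the exact inverse of the retrieval.
#'
#' @param n_days Number of daily records. Default 120, a full rice
#'   growing season.
#' @param year Calendar year stamped on the records.
#' @param start_doy First day of year; default 150 (early June).
#' @param vcmax_peak Peak of the true Vcmax trajectory, umol m-2 s-1.
#'   Default 130, the early-season canopy peak typical of paddy rice.
#' @param vcmax_shape Shape of the seasonal curve, a list with
#'   `peak_frac` (fraction of the season at which Vcmax peaks, default
#'   0.3: early season) and `width` (log-scale width, default 0.6). The
#'   curve is lognormal in normalised season time: rise, broad peak,
#'   long decline.
#' @param par_amplitude Seasonal maximum of daily PAR, W m-2. Default
#'   500 (midday-scale irradiance); PAR follows a smooth seasonal arc
#'   between 70% and 100% of this value.
#' @param ql_a,ql_b True parameters of the exponential qL-PAR law.
#'   Defaults 0.9 and -0.001 (qL about 0.55-0.9 over 0-600 W m-2).
#' @param nirv_range,fpar_range Seasonal (min, max) of the NIRv and
#'   FPAR arcs; both rise and fall with canopy development. Defaults
#'   (0.10, 0.40) and (0.40, 0.95).
#' @param noise_cv_sif Coefficient of variation of the multiplicative
#'   lognormal observation noise on SIF. Default 0.05.
#' @param noise_cv_index Same for NIRv and FPAR. Default 0 (reflectance
#'   indices are far less noisy than SIF retrievals; set > 0 to stress
#'   the escape-ratio pathway).
#' @param seed RNG seed making the season reproducible. Default 42.
#' @param photo [photo_params()] used in the forward equations.
#' @return A `sim_config` object (validated named list).
#' @seealso [simulate_season()]
#' @export
sim_config <- function(n_days = 120,
                       year = 2017,
                       start_doy = 150,
                       vcmax_peak = 130,
                       vcmax_shape = list(peak_frac = 0.3, width = 0.6),
                       par_amplitude = 500,
                       ql_a = 0.9,
                       ql_b = -0.001,
                       nirv_range = c(0.10, 0.40),
                       fpar_range = c(0.40, 0.95),
                       noise_cv_sif = 0.05,
                       noise_cv_index = 0,
                       seed = 42,
                       photo = photo_params()) {
  cfg <- list(n_days = as.integer(n_days), year = as.integer(year),
              start_doy = as.integer(start_doy),
              vcmax_peak = as.numeric(vcmax_peak),
              vcmax_shape = vcmax_shape,
              par_amplitude = as.numeric(par_amplitude),
              ql_a = as.numeric(ql_a), ql_b = as.numeric(ql_b),
              nirv_range = as.numeric(nirv_range),
              fpar_range = as.numeric(fpar_range),
              noise_cv_sif = as.numeric(noise_cv_sif),
              noise_cv_index = as.numeric(noise_cv_index),
              seed = as.integer(seed),
              photo = photo)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  if (cfg$start_doy < 1 || cfg$start_doy + cfg$n_days - 1 > 366) {
    stop("season must fit within doy 1..366", call. = FALSE)
  }
  if (cfg$vcmax_peak <= 0) stop("vcmax_peak must be > 0", call. = FALSE)
  if (cfg$vcmax_shape$peak_frac <= 0 || cfg$vcmax_shape$peak_frac > 1) {
    stop("vcmax_shape$peak_frac must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$vcmax_shape$width <= 0) stop("vcmax_shape$width must be > 0",
                                       call. = FALSE)
  if (cfg$par_amplitude <= 0) stop("par_amplitude must be > 0",
                                   call. = FALSE)
  if (cfg$ql_a <= 0 || cfg$ql_b > 0) {
    stop("qL truth requires ql_a > 0 and ql_b <= 0", call. = FALSE)
  }
  rng_ok <- function(r) length(r) == 2 && r[1] > 0 && r[2] >= r[1]
  if (!rng_ok(cfg$nirv_range)) stop("invalid nirv_range", call. = FALSE)
  if (!rng_ok(cfg$fpar_range) || cfg$fpar_range[2] > 1) {
    stop("fpar_range must lie within (0, 1]", call. = FALSE)
  }
  if (cfg$noise_cv_sif < 0 || cfg$noise_cv_index < 0) {
    stop("noise CVs must be >= 0", call. = FALSE)
  }
  validate_photo_params(cfg$photo)
  invisible(cfg)
}

# mean-one multiplicative lognormal noise with coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Simulate a synthetic growing season
#'
#' Forward simulation from known truth: for each day d with normalised
#' season time x = d / n_days,
#' \itemize{
#'   \item Vcmax*(x) = peak lognormal curve (rise, plateau, decline);
#'   \item PAR(x), NIRv(x), FPAR(x) follow smooth seasonal arcs;
#'   \item qL* = ql_a exp(ql_b PAR); epsilon = NIRv / FPAR;
#'   \item ETR* = 4 Vcmax* mc / m (inverse of the co-limitation step);
#'   \item noise-free SIF = ETR* (1 - phi) epsilon / (qL* phi (1 + kdf))
#'         (inverse of the SIF-ETR mechanism);
#'   \item gs* = (r/4) m ETR* / (Ca - Ci);
#'   \item observed SIF, NIRv, FPAR = truth x lognormal(mean 1, CV).
#' }
#' The output is deterministic given the config (which carries the
#' seed). With all noise CVs zero, [retrieve_series()] on the output
#' reproduces Vcmax* and gs* to machine precision.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{series}{a [trait_series()] of observed SIF/PAR/NIRv/FPAR,
#'       with `vcmax_obs` and `gs_obs` set to the truth (playing the
#'       role of field validation data);}
#'     \item{truth}{data frame of per-day true qL, ETR, Vcmax, gs and
#'       noise-free SIF.}
#'   }
#' @examples
#' season <- simulate_season(sim_config(n_days = 30, noise_cv_sif = 0))
#' head(season$truth)
#' @export
simulate_season <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  p <- cfg$photo
  d <- seq_len(cfg$n_days)
  x <- d / cfg$n_days
  doy <- cfg$start_doy + d - 1L

  vcmax_true <- cfg$vcmax_peak *
    exp(-(log(x / cfg$vcmax_shape$peak_frac))^2 /
          (2 * cfg$vcmax_shape$width^2))
  par <- cfg$par_amplitude * (0.7 + 0.3 * sin(pi * x))
  nirv_true <- cfg$nirv_range[1] +
    diff(cfg$nirv_range) * sin(pi * x)
  fpar_true <- cfg$fpar_range[1] +
    diff(cfg$fpar_range) * sin(pi * x)

  ql_true <- cfg$ql_a * exp(cfg$ql_b * par)
  epsilon_true <- nirv_true / fpar_true
  m <- m_factor(p)
  mc <- mc_factor(p)
  etr_true <- 4 * vcmax_true * mc / m
  sif_true <- etr_true * epsilon_true /
    (ql_true * etr_scaling_constant(p) * p$sif_scale)
  gs_true <- (p$diffusivity_ratio / 4) * m * etr_true / (p$ca - p$ci)

  obs <- withr::with_seed(cfg$seed, {
    list(sif = sif_true * lognormal_noise(cfg$n_days, cfg$noise_cv_sif),
         nirv = nirv_true * lognormal_noise(cfg$n_days, cfg$noise_cv_index),
         fpar = pmin(fpar_true *
                       lognormal_noise(cfg$n_days, cfg$noise_cv_index), 1))
  })

  series <- trait_series(
    data.frame(year = cfg$year, doy = doy, sif = obs$sif, par = par,
               nirv = obs$nirv, fpar = obs$fpar,
               vcmax_obs = vcmax_true, gs_obs = gs_true),
    label = sprintf("synthetic-%d-seed%d", cfg$year, cfg$seed)
  )
  truth <- data.frame(year = cfg$year, doy = doy, par = par,
                      ql = ql_true, epsilon = epsilon_true,
                      etr = etr_true, vcmax = vcmax_true, gs = gs_true,
                      sif = sif_true, nirv = nirv_true, fpar = fpar_true)
  list(series = series, truth = truth)
}

#' Generate synthetic (qL, PAR) fitting pairs
#'
#' Stand-in for radiative-transfer simulations of qL under varying
#' irradiance: PAR on an even grid over [0, par_max], qL sampled from
#' the exponential law plus additive Gaussian noise, clamped into
#' (0, 1]. Deterministic given the seed.
#'
#' @param a,b True parameters of the exponential law.
#' @param n Number of pairs, >= 3. Default 40.
#' @param par_max Upper end of the PAR grid, W m-2. Default 2000.
#' @param noise_sd Additive Gaussian noise standard deviation on qL.
#' @param seed RNG seed.
#' @return A data frame with columns `par`, `ql`.
#' @examples
#' pairs <- generate_ql_pairs(noise_sd = 0)
#' fit_ql_par(pairs)     # recovers a = 0.9, b = -0.001 exactly
#' @export
generate_ql_pairs <- function(a = 0.9, b = -0.001, n = 40,
                              par_max = 2000, noise_sd = 0.02,
                              seed = 42) {
  if (n < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (par_max <= 0) stop("par_max must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  par <- seq(0, par_max, length.out = n)
  ql <- withr::with_seed(seed, {
    a * exp(b * par) + stats::rnorm(n, sd = noise_sd)
  })
  ql <- pmin(pmax(ql, 1e-6), 1)
  data.frame(par = par, ql = ql)
}
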