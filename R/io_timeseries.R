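#' Construct a trait time series
#'
#' A `trait_series` is the observed per-timestamp record the retrieval
#' consumes: canopy SIF, PAR, NIRv and FPAR keyed by (year, day-of-year),
#' optionally with observed Vcmax and gs for validation.
#'
#' @param df A data frame with columns `year`, `doy`, `sif`, `par`,
#'   `nirv`, `fpar` and optionally `vcmax_obs`, `gs_obs`, `hour`.
#'   Units: SIF mW m-2 nm-1 sr-1, PAR W m-2, NIRv and FPAR unitless,
#'   Vcmax umol m-2 s-1, gs mol m-2 s-1.
#' @param label Free-text identifier (e.g. site-year). Default "".
#' @return A `trait_series`: the validated data frame, sorted by
#'   (year, doy), with attribute `label`.
#' @details Invariants enforced: `sif >= 0`, `par >= 0`, `nirv >= 0`,
#'   `0 < fpar <= 1`, and (year, doy) unique. An optional fractional
#'   `hour` column is carried through untouched.
#' @export
trait_series <- function(df, label = "") {
  required <- c("year", "doy", "sif", "par", "nirv", "fpar")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("trait_series is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("trait_series must be non-empty", call. = FALSE)
  df <- df[order(df$year, df$doy), , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$year, df$doy)
  if (anyDuplicated(key)) {
    stop("duplicate (year, doy) pairs in trait_series", call. = FALSE)
  }
  if (any(df$doy < 1 | df$doy > 366)) {
    stop("doy must lie in 1..366", call. = FALSE)
  }
  bad <- df$sif < 0 | df$par < 0 | df$nirv < 0 | df$fpar <= 0 | df$fpar > 1
  if (any(bad)) {
    stop(sum(bad), " record(s) violate trait invariants ",
         "(sif, par, nirv >= 0; 0 < fpar <= 1)", call. = FALSE)
  }
  structure(df, class = c("trait_series", "data.frame"), label = label)
}

#' Read a trait time series from CSV
#'
#' Reads a comma-separated file ('.' decimal, header row required) into a
#' [trait_series()]. Rows with missing or invariant-violating required
#' fields are dropped, not imputed; the number of drops is reported via a
#' message and stored in the `n_dropped` attribute.
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector mapping canonical field names
#'   to file column names, e.g. `c(sif = "SIF_760")`. Unmapped fields are
#'   read from columns of the same name.
#' @param label Series label; defaults to the file name.
#' @return A `trait_series` with attribute `n_dropped`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(year = 2017, doy = 180:182, sif = c(1, 1.2, 0.9),
#'                      par = 450, nirv = 0.3, fpar = 0.9),
#'           f, row.names = FALSE)
#' ts <- read_timeseries(f)
#' nrow(ts)
#' @export
read_timeseries <- function(path, column_map = character(), label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("year", "doy", "sif", "par", "nirv", "fpar")
  optional <- c("vcmax_obs", "gs_obs", "hour")
  for (field in c(required, optional)) {
    src <- if (field %in% names(column_map)) column_map[[field]] else field
    if (src %in% names(raw)) {
      raw[[field]] <- suppressWarnings(as.numeric(raw[[src]]))
    } else if (field %in% required) {
      stop("column '", src, "' (field '", field, "') not found in ", path,
           call. = FALSE)
    }
  }
  keep_cols <- intersect(c(required, optional), names(raw))
  df <- raw[, keep_cols, drop = FALSE]

  complete <- stats::complete.cases(df[, required])
  valid <- complete &
    df$sif >= 0 & df$par >= 0 & df$nirv >= 0 &
    df$fpar > 0 & df$fpar <= 1
  valid[is.na(valid)] <- FALSE
  n_dropped <- sum(!valid)
  if (n_dropped > 0) {
    message("read_timeseries: dropped ", n_dropped,
            " row(s) with missing or invalid required fields")
  }
  df <- df[valid, , drop = FALSE]
  if (nrow(df) == 0) {
    stop("no valid rows remain after filtering ", path, call. = FALSE)
  }
  out <- trait_series(df, label = label %||% basename(path))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a retrieval series to CSV
#'
#' Writes one row per timestamp with columns
#' `year,doy,epsilon,ql,etr,vcmax,gs` at full double precision, so the
#' file round-trips through [read_retrieval()] without loss (better than
#' 10 significant digits). A `retrieval_series` with the gs stage
#' disabled writes an empty `gs` column.
#'
#' @param path Destination file path.
#' @param series A `retrieval_series` from [retrieve_series()], or a data
#'   frame with the columns above.
#' @return Invisibly, the path written.
#' @export
write_retrieval <- function(path, series) {
  cols <- c("year", "doy", "epsilon", "ql", "etr", "vcmax", "gs")
  df <- as.data.frame(series)[, intersect(cols, names(as.data.frame(series))),
                              drop = FALSE]
  for (col in setdiff(cols, names(df))) df[[col]] <- rep(NA_real_, nrow(df))
  df <- df[, cols, drop = FALSE]
  out <- df
  for (col in cols) {
    out[[col]] <- ifelse(is.na(df[[col]]), "",
                         formatC(df[[col]], digits = 17, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a retrieval series from CSV
#'
#' Inverse of [write_retrieval()].
#'
#' @param path Path to a retrieval CSV.
#' @return A data frame with columns `year,doy,epsilon,ql,etr,vcmax,gs`.
#' @export
read_retrieval <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("year", "doy", "epsilon", "ql", "etr", "vcmax", "gs")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop("retrieval CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in cols) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df
}

#' Load a configuration file
#'
#' Reads a flat key-value configuration (YAML syntax: `key: value`, one
#' per line) into a [photo_params()] object plus, when `ql_a`/`ql_b` are
#' given, a [ql_model()]. Keys not present fall back to the documented
#' defaults; out-of-range values are rejected.
#'
#' Recognised keys: `phi_psii_max`, `k_df`, `ci`, `ca`, `gamma_star`,
#' `km`, `diffusivity_ratio`, `sif_scale`, `ql_a`, `ql_b`.
#'
#' @param path Path to the config file, or `NULL` for all defaults.
#' @return A list with elements `params` (`photo_params`) and `ql`
#'   (`ql_model` or `NULL` when `ql_a`/`ql_b` are not configured).
#' @examples
#' cfg <- load_config(NULL)       # all defaults
#' cfg$params$k_df                # 19
#' @export
load_config <- function(path = NULL) {
  values <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    values <- yaml::read_yaml(path)
    if (is.null(values)) values <- list()
    if (!is.list(values)) {
      stop("config must be flat key: value text", call. = FALSE)
    }
  }
  param_keys <- c("phi_psii_max", "k_df", "ci", "ca", "gamma_star", "km",
                  "diffusivity_ratio", "sif_scale")
  known <- c(param_keys, "ql_a", "ql_b")
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0) {
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  args <- values[intersect(names(values), param_keys)]
  args <- lapply(args, as.numeric)
  params <- do.call(photo_params, args)

  ql <- NULL
  if (!is.null(values$ql_a) || !is.null(values$ql_b)) {
    if (is.null(values$ql_a) || is.null(values$ql_b)) {
      stop("config must give both ql_a and ql_b or neither", call. = FALSE)
    }
    ql <- ql_model(a = as.numeric(values$ql_a), b = as.numeric(values$ql_b))
  }
  list(params = params, ql = ql)
}

#' Write a configuration file
#'
#' Serialises a [photo_params()] object and optionally a fitted
#' [ql_model()] to the flat key-value format read by [load_config()], so
#' a fitted qL model can be reused across retrieval runs.
#'
#' @param path Destination path.
#' @param params A `photo_params` object.
#' @param ql Optional `ql_model`; writes keys `ql_a`, `ql_b`.
#' @return Invisibly, the path written.
#' @export
write_config <- function(path, params = photo_params(), ql = NULL) {
  validate_photo_params(params)
  values <- unclass(params)
  if (!is.null(ql)) {
    values$ql_a <- ql$a
    values$ql_b <- ql$b
  }
  yaml::write_yaml(values, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
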