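# Shared fixtures: small in-code series and CSV writers.

make_series_df <- function(n = 10, year = 2017) {
  doy <- 180 + seq_len(n) - 1
  data.frame(year = year, doy = doy,
             sif = 0.8 + 0.05 * seq_len(n),
             par = 400 + 10 * seq_len(n),
             nirv = 0.30, fpar = 0.90)
}

write_series_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

default_ql <- function() ql_model(a = 0.9, b = -0.001)

# photo params used in the worked hand-arithmetic examples
params_gamma43 <- function() photo_params(gamma_star = 43)
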