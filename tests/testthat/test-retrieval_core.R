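test_that("escape_ratio is NIRv/FPAR with validated inputs", {
  expect_equal(escape_ratio(0.3, 0.9), 1 / 3)
  expect_equal(round(escape_ratio(0.3, 0.9), 6), 0.333333)
  expect_equal(escape_ratio(0, 0.5), 0)
  expect_equal(escape_ratio(0.5, 0.5), 1)
  expect_error(escape_ratio(0.3, 0), "> 0")
  expect_error(escape_ratio(-0.1, 0.5), ">= 0")
})

test_that("SIF-ETR mechanism matches hand arithmetic at the defaults", {
  p <- photo_params()
  # scaling constant 0.83 * 20 / 0.17
  etr <- etr_from_sif(1.0, par = 0, epsilon = 1 / 3,
                      ql_model = ql_model(0.3, 0), p = p)
  expect_equal(etr, 0.3 * (0.83 * 20 / 0.17) / (1 / 3) * 1.0,
               tolerance = 1e-12)
  expect_equal(round(etr, 6), 87.882353)

  # linearity in SIF
  expect_equal(etr_from_sif(0, 0, 1 / 3, ql_model(0.3, 0), p), 0)
  expect_equal(etr_from_sif(2, 0, 1 / 3, ql_model(0.3, 0), p), 2 * etr / 1,
               tolerance = 1e-12)
  # sif_scale enters multiplicatively
  p2 <- photo_params(sif_scale = 0.5)
  expect_equal(etr_from_sif(1, 0, 1 / 3, ql_model(0.3, 0), p2), etr / 2,
               tolerance = 1e-12)

  expect_error(etr_from_sif(1, 0, 0, ql_model(0.3, 0), p), "epsilon")
  expect_error(etr_from_sif(-1, 0, 1, ql_model(0.3, 0), p), "sif")
})

test_that("CO2 factors m and mc match closed forms and limits", {
  p <- params_gamma43()                       # ci = 280, gamma* = 43, km = 711
  expect_equal(m_factor(p), 237 / 366)
  expect_equal(round(m_factor(p), 6), 0.647541)
  expect_equal(mc_factor(p), 237 / 991)
  expect_equal(round(mc_factor(p), 6), 0.239152)

  # ci just above the compensation point: both factors vanish
  p_low <- photo_params(ci = 43.001, gamma_star = 43)
  expect_lt(m_factor(p_low), 1e-4)
  expect_lt(mc_factor(p_low), 1e-4)

  # saturating ci: m approaches 1
  p_high <- photo_params(ci = 1e7, ca = 2e7, gamma_star = 43)
  expect_equal(m_factor(p_high), 1, tolerance = 1e-4)

  # km = 2 gamma* collapses mc onto m
  p_eq <- photo_params(km = 2 * 42.75)
  expect_equal(mc_factor(p_eq), m_factor(p_eq))

  expect_true(m_factor(p) > 0 && m_factor(p) < 1)
  expect_true(mc_factor(p) > 0 && mc_factor(p) < 1)
})

test_that("Vcmax from ETR solves the co-limitation balance", {
  p <- params_gamma43()
  v <- vcmax_from_etr(87.882353, p)
  expect_equal(v, 87.882353 * (237 / 366) / (4 * 237 / 991),
               tolerance = 1e-12)
  expect_equal(round(v, 3), 59.489)
  expect_equal(vcmax_from_etr(0, p), 0)
  # linear in ETR
  etr <- c(10, 20, 40)
  expect_equal(vcmax_from_etr(etr, p), etr * vcmax_from_etr(1, p),
               tolerance = 1e-12)
  # m/mc > 1 when km > 2 gamma*, so Vcmax > ETR/4
  expect_gt(vcmax_from_etr(100, p), 25)
})

test_that("gs from ETR follows electron-use efficiency plus Fick's law", {
  p <- params_gamma43()
  g <- gs_from_etr(87.882353, p)
  expect_equal(g, 0.4 * (237 / 366) * 87.882353 / 120, tolerance = 1e-12)
  expect_equal(round(g, 6), 0.189691)
  expect_equal(gs_from_etr(0, p), 0)

  # implied assimilation A = gs (Ca - Ci) / 1.6 equals (ETR/4) m exactly
  etr <- c(30, 90, 150)
  A_fick <- gs_from_etr(etr, p) * (p$ca - p$ci) / p$diffusivity_ratio
  expect_equal(A_fick, etr / 4 * m_factor(p), tolerance = 1e-12)

  expect_error(photo_params(ca = 280, ci = 280), "ca must exceed ci")
})

test_that("retrieve_series composes the chain per record", {
  ts <- trait_series(data.frame(year = 2017, doy = 200, sif = 1.0,
                                par = 500, nirv = 0.3, fpar = 0.9))
  rs <- retrieve_series(ts, ql_model(0.3, 0), params_gamma43())
  expect_equal(round(rs$epsilon, 6), 0.333333)
  expect_equal(rs$ql, 0.3)
  expect_equal(round(rs$etr, 6), 87.882353)
  expect_equal(round(rs$vcmax, 3), 59.489)
  expect_equal(round(rs$gs, 6), 0.189691)
  expect_s3_class(rs, "retrieval_series")
  expect_equal(attr(rs, "params_used")$gamma_star, 43)
})

test_that("degenerate records are skipped with accounting", {
  df <- make_series_df(10)
  df$nirv[4] <- 0                      # epsilon = 0: not retrievable
  ts <- trait_series(df)
  expect_message(rs <- retrieve_series(ts, default_ql()), "skipped 1")
  expect_equal(nrow(rs), 9)
  expect_equal(attr(rs, "n_skipped"), 1)
  expect_false(df$doy[4] %in% rs$doy)

  df_all <- make_series_df(3)
  df_all$nirv <- 0
  expect_error(suppressMessages(
    retrieve_series(trait_series(df_all), default_ql())),
    "all records skipped")
})

test_that("retrieved traits are homogeneous of degree 1 in SIF", {
  df <- make_series_df(8)
  ts1 <- trait_series(df)
  df2 <- df; df2$sif <- 3 * df2$sif
  ts2 <- trait_series(df2)
  r1 <- retrieve_series(ts1, default_ql())
  r2 <- retrieve_series(ts2, default_ql())
  expect_equal(r2$etr, 3 * r1$etr, tolerance = 1e-12)
  expect_equal(r2$vcmax, 3 * r1$vcmax, tolerance = 1e-12)
  expect_equal(r2$gs, 3 * r1$gs, tolerance = 1e-12)
})

test_that("finite-difference elasticities of ETR match the closed forms", {
  p <- photo_params()
  etr_at <- function(pp) etr_from_sif(1, 0, 1 / 3, ql_model(0.3, 0), pp)
  h <- 1e-6
  fd <- function(name) {
    up <- perturb(p, name, h); dn <- perturb(p, name, -h)
    (log(etr_at(up)) - log(etr_at(dn))) / (log(1 + h) - log(1 - h))
  }
  expect_equal(fd("phi_psii_max"), 1 / (1 - 0.83), tolerance = 1e-4)
  expect_equal(fd("k_df"), 19 / 20, tolerance = 1e-4)
})
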