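test_that("perturb scales a single field and guards the invariants", {
  p <- photo_params()
  expect_equal(perturb(p, "phi_psii_max", 0.10)$phi_psii_max, 0.913)
  expect_equal(perturb(p, "k_df", -0.10)$k_df, 17.1)
  expect_equal(perturb(p, "k_df", 0.10)$phi_psii_max, 0.83)  # untouched

  expect_error(perturb(photo_params(phi_psii_max = 0.95),
                       "phi_psii_max", 0.10), "invariants")
  expect_error(perturb(p, "not_a_param", 0.1), "unknown parameter")
})

test_that("analytic elasticities match closed forms and limits", {
  e <- analytic_elasticities(photo_params())
  expect_equal(unname(e["e_phi"]), 5.882353, tolerance = 1e-6)
  expect_equal(unname(e["e_kdf"]), 0.95)

  # phi -> 0: elasticity tends to 1; kdf -> inf: tends to 1
  expect_equal(unname(analytic_elasticities(
    photo_params(phi_psii_max = 1e-6))["e_phi"]), 1, tolerance = 1e-5)
  expect_equal(unname(analytic_elasticities(
    photo_params(k_df = 1e8))["e_kdf"]), 1, tolerance = 1e-7)
})

test_that("perturbations act as exact global multiplicative factors", {
  ts <- trait_series(make_series_df(12))
  report <- sensitivity_analysis(ts, default_ql(), photo_params())
  expect_s3_class(report, "sensitivity_report")
  expect_equal(nrow(report), 4)

  deltas <- attr(report, "series_delta")
  # the factor is uniform across timestamps and identical for both traits
  for (param in c("phi_psii_max", "k_df")) {
    for (sgn in c(0.10, -0.10)) {
      d <- deltas[deltas$parameter == param & deltas$perturbation == sgn, ]
      expect_equal(max(d$rel_change_vcmax) - min(d$rel_change_vcmax), 0,
                   tolerance = 1e-12)
      expect_equal(d$rel_change_vcmax, d$rel_change_gs, tolerance = 1e-12)
    }
  }

  # closed forms: ETR is proportional to (1 + kdf) and to phi/(1 - phi)
  kdf_up <- deltas[deltas$parameter == "k_df" & deltas$perturbation == 0.10, ]
  expect_equal(unique(round(kdf_up$rel_change_vcmax + 1, 12)), 21.9 / 20)

  phi_up <- deltas[deltas$parameter == "phi_psii_max" &
                     deltas$perturbation == 0.10, ]
  expect_equal(mean(phi_up$rel_change_vcmax) + 1,
               (0.913 * 0.17) / (0.83 * 0.087), tolerance = 1e-12)
})

test_that("the retrieval responds more to phi_psii_max than to k_df", {
  ts <- trait_series(make_series_df(12))
  report <- sensitivity_analysis(ts, default_ql(), photo_params())
  mean_abs <- function(param) {
    mean(report$mean_abs_rel_change_vcmax[report$parameter == param])
  }
  expect_gt(mean_abs("phi_psii_max"), mean_abs("k_df"))
  # same ordering for gs
  mean_abs_gs <- function(param) {
    mean(report$mean_abs_rel_change_gs[report$parameter == param])
  }
  expect_gt(mean_abs_gs("phi_psii_max"), mean_abs_gs("k_df"))
})

test_that("finite differences bracket and converge to the elasticity", {
  p <- photo_params()
  etr_at <- function(pp) etr_from_sif(1, 0, 0.5, ql_model(0.3, 0), pp)
  elast_fd <- function(name, h) {
    (log(etr_at(perturb(p, name, h))) - log(etr_at(perturb(p, name, -h)))) /
      (log(1 + h) - log(1 - h))
  }
  e <- analytic_elasticities(p)
  # at +/-10% the secant brackets the point elasticity
  expect_gt(elast_fd("phi_psii_max", 0.10), unname(e["e_phi"]))
  # tiny perturbation converges
  expect_equal(elast_fd("phi_psii_max", 1e-6), unname(e["e_phi"]),
               tolerance = 1e-4)
  expect_equal(elast_fd("k_df", 1e-6), unname(e["e_kdf"]),
               tolerance = 1e-4)
})
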