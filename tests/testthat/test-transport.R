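buffer <- hydro_environment() # AUC buffer defaults
m336 <- molecular_spec(207.576)
m672 <- molecular_spec(415.152)

test_that("Stokes-Einstein conversion and its inverse are exact", {
  expect_equal(diffusion_from_rh(129.9, buffer), 16.1, tolerance = 1e-3)
  expect_equal(diffusion_from_rh(2 * 129.9, buffer),
               diffusion_from_rh(129.9, buffer) / 2)
  for (Rh in c(50, 129.9, 300)) {
    expect_equal(rh_from_diffusion(diffusion_from_rh(Rh, buffer), buffer), Rh,
                 tolerance = 1e-12)
  }
})

test_that("the Svedberg relation reproduces the published predictions", {
  expect_equal(svedberg_s(17.2, m336, buffer), 7.5, tolerance = 0.01)
  expect_equal(svedberg_s(12.4, m672, buffer), 10.9, tolerance = 0.01)
  ## neutral buoyancy is rejected
  heavy <- molecular_spec(207.576, psv_ml_g = 1 / buffer$rho)
  expect_error(svedberg_s(17.2, heavy, buffer), "buoyant|floats")
})

test_that("apparent PSV inverts the Svedberg relation", {
  expect_equal(apparent_psv(7.25, 16.1, m336, buffer), 0.468,
               tolerance = 1e-3)
  ## algebraic round trip
  for (v in c(0.45, 0.482, 0.55)) {
    sp <- molecular_spec(207.576, psv_ml_g = v)
    s <- svedberg_s(16.1, sp, buffer)
    expect_equal(apparent_psv(s, 16.1, sp, buffer), v, tolerance = 1e-12)
  }
  expect_warning(apparent_psv(100, 1, m336, buffer), "non-physical")
})

test_that("per-sample apparent PSV averages to the study value", {
  tab <- minicircle_auc_table()
  expect_equal(round(mean(tab$psv), 3), 0.482)
})

test_that("frictional ratio compares to the equal-volume sphere", {
  sp <- molecular_spec(207.576, psv_ml_g = 0.482)
  R0 <- 129.9 / frictional_ratio(129.9, sp)
  expect_equal(R0, 34.1, tolerance = 0.05)
  expect_equal(frictional_ratio(129.9, sp), 3.81, tolerance = 0.01)
  expect_equal(frictional_ratio(R0, sp), 1.0, tolerance = 1e-9)
  expect_gt(frictional_ratio(140, sp), frictional_ratio(130, sp))
})

test_that("standard-condition corrections are exact and reduce to identity", {
  water20 <- hydro_environment(1.0016, 293.15, 0.99823)
  id <- standard_conditions(7.25, 16.1, water20, vbar = 0.482)
  expect_equal(id$s_20w, 7.25)
  expect_equal(id$D_20w, 16.1)
  ## doubling viscosity at equal densities doubles both
  thick <- hydro_environment(2 * 1.0016, 293.15, 0.99823)
  sc <- standard_conditions(7.25, 16.1, thick, vbar = 0.482)
  expect_equal(sc$s_20w, 2 * 7.25)
  expect_equal(sc$D_20w, 2 * 16.1)
  ## the AUC buffer correction for D
  expect_equal(standard_conditions(7.25, 16.1, buffer, 0.482)$D_20w,
               16.1 * 1.02667 / 1.0016, tolerance = 1e-9)
  expect_equal(standard_conditions(7.25, 16.1, buffer, 0.482)$D_20w, 16.5,
               tolerance = 1e-2)
})

test_that("transport_predict bundles a consistent record", {
  tr <- transport_predict(128, m336, buffer)
  expect_equal(tr$s, svedberg_s(tr$D, m336, buffer))
  expect_gt(tr$f_over_f0, 1)
})
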