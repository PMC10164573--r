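test_that("Debye length follows the ionic-strength estimate", {
  expect_equal(debye_length(electrostatic_params(0.23)), 6.34,
               tolerance = 1e-3)
  expect_equal(debye_length(electrostatic_params(1 / 0.329^2)), 1.0)
  expect_equal(debye_length(electrostatic_params(0.1)), 9.61,
               tolerance = 1e-3)
  expect_error(electrostatic_params(0), "positive")
  expect_error(electrostatic_params(-0.1), "positive")
})

test_that("electrostatic persistence length adds to the intrinsic part", {
  pl <- persistence_length(electrostatic_params(0.23))
  expect_equal(pl$P_el, pl$R_D^2 / (4 * 7.1))
  expect_equal(pl$P_el, 1.42, tolerance = 0.02)
  expect_equal(pl$P_total, 500 + pl$P_el)
  ## vanishing screening length: purely intrinsic stiffness
  pl0 <- persistence_length(electrostatic_params(1e8))
  expect_lt(pl0$P_el, 1e-3)
})

test_that("loop energy scales reproduce the published worked example", {
  es <- loop_energy_scales(2, 336, 150)
  expect_equal(es$E_bend, 4 * pi^2 * 150 / 336)
  expect_equal(es$E_twist, 6 * pi^2 * 4 * 150 / 336)
  expect_equal(es$E_bend, 17, tolerance = 0.05)   # literature value ~17 kT
  expect_equal(es$E_twist, 105, tolerance = 0.05) # literature value ~105 kT
  expect_equal(loop_energy_scales(0, 336, 150)$E_twist, 0)
  ## 1/L scaling
  expect_equal(loop_energy_scales(2, 672, 150)$E_bend, es$E_bend / 2)
  expect_equal(loop_energy_scales(2, 672, 150)$E_bend, 8.8, tolerance = 0.02)
  ## exact quadratic scaling in dLk
  expect_equal(loop_energy_scales(4, 336, 150)$E_twist, 4 * es$E_twist)
})

test_that("the stiff-beam premise holds for study-size loops", {
  ## stored bending energy far exceeds kB T throughout the study regime
  for (L in c(336, 500, 672)) {
    expect_gt(loop_energy_scales(1, L, 150)$E_bend, 5)
  }
  expect_gt(loop_energy_scales(1, 500, 150)$E_bend, 10)
})

test_that("long-range screened repulsion is negligible and monotone", {
  par <- electrostatic_params(0.23, n_charges_N = 672)
  L336 <- 336 * 3.4
  expect_lt(long_range_electrostatic_energy(par, L336), 1e-10)
  ## unscreened limit
  par0 <- electrostatic_params(1e-12, n_charges_N = 672)
  expect_equal(long_range_electrostatic_energy(par0, L336),
               672 * 7.1 / (2 * L336), tolerance = 1e-3)
  ## decreasing in L and in ionic strength
  expect_lt(long_range_electrostatic_energy(par, 2 * L336),
            long_range_electrostatic_energy(par, L336))
  expect_lt(long_range_electrostatic_energy(electrostatic_params(0.4,
              n_charges_N = 672), L336),
            long_range_electrostatic_energy(electrostatic_params(0.2,
              n_charges_N = 672), L336))
  expect_error(long_range_electrostatic_energy(electrostatic_params(0.2), 100),
               "n_charges_N")
})

test_that("the summary table is internally consistent", {
  tab <- electrostatic_estimates(0.23, 336, 2)
  expect_equal(tab$E_bend, loop_energy_scales(2, 336, 150)$E_bend)
  expect_equal(tab$R_D, debye_length(electrostatic_params(0.23)))
  expect_true(all(unlist(tab) > 0))
})
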