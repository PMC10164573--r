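env <- hydro_environment()

test_that("torus closed forms evaluate and scale correctly", {
  expect_equal(torus_rh_exact(1142.4, 29.4), 128.0, tolerance = 1e-3)
  expect_equal(torus_rh_slender(1142.4, 29.4), 125.4, tolerance = 1e-3)
  expect_equal(torus_rh_slender(2284.8, 29.4), 220.1, tolerance = 1e-3)
  ## dimensional homogeneity
  expect_equal(torus_rh_exact(3 * 1142.4, 3 * 29.4),
               3 * torus_rh_exact(1142.4, 29.4))
  ## slender limit: R_h/L decays with slenderness
  r1 <- torus_rh_exact(100 * 29.4, 29.4) / (100 * 29.4)
  r2 <- torus_rh_exact(1000 * 29.4, 29.4) / (1000 * 29.4)
  expect_lt(r2, r1)
  expect_error(torus_rh_exact(50, 29.4), "overlap")
  expect_warning(torus_rh_slender(20 * 29.4, 29.4), "accuracy")
  ## log growth: doubling L less than doubles R_h
  expect_lt(torus_rh_slender(2284.8, 29.4), 2 * torus_rh_slender(1142.4, 29.4))
})

test_that("the exact and slender torus forms agree for slender tori", {
  for (ratio in c(35, 50, 77, 100)) {
    L <- ratio * 29.4
    expect_equal(torus_rh_slender(L, 29.4), torus_rh_exact(L, 29.4),
                 tolerance = 0.025)
  }
})

test_that("axisymmetric mobility averaging reduces to known cases", {
  R <- 100 # Angstrom
  mu <- 1 / (6 * pi * env$eta * R * 1e-10)
  expect_equal(rh_from_axisymmetric_mobilities(mu, mu, env), R,
               tolerance = 1e-9)
  ## mu_x = 2 mu_z: harmonic combination gives (3/5) of the mu_z radius
  expect_equal(rh_from_axisymmetric_mobilities(2 * mu, mu, env), 0.6 * R,
               tolerance = 1e-9)
  ## R_h always lies between the two single-axis equivalent radii
  rh <- rh_from_axisymmetric_mobilities(1.7 * mu, mu, env)
  expect_true(rh > R / 1.7 && rh < R)
  expect_error(rh_from_axisymmetric_mobilities(-mu, mu, env), "positive")
})

test_that("bead models are equally spaced and length preserving", {
  L <- 1142.4
  bm <- build_bead_model(build_circle(L), 29.4, 400)
  spacings <- sqrt(rowSums((bm$centers[c(2:400, 1), ] - bm$centers)^2))
  expect_equal(mean(spacings), L / 400, tolerance = 1e-4)
  expect_lt(max(spacings), 29.4) # consecutive beads overlap
  expect_equal(sum(spacings), L, tolerance = 0.005) # within 0.5 %
  ## all centers on the circle radius
  r <- sqrt(rowSums(sweep(bm$centers, 2, colMeans(bm$centers))^2))
  expect_equal(max(abs(r - L / (2 * pi))), 0, tolerance = 1e-6)
  expect_error(build_bead_model(build_circle(L), 29.4, 10), "overlap")
})

test_that("the sphere limit is exact for both mobility engines", {
  one <- build_bead_model(generate_fixture("straight_rod", 1), 20, 1)
  expect_equal(bead_model_rh(one, env)$Rh, 10)
  expect_equal(bead_model_rh(one, env, method = "montecarlo",
                             n_walks = 2000, seed = 1)$Rh, 10,
               tolerance = 0.05)
})

test_that("a touching dumbbell matches the two-sphere benchmark", {
  a <- 10
  dumb <- structure(list(centers = rbind(c(0, 0, 0), c(2 * a, 0, 0)),
                         dh = 2 * a, n_beads = 2L, closed = FALSE),
                    class = "bead_model")
  ## exact two-sphere value: R_h = 1.3799 a
  wos <- bead_model_rh(dumb, env, method = "montecarlo",
                       n_walks = 40000, seed = 2)
  expect_equal(wos$Rh / a, 1.3799, tolerance = 0.03)
  ## the pairwise RPY truncation is good to the stated 5 % model error
  pw <- bead_model_rh(dumb, env)
  expect_equal(pw$Rh / a, 1.3799, tolerance = 0.05)
  ## origin invariance of the rigid-body solve
  shifted <- dumb
  shifted$centers <- dumb$centers + 750
  expect_equal(bead_model_rh(shifted, env)$Rh, pw$Rh, tolerance = 1e-9)
})

test_that("the 400-bead ring reproduces the torus closed form", {
  L <- 1142.4; dh <- 29.4
  target <- torus_rh_exact(L, dh)
  bm <- build_bead_model(build_circle(L), dh, 400)
  expect_equal(bead_model_rh(bm, env)$Rh, target, tolerance = 0.05)
  mc <- bead_model_rh(bm, env, method = "montecarlo", n_walks = 30000,
                      seed = 1)
  expect_equal(mc$Rh, target, tolerance = 0.05)
  expect_gt(mc$stderr, 0)
})

test_that("bead-count refinement is converged at 400 beads", {
  L <- 1142.4; dh <- 29.4
  bm4 <- build_bead_model(build_circle(L), dh, 400)
  bm8 <- build_bead_model(build_circle(L), dh, 800)
  r4 <- bead_model_rh(bm4, env)$Rh
  r8 <- bead_model_rh(bm8, env)$Rh
  expect_lt(abs(r4 - r8) / r4, 0.01)
})

test_that("R_h grows with thickness and with length", {
  L <- 1142.4
  circ <- build_circle(L)
  r_thin <- bead_model_rh(build_bead_model(circ, 20, 400), env)$Rh
  r_thick <- bead_model_rh(build_bead_model(circ, 29.4, 400), env)$Rh
  expect_gt(r_thick, r_thin)
  r_long <- bead_model_rh(build_bead_model(build_circle(2 * L), 29.4, 400),
                          env)$Rh
  expect_gt(r_long, r_thick)
})

test_that("a linear chain is hydrodynamically larger than the circle", {
  L <- 1142.4; dh <- 29.4
  rod <- build_bead_model(generate_fixture("straight_rod", L), dh, 400)
  circ <- build_bead_model(build_circle(L), dh, 400)
  ratio <- bead_model_rh(rod, env)$Rh / bead_model_rh(circ, env)$Rh
  expect_gt(ratio, 1)
  expect_equal(ratio, 7 / 6, tolerance = 0.08) # about 7:6
})

test_that("thickness calibration recovers a known diameter", {
  lengths <- c(29.4 / 0.026, 29.4 / 0.013)
  truth <- 25
  rh_true <- torus_rh_exact(lengths, truth)
  set.seed(11)
  noisy <- rh_true * (1 + rnorm(2, sd = 0.01))
  fit <- calibrate_dh(data.frame(length = lengths, Rh = noisy))
  expect_lt(abs(fit$dh - truth), 1)
  ## single exact point: zero residual
  fit1 <- calibrate_dh(data.frame(length = lengths[1], Rh = rh_true[1]))
  expect_equal(fit1$dh, truth, tolerance = 1e-6)
  expect_lt(abs(fit1$residuals$residual), 1e-8)
  expect_error(calibrate_dh(data.frame(length = numeric(), Rh = numeric())),
               "no measurements")
  ## radii far outside the torus model force a boundary fit whose residuals
  ## cannot bracket the data
  expect_warning(
    calibrate_dh(data.frame(length = lengths, Rh = lengths / 1.5)),
    "bracket")
  expect_equal(nrow(tidy(fit)), 2)
  expect_equal(glance(fit)$dh, fit$dh)
})

test_that("open-circle deficits leave the hydrodynamic radius unchanged", {
  p <- params_336()
  out <- predict_rh_for_dlk(0, p, dh = 29.4, config = test_config(),
                            env = env, n_beads = 150)
  expect_equal(out$Rh_rel, 1.0, tolerance = 1e-9)
  expect_equal(out$regime, "circle_only")
})
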