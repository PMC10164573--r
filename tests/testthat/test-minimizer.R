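# Shared reduced-cost minimizations used by several tests below.
p336 <- params_336()
shape_32 <- minimize_shape(-3.2, p336, test_config(seed = 1))
shape_22 <- minimize_shape(-2.2, p336, test_config(seed = 1))

test_that("a relaxed loop stays an open circle", {
  sh <- minimize_shape(0, p336, test_config())
  expect_equal(sh$regime, "circle_only")
  expect_equal(sh$writhe, 0)
  expect_equal(sh$energy_total, 2 * pi^2 * p336$P / p336$L, tolerance = 1e-9)
  expect_equal(sh$n_contacts, 0L)
  expect_true(sh$converged)

  ## small deficits below Lk_crit: circle with residual twist only
  sh2 <- minimize_shape(-0.2, p336, test_config())
  expect_equal(sh2$regime, "circle_only")
  expect_lt(abs(sh2$writhe), 0.05)
  expect_equal(sh2$energy_twist,
               2 * pi^2 * p336$omega * p336$P * 0.04 / p336$L,
               tolerance = 1e-9)
})

test_that("strong underwinding yields a writhed, sterically valid shape", {
  expect_equal(shape_32$regime, "writhed_only")
  expect_gt(abs(shape_32$writhe), 1.2)
  expect_lt(shape_32$writhe, 0) # negative supercoiling, negative writhe
  ## global minimum undercuts the flat circle at the same deficit
  circleE <- 2 * pi^2 * p336$P / p336$L * (1 + p336$omega * 3.2^2)
  expect_lt(shape_32$energy_total, circleE)
  ## steric constraint holds to tolerance
  expect_gte(shape_32$min_distance, p336$ds - 0.1)
  ## self-contact present
  expect_gte(shape_32$n_contacts, 1L)
  expect_true(shape_32$contact_type %in% c("point", "line"))
})

test_that("the energy landscape branches are tabulated", {
  br <- tidy(shape_32)
  expect_true("flat_circle_analytic" %in% br$start)
  expect_true(all(c("energy_bend", "energy_twist", "writhe") %in% names(br)))
  g <- glance(shape_32)
  expect_equal(g$energy_total, g$energy_bend + g$energy_twist)
})

test_that("minimization is reproducible for a fixed seed", {
  a <- minimize_shape(-2.2, p336, test_config(seed = 7))
  b <- minimize_shape(-2.2, p336, test_config(seed = 7))
  expect_identical(a$energy_total, b$energy_total)
  expect_identical(a$curve$control_points, b$curve$control_points)
})

test_that("energies agree across seeds within the optimization noise", {
  energies <- vapply(1:3, function(s) {
    minimize_shape(-2.6, p336, test_config(seed = s))$energy_total
  }, numeric(1))
  expect_lt(diff(range(energies)) / mean(energies), 0.02)
})

test_that("tighter supercoiling bends the loop more sharply", {
  rad_min <- function(sh) 1 / max(curvature_profile(sh$curve, 200)$kappa)
  r_circle <- p336$L / (2 * pi)
  expect_lt(rad_min(shape_22), r_circle)
  expect_lt(rad_min(shape_32), rad_min(shape_22))
})

test_that("writhe tables switch on at the critical deficit", {
  cfg <- test_config()
  tab <- writhe_vs_dlk_curve(p336, c(0, -0.5, -1.0, -2.2), cfg)
  below <- abs(tab$dLk) < lk_crit_empirical(p336$ds / p336$L)
  expect_true(all(tab$writhe[below] == 0))
  expect_true(all(abs(tab$writhe[!below]) > 0.5))
  expect_true(all(tab$energy_total <=
                    2 * pi^2 * p336$P / p336$L *
                      (1 + p336$omega * tab$dLk^2) + 1e-6))
  expect_s3_class(autoplot(tab), "ggplot")
})

test_that("the curvature profile of a writhed shape is inhomogeneous", {
  prof <- curvature_profile(shape_32$curve, 200)
  expect_gt(max(prof$kappa) / min(prof$kappa), 1.5)
  expect_s3_class(autoplot(shape_32), "ggplot")
})
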