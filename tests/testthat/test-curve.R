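test_that("circles have the exact radius, curvature and arclength", {
  circ <- build_circle(2 * pi, 16)
  s <- minicircle:::curve_samples(circ, 64)
  expect_lt(max(abs(s$kappa - 1)), 1e-6)
  expect_equal(arclength(circ), 2 * pi, tolerance = 1e-9)

  circ2 <- build_circle(1142.4)
  r <- sqrt(rowSums(curve_eval(circ2, seq(0, 1, 0.05))^2))
  expect_equal(max(abs(r - 1142.4 / (2 * pi))), 0, tolerance = 1e-6)
  expect_equal(1142.4 / (2 * pi), 181.8, tolerance = 1e-3)
})

test_that("degenerate construction inputs are rejected", {
  expect_error(build_circle(-1), "positive")
  expect_error(build_circle(0), "positive")
  expect_error(build_circle(100, n_nodes = 4), "at least 8")
  cp <- matrix(rnorm(30), 10, 3)
  cp[5, ] <- cp[4, ] # coincident neighbours
  expect_error(closed_curve(cp), "coincident")
  expect_error(closed_curve(matrix(1:9, 3, 3)), "at least 4")
})

test_that("ellipse curvature extrema and circumference match closed forms", {
  a <- 2; b <- 1
  f <- function(t, deriv = 0L) {
    ang <- 2 * pi * t
    switch(deriv + 1L,
      cbind(a * cos(ang), b * sin(ang), 0),
      2 * pi * cbind(-a * sin(ang), b * cos(ang), 0),
      (2 * pi)^2 * cbind(-a * cos(ang), -b * sin(ang), 0))
  }
  ell <- closed_curve(f(seq(0, 1, length.out = 33)[-33]), fun = f)
  s <- minicircle:::curve_samples(ell, 720)
  expect_equal(max(s$kappa), a / b^2, tolerance = 1e-6)
  expect_equal(min(s$kappa), b / a^2, tolerance = 1e-6)
  ## oracle: complete elliptic integral of the second kind
  perim <- 4 * a * pracma::ellipke(1 - b^2 / a^2)$e
  expect_equal(arclength(ell), perim, tolerance = 1e-6)
})

test_that("periodic spline interpolation is seamless and close to analytic", {
  circ_spline <- closed_curve(build_circle(2 * pi, 32)$control_points)
  expect_equal(curve_eval(circ_spline, 0), curve_eval(circ_spline, 1))
  expect_equal(curve_eval(circ_spline, 0, 1L), curve_eval(circ_spline, 1, 1L))
  s <- minicircle:::curve_samples(circ_spline, 128)
  expect_lt(max(abs(s$kappa - 1)), 1e-2)
  expect_equal(arclength(circ_spline), 2 * pi, tolerance = 1e-4)
})

test_that("curvature profiles are non-negative, normalized and shiftable", {
  pl <- random_loop(3)
  prof <- curvature_profile(pl, 128)
  expect_true(all(prof$kappa >= 0))
  expect_true(all(prof$position >= 0 & prof$position < 1))
  circ <- build_circle(2 * pi)
  expect_lt(max(abs(curvature_profile(circ, 64)$kappa - 1)), 1e-6)
  shifted <- curvature_profile(pl, 128, origin = 0.25)
  expect_equal(sort(shifted$kappa), sort(prof$kappa), tolerance = 1e-9)
})

test_that("rigid transforms preserve arclength; scaling multiplies it", {
  pl <- random_loop(5)
  Rz <- matrix(c(cos(1), sin(1), 0, -sin(1), cos(1), 0, 0, 0, 1), 3, 3)
  moved <- transform_curve(pl, Rz, c(10, -4, 2))
  expect_equal(arclength(moved), arclength(pl), tolerance = 1e-8)
  expect_equal(arclength(transform_curve(pl, scale = 2.5)),
               2.5 * arclength(pl), tolerance = 1e-8)
})

test_that("curve CSV and JSON round-trip exactly", {
  pl <- random_loop(7)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(pl, csv)
  back <- read_curve_csv(csv)
  expect_equal(back$control_points, pl$control_points, tolerance = 1e-12)

  js <- withr::local_tempfile(fileext = ".json")
  write_curve_json(pl, js, length_bp = 336, dLk = -3, labels = "test")
  back2 <- read_curve_json(js)
  expect_equal(back2$control_points, pl$control_points,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(attr(back2, "length_bp"), 336)
  expect_equal(attr(back2, "dLk"), -3)
})

test_that("bead exports produce well-formed PDB and XYZ files", {
  bm <- build_bead_model(build_circle(500), dh = 20, n_beads = 40)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_beads_pdb(bm, pdb)
  lines <- readLines(pdb)
  atoms <- grep("^HETATM", lines, value = TRUE)
  expect_length(atoms, 40)
  ## occupancy column records the bead diameter
  expect_equal(as.numeric(substr(atoms[1], 55, 60)), 20)

  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_beads_xyz(bm, xyz)
  expect_equal(as.integer(readLines(xyz, n = 1)), 40)
})
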