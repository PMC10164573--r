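# Independent oracles and shared reduced-cost settings for the test suite.

# Brute-force writhe: direct double Riemann sum of the Gauss integral over
# the smooth curve (tangents from the analytic/spline parameterization),
# skipping near-diagonal pairs. Independent of the segment-pair closed form
# used by writhe().
gauss_writhe <- function(curve, n = 800L) {
  t <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
  r <- curve_eval(curve, t, 0L)
  r1 <- curve_eval(curve, t, 1L)
  dt <- 1 / n
  idx <- seq_len(n)
  tot <- 0
  for (i in idx) {
    rij <- cbind(r[i, 1] - r[, 1], r[i, 2] - r[, 2], r[i, 3] - r[, 3])
    d3 <- (rowSums(rij^2))^1.5
    ti <- r1[i, ]
    cr <- cbind(ti[2] * r1[, 3] - ti[3] * r1[, 2],
                ti[3] * r1[, 1] - ti[1] * r1[, 3],
                ti[1] * r1[, 2] - ti[2] * r1[, 1])
    integrand <- rowSums(cr * rij) / d3
    gap <- pmin(abs(idx - i), n - abs(idx - i))
    integrand[gap < 2L] <- 0
    tot <- tot + sum(integrand) * dt * dt
  }
  tot / (4 * pi)
}

# Smooth random closed loop with bounded perturbation, seeded.
random_loop <- function(seed, amplitude = 0.35, n_modes = 4L) {
  generate_fixture("perturbed_loop", contour_length = 2 * pi * 100,
                   amplitude = amplitude, n_modes = n_modes, seed = seed)
}

# Reduced-resolution minimizer settings for tests: same algorithm, smaller
# discretization and step budget.
test_config <- function(seed = 1L, ...) {
  minimizer_config(n_nodes = 12L, n_writhe_segments = 100L,
                   n_energy_samples = 100L, n_steric_samples = 250L,
                   mc_steps = 500L, quench_maxit = 120L, rng_seed = seed, ...)
}

# 336 bp study geometry: contour length from the published hydrodynamic
# aspect ratio d_h/L = 2.6e-2 with d_h = 29.4 A; steric ratio d_s/L = 0.018.
params_336 <- function() {
  L <- 29.4 / 0.026
  elastic_params(L, steric_thickness_ds = 0.018 * L)
}

params_672 <- function() {
  L <- 29.4 / 0.013
  elastic_params(L, steric_thickness_ds = 0.0090 * L)
}
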