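test_that("planar curves have zero writhe", {
  expect_lt(abs(writhe(build_circle(2 * pi, 16))), 1e-6)
  ell <- random_loop(1, amplitude = 0) # circle through the fixture path
  expect_lt(abs(writhe(ell)), 1e-6)
})

test_that("the figure-8 writhe approaches one as the crossing closes", {
  L <- 2 * pi * 100
  seps <- c(60, 20, 1)
  wr <- vapply(seps, function(s) {
    writhe(generate_fixture("figure8", contour_length = L, separation = s), 300)
  }, numeric(1))
  expect_true(all(diff(abs(wr)) > 0)) # tighter crossing, larger |Wr|
  expect_gt(abs(wr[3]), 0.98)
  expect_lt(abs(wr[1]), 0.9)
})

test_that("segment-pair writhe matches the brute-force Gauss integral", {
  for (seed in 1:20) {
    amp <- 0.2 + 0.01 * seed
    pl <- random_loop(seed, amplitude = amp, n_modes = 3L + seed %% 3L)
    expect_lt(abs(writhe(pl, 300) - gauss_writhe(pl, 1200)), 1e-3)
  }
})

test_that("a random closed polygon matches brute-force quadrature", {
  set.seed(42)
  repeat { # draw until non-adjacent edges are well separated, so the
           # midpoint quadrature below is well converged
    p <- matrix(rnorm(36), 12, 3)
    n0 <- nrow(p); nxt0 <- c(2:n0, 1L)
    mids <- NULL
    for (i in seq_len(n0)) {
      u <- (seq_len(12L) - 0.5) / 12L
      mids <- rbind(mids, outer(u, p[nxt0[i], ] - p[i, ]) +
                            matrix(p[i, ], 12L, 3, byrow = TRUE))
    }
    par0 <- (seq_len(nrow(mids)) - 1L) %/% 12L
    dm <- as.matrix(dist(mids))
    gp <- abs(outer(par0, par0, "-"))
    dm[pmin(gp, n0 - gp) <= 1L] <- Inf
    if (min(dm) > 0.8) break
  }
  wr_exact <- minicircle:::polygon_writhe(p)
  ## refine each edge into sub-segments and sum the Gauss integrand; pairs on
  ## the same or on adjacent edges contribute exactly zero for straight
  ## segments (collinear / shared-vertex geometry) and are skipped
  nsub <- 60L
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  pts <- NULL; tang <- NULL; dl <- NULL
  for (i in seq_len(n)) {
    e <- p[nxt[i], ] - p[i, ]
    len <- sqrt(sum(e^2))
    u <- (seq_len(nsub) - 0.5) / nsub
    pts <- rbind(pts, outer(u, e) + matrix(p[i, ], nsub, 3, byrow = TRUE))
    tang <- rbind(tang, matrix(e / len, nsub, 3, byrow = TRUE))
    dl <- c(dl, rep(len / nsub, nsub))
  }
  N <- nrow(pts)
  parent <- (seq_len(N) - 1L) %/% nsub
  tot <- 0
  for (i in seq_len(N)) {
    rij <- cbind(pts[i, 1] - pts[, 1], pts[i, 2] - pts[, 2],
                 pts[i, 3] - pts[, 3])
    d3 <- (rowSums(rij^2))^1.5
    ti <- tang[i, ]
    cr <- cbind(ti[2] * tang[, 3] - ti[3] * tang[, 2],
                ti[3] * tang[, 1] - ti[1] * tang[, 3],
                ti[1] * tang[, 2] - ti[2] * tang[, 1])
    v <- rowSums(cr * rij) / d3
    gap <- abs(parent - parent[i])
    v[pmin(gap, n - gap) <= 1L] <- 0
    tot <- tot + sum(v * dl * dl[i])
  }
  expect_equal(wr_exact, tot / (4 * pi), tolerance = 5e-3)
})

test_that("writhe is frame-invariant, scale-invariant, and mirror-odd", {
  f8 <- generate_fixture("figure8", contour_length = 2 * pi, separation = 0.3)
  w0 <- writhe(f8, 250)
  th <- 0.8
  Ry <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  expect_equal(writhe(transform_curve(f8, Ry, c(5, 5, -2)), 250), w0,
               tolerance = 1e-9)
  expect_equal(writhe(transform_curve(f8, scale = 7), 250), w0,
               tolerance = 1e-9)
  expect_equal(writhe(transform_curve(f8, diag(c(1, 1, -1))), 250), -w0,
               tolerance = 1e-9)
})

test_that("writhe rejects open curves", {
  rod <- generate_fixture("straight_rod", contour_length = 100)
  expect_error(writhe(rod), "closed")
})
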