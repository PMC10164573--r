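#' Solvent environment for hydrodynamic calculations
#'
#' Viscosity, temperature and density of the solvent. Defaults are the AUC
#' buffer (50 mM Tris-Cl, 150 mM NaCl, 10 mM CaCl2 at 20 C): eta = 1.02667
#' cP, rho = 1.00682 g/ml, T = 293.15 K.
#'
#' @param viscosity_cP dynamic viscosity in centipoise.
#' @param temperature_K absolute temperature in kelvin.
#' @param density_g_ml solvent density in g/ml.
#' @return an object of class `hydro_environment`.
#' @export
hydro_environment <- function(viscosity_cP = 1.02667,
                              temperature_K = 293.15,
                              density_g_ml = 1.00682) {
  stopifnot(viscosity_cP > 0, temperature_K > 0, density_g_ml > 0)
  structure(list(eta_cP = viscosity_cP, eta = cP_to_Pas(viscosity_cP),
                 T = temperature_K, rho = density_g_ml),
            class = "hydro_environment")
}

#' @export
print.hydro_environment <- function(x, ...) {
  cat(sprintf("<hydro_environment: eta = %.5f cP, T = %.2f K, rho = %.5f g/ml>\n",
              x$eta_cP, x$T, x$rho))
  invisible(x)
}

#' Hydrodynamic radius of a torus (closed form)
#'
#' Orientation-averaged hydrodynamic radius of a rigid torus of centerline
#' length `L` and tube diameter `dh`:
#' `R_h = (L/2pi + dh/2) * 72 pi (1/(16 x^2) + 1) x / (25 x + 6 (11 x + 8) log(8 x) + 16)`
#' with `x = L / (pi dh)` (natural log). Accurate for non-slender tori;
#' agrees with the slender-torus fit [torus_rh_slender()] within 2.5 percent
#' for `L/dh > 30`.
#'
#' @param L centerline (contour) length in Angstrom.
#' @param dh hydrodynamic (tube) diameter in Angstrom.
#' @return hydrodynamic radius in Angstrom.
#' @export
#' @examples
#' torus_rh_exact(1142.4, 29.4)  # 128.0 A
torus_rh_exact <- function(L, dh) {
  stopifnot(L > 0, dh > 0)
  x <- L / (pi * dh)
  if (any(x <= 1)) {
    stop("self-overlapping torus: require L > pi * dh.", call. = FALSE)
  }
  (L / (2 * pi) + dh / 2) * 72 * pi * (1 / (16 * x^2) + 1) * x /
    (25 * x + 6 * (11 * x + 8) * log(8 * x) + 16)
}

#' Hydrodynamic radius of a slender torus
#'
#' Logarithmically accurate fit `R_h = L / ((11/6) log(2 L / dh) + 1.13)`,
#' valid without loss of accuracy for `L/dh > 30`; a warning is issued for
#' stouter tori.
#'
#' @inheritParams torus_rh_exact
#' @return hydrodynamic radius in Angstrom.
#' @export
torus_rh_slender <- function(L, dh) {
  stopifnot(L > 0, dh > 0)
  if (any(L / dh <= 30)) {
    warning("slender-torus fit used outside its stated accuracy range (L/dh <= 30).",
            call. = FALSE)
  }
  L / (11 / 6 * log(2 * L / dh) + 1.13)
}

#' Hydrodynamic radius from axisymmetric mobility coefficients
#'
#' For an axially symmetric rigid particle with translational mobilities
#' `mu_x` (transverse, twofold degenerate) and `mu_z` (axial), the
#' orientation-averaged hydrodynamic radius is the inverse of the arithmetic
#' mobility mean: `R_h = (1 / 6 pi eta) * 3 / (2 mu_x + mu_z)`.
#'
#' @param mu_x,mu_z translational mobilities in SI units (m/(N s)).
#' @param env a [hydro_environment()].
#' @return hydrodynamic radius in Angstrom.
#' @export
rh_from_axisymmetric_mobilities <- function(mu_x, mu_z,
                                            env = hydro_environment()) {
  if (any(c(mu_x, mu_z) <= 0)) {
    stop("mobilities must be positive.", call. = FALSE)
  }
  (1 / (6 * pi * env$eta)) * 3 / (2 * mu_x + mu_z) / .ANGSTROM
}

#' Rigid bead model of a centerline
#'
#' Represents a shape by equal spheres of diameter `dh` whose centers are
#' equally spaced in arclength along the centerline; consecutive beads
#' overlap and the center-to-center spacings sum to the molecule length
#' (within 0.5 percent). Open chains (linear DNA) are supported by placing
#' the terminal bead centers at the chain ends.
#'
#' @param curve a [closed_curve()] or an `open_chain` (see
#'   [generate_fixture()]).
#' @param dh bead (hydrodynamic) diameter in Angstrom.
#' @param n_beads number of beads (default 400).
#' @return an object of class `bead_model` with fields `centers`
#'   (`n_beads` x 3, Angstrom), `dh`, `n_beads`, `closed`.
#' @export
build_bead_model <- function(curve, dh, n_beads = 400L) {
  stopifnot(dh > 0, n_beads >= 1L)
  if (inherits(curve, "open_chain")) {
    L <- curve$length
    if (n_beads > 1L && L / (n_beads - 1L) >= dh) {
      stop("beads do not overlap: increase `n_beads` or `dh`.", call. = FALSE)
    }
    a <- curve$points[1L, ]; b <- curve$points[nrow(curve$points), ]
    u <- seq(0, 1, length.out = n_beads)
    centers <- cbind(a[1] + u * (b[1] - a[1]), a[2] + u * (b[2] - a[2]),
                     a[3] + u * (b[3] - a[3]))
    return(structure(list(centers = centers, dh = dh,
                          n_beads = as.integer(n_beads), closed = FALSE),
                     class = "bead_model"))
  }
  stopifnot(is_closed_curve(curve))
  ## equal-arclength placement: invert t -> s on a fine grid
  nf <- max(4000L, 8L * n_beads)
  s <- curve_samples(curve, nf)
  cs <- cumsum(s$speed) / nf
  L <- cs[nf]
  if (n_beads > 1L && L / n_beads >= dh) {
    stop("beads do not overlap: increase `n_beads` or `dh`.", call. = FALSE)
  }
  target <- (seq_len(n_beads) - 1L) * L / n_beads
  tt <- stats::approx(c(0, cs), c(s$t, 1), xout = target, ties = "ordered")$y
  centers <- curve_eval(curve, tt, 0L)
  structure(list(centers = centers, dh = dh, n_beads = as.integer(n_beads),
                 closed = TRUE),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model: %d beads, diameter %.2f A, %s>\n",
              x$n_beads, x$dh, if (x$closed) "closed" else "open"))
  invisible(x)
}

#' Hydrodynamic radius of a rigid bead conglomerate
#'
#' Orientation-averaged translational hydrodynamic radius of a rigid
#' assembly of equal spheres.
#'
#' Method `"pairwise"` (default, deterministic) solves the rigid-body
#' mobility problem with the Rotne-Prager-Yamakawa pair tensor, which
#' remains positive definite for overlapping equal spheres: the grand
#' (6x6) resistance matrix is assembled from constrained Stokeslet
#' solves, inverted, the translational mobility block is evaluated at the
#' center of mobility, and `R_h = 1 / (6 pi eta tr(mu_tt)/3)`.
#'
#' Method `"montecarlo"` estimates the electrostatic capacitance of the
#' bead union by walk-on-spheres random walks (the path-integral
#' approximation to the Stokes mobility, exact for a sphere and accurate to
#' about one percent for compact shapes) and reports a Monte Carlo standard
#' error.
#'
#' @param model a [build_bead_model()].
#' @param env a [hydro_environment()].
#' @param method `"pairwise"` or `"montecarlo"`.
#' @param n_walks walk count for the stochastic estimator.
#' @param seed RNG seed for the stochastic estimator.
#' @return a one-row tibble: `Rh` (Angstrom), `method`, `n_beads`,
#'   `stderr` (Angstrom; 0 for the deterministic method).
#' @export
bead_model_rh <- function(model, env = hydro_environment(),
                          method = c("pairwise", "montecarlo"),
                          n_walks = 20000L, seed = 1L) {
  stopifnot(inherits(model, "bead_model"))
  method <- match.arg(method)
  if (model$n_beads == 1L) {
    return(tibble::tibble(Rh = model$dh / 2, method = method,
                          n_beads = 1L, stderr = 0))
  }
  if (method == "pairwise") {
    Rh <- rigid_body_rh(model$centers, model$dh / 2, env)
    tibble::tibble(Rh = Rh, method = method, n_beads = model$n_beads,
                   stderr = 0)
  } else {
    est <- wos_capacitance(model$centers, model$dh / 2, n_walks, seed)
    tibble::tibble(Rh = est$C, method = method, n_beads = model$n_beads,
                   stderr = est$stderr)
  }
}

## Rotne-Prager-Yamakawa mobility matrix (3N x 3N, SI) for equal spheres of
## radius `a` (Angstrom) at `centers` (Angstrom).
rpy_matrix <- function(centers, a, eta) {
  x <- centers * .ANGSTROM
  a <- a * .ANGSTROM
  n <- nrow(x)
  dx <- outer(x[, 1], x[, 1], "-")
  dy <- outer(x[, 2], x[, 2], "-")
  dz <- outer(x[, 3], x[, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  self <- 1 / (6 * pi * eta * a)
  near <- r < 2 * a & r > 0
  far <- r >= 2 * a
  C1 <- matrix(0, n, n); C2 <- matrix(0, n, n)
  ## far field: Rotne-Prager
  C1[far] <- (1 + 2 * a^2 / (3 * r[far]^2)) / (8 * pi * eta * r[far])
  C2[far] <- (1 - 2 * a^2 / r[far]^2) / (8 * pi * eta * r[far]^3) # times r_i r_j
  ## overlapping: Yamakawa regularization
  C1[near] <- self * (1 - 9 * r[near] / (32 * a))
  C2[near] <- self * 3 / (32 * a * r[near])
  diag(C1) <- self
  M <- matrix(0, 3 * n, 3 * n)
  ix <- seq(1, 3 * n, by = 3); iy <- ix + 1L; iz <- ix + 2L
  M[ix, ix] <- C1 + C2 * dx * dx
  M[iy, iy] <- C1 + C2 * dy * dy
  M[iz, iz] <- C1 + C2 * dz * dz
  M[ix, iy] <- C2 * dx * dy; M[iy, ix] <- t(C2 * dx * dy)
  M[ix, iz] <- C2 * dx * dz; M[iz, ix] <- t(C2 * dx * dz)
  M[iy, iz] <- C2 * dy * dz; M[iz, iy] <- t(C2 * dy * dz)
  M
}

## Orientation-averaged rigid-body hydrodynamic radius (Angstrom) of equal
## spheres; grand resistance from constrained solves, translational mobility
## evaluated at the center of mobility.
rigid_body_rh <- function(centers, a, env) {
  n <- nrow(centers)
  M <- rpy_matrix(centers, a, env$eta)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    warning("mobility matrix not positive definite; shrinking beads to contact.",
            call. = FALSE)
    ## conserve total surface with non-overlapping beads
    dmin <- min(stats::dist(centers))
    a2 <- min(a, dmin / 2 * 0.999)
    M <- rpy_matrix(centers, a2, env$eta)
    ch <- chol(M)
  }
  x0 <- colMeans(centers) * .ANGSTROM
  xr <- sweep(centers * .ANGSTROM, 2, x0)
  ## six rigid unit motions: velocities at every bead
  U <- matrix(0, 3 * n, 6)
  for (k in 1:3) U[seq(k, 3 * n, by = 3), k] <- 1
  om <- diag(3)
  for (k in 1:3) {
    w <- om[, k]
    v <- cbind(w[2] * xr[, 3] - w[3] * xr[, 2],
               w[3] * xr[, 1] - w[1] * xr[, 3],
               w[1] * xr[, 2] - w[2] * xr[, 1])
    U[, 3 + k] <- as.vector(t(v))
  }
  FF <- backsolve(ch, forwardsolve(t(ch), U)) # forces for each rigid motion
  ## total force and torque -> 6x6 resistance
  Xi <- matrix(0, 6, 6)
  for (k in 1:6) {
    f <- matrix(FF[, k], ncol = 3, byrow = TRUE)
    Ft <- colSums(f)
    Tq <- colSums(cbind(xr[, 2] * f[, 3] - xr[, 3] * f[, 2],
                        xr[, 3] * f[, 1] - xr[, 1] * f[, 3],
                        xr[, 1] * f[, 2] - xr[, 2] * f[, 1]))
    Xi[, k] <- c(Ft, Tq)
  }
  Xi <- (Xi + t(Xi)) / 2
  ## self rotational drag of each bead (volume correction); also removes the
  ## singularity of collinear point-bead bodies
  aSI <- a * .ANGSTROM
  Xi[4:6, 4:6] <- Xi[4:6, 4:6] + n * 8 * pi * env$eta * aSI^3 * diag(3)
  ## rescale rotational blocks by the body size before inverting: the raw
  ## 6x6 mixes scales eta*l and eta*l^3 and is numerically ill-conditioned
  ell <- max(aSI, sqrt(max(rowSums(xr^2))))
  S <- diag(c(1, 1, 1, 1 / ell, 1 / ell, 1 / ell))
  mu <- S %*% solve(S %*% Xi %*% S) %*% S
  mtt <- mu[1:3, 1:3]; mtr <- mu[1:3, 4:6]
  mrt <- mu[4:6, 1:3]; mrr <- mu[4:6, 4:6]
  ## translational mobility at displacement r from the origin:
  ## mu_tt(r) = mu_tt + mu_tr A - A mu_rt - A mu_rr A, A = skew(r).
  trace_at <- function(r) {
    A <- matrix(c(0, r[3], -r[2], -r[3], 0, r[1], r[2], -r[1], 0), 3, 3)
    sum(diag(mtt + mtr %*% A - A %*% mrt - A %*% mrr %*% A))
  }
  opt <- stats::optim(c(0, 0, 0), trace_at, method = "BFGS",
                      control = list(reltol = 1e-12))
  mu_bar <- opt$value / 3
  1 / (6 * pi * env$eta * mu_bar) / .ANGSTROM
}

## Walk-on-spheres capacitance of a union of equal spheres of radius `a`
## (Angstrom). Returns the capacitance radius (Angstrom) and its standard
## error. Batch-vectorized over walkers; unbiased re-entry through the
## launch sphere via the exterior Poisson kernel.
wos_capacitance <- function(centers, a, n_walks, seed) {
  c0 <- colMeans(centers)
  xr <- sweep(centers, 2, c0)
  aL <- max(sqrt(rowSums(xr^2))) + a
  eps <- 1e-4 * a
  withr_seed(seed, function() {
    ## start on the launch sphere, uniform
    pos <- runit(n_walks) * aL
    status <- rep.int(0L, n_walks) # 0 active, 1 hit, -1 escaped
    for (it in 1:10000) {
      act <- which(status == 0L)
      if (!length(act)) break
      p <- pos[act, , drop = FALSE]
      ## distance to the union
      d2 <- outer(rowSums(p^2), rowSums(xr^2), "+") - 2 * p %*% t(xr)
      d <- sqrt(pmax(apply(d2, 1L, min), 0)) - a
      hit <- d < eps
      status[act[hit]] <- 1L
      act <- act[!hit]; p <- p[!hit, , drop = FALSE]; d <- d[!hit]
      if (!length(act)) break
      p <- p + runit(length(act)) * d
      rr <- sqrt(rowSums(p^2))
      out <- rr > aL
      if (any(out)) {
        u <- stats::runif(sum(out))
        esc <- u > aL / rr[out]
        status[act[out][esc]] <- -1L
        ## unbiased re-entry: sample the exterior Poisson kernel on the
        ## launch sphere conditioned on return
        back_rows <- which(out)[!esc]
        if (length(back_rows)) {
          p[back_rows, ] <- poisson_reentry(p[back_rows, , drop = FALSE],
                                            rr[back_rows], aL)
        }
      }
      keep <- status[act] == 0L
      pos[act[keep], ] <- p[keep, , drop = FALSE]
    }
    p_hit <- mean(status == 1L)
    list(C = aL * p_hit, stderr = aL * sqrt(p_hit * (1 - p_hit) / n_walks))
  })
}

## Uniform random unit vectors, n x 3.
runit <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

## Sample the hitting point on a sphere of radius `aL` for a walker at
## exterior distance `r` (conditioned on hitting), via the inverse-CDF of
## the Poisson kernel marginal in cos(theta) about the walker direction.
poisson_reentry <- function(p, r, aL) {
  n <- nrow(p)
  U <- stats::runif(n)
  ## F(u) = ((r^2-a^2)/(2r)) [ (a^2+r^2-2aru)^{-1/2} - 1/(r+a) ]
  inv <- 2 * r * U / (r^2 - aL^2) + 1 / (r + aL)
  u <- (aL^2 + r^2 - 1 / inv^2) / (2 * aL * r)
  u <- clamp1(u)
  ## build an orthonormal frame with e3 = -p/|p| (towards the origin);
  ## theta measured from the walker direction +p/|p|
  e3 <- p / r
  ref <- cbind(rep(1, n), 0, 0)
  swap <- abs(e3[, 1]) > 0.9
  if (any(swap)) ref[swap, ] <- matrix(c(0, 1, 0), sum(swap), 3, byrow = TRUE)
  e1 <- cross3(e3, ref)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cross3(e3, e1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(1 - u^2, 0))
  aL * (e3 * u + e1 * (s * cos(phi)) + e2 * (s * sin(phi)))
}

#' Calibrate the hydrodynamic thickness from measured radii
#'
#' Least-squares fit of a single hydrodynamic diameter `dh` to the torus
#' model across measurements of open-circular molecules of different
#' lengths. Residuals are generally nonzero: a common `dh` cannot match all
#' lengths exactly, and the logarithmic dependence of `R_h` on `dh` makes
#' the fitted value approximate by nature.
#'
#' @param measurements a data frame with columns `length` (contour length,
#'   Angstrom) and `Rh` (measured hydrodynamic radius, Angstrom).
#' @return an object of class `dh_calibration`: fields `dh` (Angstrom),
#'   `residuals` tibble (`length`, `Rh`, `fitted`, `residual`), `rss`.
#' @export
calibrate_dh <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  if (!all(c("length", "Rh") %in% names(m))) {
    stop("`measurements` needs columns `length` and `Rh`.", call. = FALSE)
  }
  if (nrow(m) < 1L) stop("no measurements supplied.", call. = FALSE)
  if (nrow(m) < 2L) {
    ## single exact point: solve the torus equation
    f <- function(dh) torus_rh_exact(m$length, dh) - m$Rh
    dh <- stats::uniroot(f, c(1e-3, m$length / pi * 0.999), tol = 1e-10)$root
  } else {
    rss <- function(dh) sum((torus_rh_exact(m$length, dh) - m$Rh)^2)
    dh <- stats::optimize(rss, c(1e-3, min(m$length) / pi * 0.999))$minimum
  }
  fitted <- torus_rh_exact(m$length, dh)
  res <- m$Rh - fitted
  if (nrow(m) >= 2L && (all(res > 0) || all(res < 0))) {
    warning("all residuals have the same sign; the common-thickness fit does not bracket the data.",
            call. = FALSE)
  }
  structure(list(dh = dh,
                 residuals = tibble::tibble(length = m$length, Rh = m$Rh,
                                            fitted = fitted, residual = res),
                 rss = sum(res^2)),
            class = "dh_calibration")
}

#' @export
print.dh_calibration <- function(x, ...) {
  cat(sprintf("<dh_calibration: dh = %.2f A, rss = %.3g A^2, %d point(s)>\n",
              x$dh, x$rss, nrow(x$residuals)))
  invisible(x)
}

#' Hydrodynamic radius of the minimized shape at a given deficit
#'
#' Full shape-to-hydrodynamics pipeline for one linking-number deficit:
#' minimize the rod energy, build the overlapping-bead model on the
#' minimized centerline, and compute the orientation-averaged `R_h`; the
#' same bead pipeline applied to the flat circle gives the reference
#' `R_h0`, so the relative value is 1 below the writhing threshold.
#'
#' @param dLk linking-number deficit (turns).
#' @param params an [elastic_params()].
#' @param dh hydrodynamic diameter in Angstrom.
#' @param config a [minimizer_config()].
#' @param env a [hydro_environment()].
#' @param n_beads beads in the hydrodynamic model.
#' @param method mobility engine passed to [bead_model_rh()].
#' @return a one-row tibble: `dLk`, `Rh`, `Rh0`, `Rh_rel`, `writhe`,
#'   `regime`.
#' @export
predict_rh_for_dlk <- function(dLk, params, dh, config = minimizer_config(),
                               env = hydro_environment(), n_beads = 400L,
                               method = "pairwise") {
  shape <- minimize_shape(dLk, params, config)
  rh <- bead_model_rh(build_bead_model(shape$curve, dh, n_beads), env,
                      method = method, seed = config$rng_seed)$Rh
  rh0 <- bead_model_rh(build_bead_model(build_circle(params$L), dh, n_beads),
                       env, method = method, seed = config$rng_seed)$Rh
  tibble::tibble(dLk = dLk, Rh = rh, Rh0 = rh0, Rh_rel = rh / rh0,
                 writhe = shape$writhe, regime = shape$regime)
}
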