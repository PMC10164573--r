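#' Closed three-dimensional centerline curves
#'
#' A `closed_curve` represents the centerline of a closed DNA loop as a
#' periodic cubic spline through an ordered set of 3-D control points
#' (coordinates in Angstrom). Periodic interpolation makes the position and
#' its first two derivatives continuous across the seam, so curvature is well
#' defined everywhere. Curves produced by analytic generators (circles,
#' figure-8 families) additionally carry their exact parameterization, which
#' is used instead of the interpolant when present.
#'
#' @param control_points numeric matrix with one row per control point and
#'   columns x, y, z (Angstrom). The curve closes implicitly from the last
#'   point back to the first.
#' @param fun optional analytic parameterization: `function(t, deriv)`
#'   returning an `length(t)` x 3 matrix of the curve position (`deriv = 0`)
#'   or parameter-derivatives (`deriv = 1, 2`) at parameter `t` in `[0, 1)`.
#'
#' @return An object of class `closed_curve`.
#' @export
closed_curve <- function(control_points, fun = NULL) {
  cp <- as.matrix(control_points)
  if (!is.numeric(cp) || ncol(cp) != 3L) {
    stop("`control_points` must be a numeric matrix with 3 columns (x, y, z).",
         call. = FALSE)
  }
  if (nrow(cp) < 4L) {
    stop("a closed curve needs at least 4 control points.", call. = FALSE)
  }
  if (anyNA(cp) || any(!is.finite(cp))) {
    stop("control points must be finite.", call. = FALSE)
  }
  ## coincident neighbours (including the seam) break the interpolant
  nxt <- c(seq_len(nrow(cp))[-1L], 1L)
  seg <- sqrt(rowSums((cp[nxt, , drop = FALSE] - cp)^2))
  if (any(seg < 1e-9)) {
    stop("coincident neighbouring control points; curve is degenerate.",
         call. = FALSE)
  }
  dimnames(cp) <- list(NULL, c("x", "y", "z"))
  structure(list(control_points = cp, n_nodes = nrow(cp), fun = fun),
            class = "closed_curve")
}

#' @export
print.closed_curve <- function(x, ...) {
  cat(sprintf("<closed_curve: %d control points%s>\n", x$n_nodes,
              if (is.null(x$fun)) "" else ", analytic"))
  invisible(x)
}

is_closed_curve <- function(x) inherits(x, "closed_curve")

## Periodic cubic spline interpolants, one per coordinate, parameter t in [0,1).
curve_splines <- function(curve) {
  cp <- curve$control_points
  n <- nrow(cp)
  tk <- seq(0, 1, length.out = n + 1L)
  lapply(1:3, function(j) {
    stats::splinefun(tk, c(cp[, j], cp[1L, j]), method = "periodic")
  })
}

#' Evaluate a closed curve
#'
#' @param curve a [closed_curve()].
#' @param t numeric vector of parameter values (wrapped into `[0, 1)`).
#' @param deriv derivative order 0, 1 or 2 with respect to the parameter.
#' @return a `length(t)` x 3 matrix.
#' @export
curve_eval <- function(curve, t, deriv = 0L) {
  stopifnot(is_closed_curve(curve), deriv %in% 0:2)
  t <- t %% 1
  if (!is.null(curve$fun)) return(curve$fun(t, deriv))
  sf <- curve_splines(curve)
  cbind(sf[[1]](t, deriv = deriv), sf[[2]](t, deriv = deriv),
        sf[[3]](t, deriv = deriv))
}

## Sample positions, derivatives, speed, unit tangent and curvature at n
## equispaced parameter values (t = 0, 1/n, ..., (n-1)/n).
curve_samples <- function(curve, n) {
  t <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
  r  <- curve_eval(curve, t, 0L)
  r1 <- curve_eval(curve, t, 1L)
  r2 <- curve_eval(curve, t, 2L)
  speed <- sqrt(rowSums(r1^2))
  cr <- cross3(r1, r2)
  kappa <- sqrt(rowSums(cr^2)) / speed^3
  list(t = t, r = r, r1 = r1, r2 = r2, speed = speed,
       tangent = r1 / speed, kappa = kappa)
}

## Row-wise cross product of n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Arclength of a closed curve
#'
#' Integrates the parametric speed with adaptive Simpson quadrature.
#'
#' @param curve a [closed_curve()].
#' @param tol absolute quadrature tolerance (Angstrom).
#' @return contour length in Angstrom.
#' @export
arclength <- function(curve, tol = 1e-9) {
  stopifnot(is_closed_curve(curve))
  speed <- function(t) sqrt(rowSums(curve_eval(curve, t, 1L)^2))
  ## pracma::simpadpt handles vectorized integrands
  pracma::simpadpt(speed, 0, 1, tol = tol * max(1, speed(0)))
}

#' Build a planar circle of prescribed circumference
#'
#' Reference open-circle configuration of a relaxed loop: constant curvature
#' `2 pi / L` everywhere. The circle lies in the x-z plane (so that it is
#' invariant under the two-fold symmetry operation used by the shape
#' minimizer) and carries its exact parameterization.
#'
#' @param contour_length circumference L in Angstrom.
#' @param n_nodes number of control points (>= 8).
#' @return a [closed_curve()].
#' @export
#' @examples
#' circ <- build_circle(2 * pi, 16)
#' range(curvature_profile(circ, 64)$kappa)  # == 1
build_circle <- function(contour_length, n_nodes = 16L) {
  if (!is.numeric(contour_length) || length(contour_length) != 1L ||
      !is.finite(contour_length) || contour_length <= 0) {
    stop("`contour_length` must be a positive number.", call. = FALSE)
  }
  if (n_nodes < 8L) {
    stop("`n_nodes` must be at least 8.", call. = FALSE)
  }
  R <- contour_length / (2 * pi)
  f <- function(t, deriv = 0L) {
    a <- 2 * pi * t
    switch(deriv + 1L,
      cbind(R * cos(a), 0, R * sin(a)),
      cbind(-2 * pi * R * sin(a), 0, 2 * pi * R * cos(a)),
      cbind(-(2 * pi)^2 * R * cos(a), 0, -(2 * pi)^2 * R * sin(a)))
  }
  tt <- seq(0, 1, length.out = n_nodes + 1L)[-(n_nodes + 1L)]
  closed_curve(f(tt), fun = f)
}

#' Curvature along a closed loop
#'
#' Returns the local curvature at positions along the loop, the position
#' coordinate running from 0 to 1 around the loop. When `origin` is given
#' (e.g. the parameter of a self-contact point of a writhed shape, or the
#' center of symmetry), positions are measured from it.
#'
#' @param curve a [closed_curve()].
#' @param n_samples number of sample points.
#' @param origin parameter value in `[0, 1)` taken as position 0.
#' @return a tibble with columns `position` (arclength fraction in `[0, 1)`)
#'   and `kappa` (1/Angstrom).
#' @export
curvature_profile <- function(curve, n_samples = 200L, origin = 0) {
  stopifnot(is_closed_curve(curve), n_samples >= 8L)
  s <- curve_samples(curve, n_samples)
  ## arclength fraction via cumulative trapezoid of the speed
  ds <- s$speed / sum(s$speed)
  pos <- (cumsum(ds) - ds) # fraction at each sample, starting at 0
  ## shift so that `origin` (a parameter value) maps to position 0
  if (origin != 0) {
    i0 <- which.min(abs(s$t - (origin %% 1)))
    pos <- (pos - pos[i0]) %% 1
  }
  ord <- order(pos)
  tibble::tibble(position = pos[ord], kappa = s$kappa[ord])
}

#' Rigidly transform or mirror a curve
#'
#' @param curve a [closed_curve()].
#' @param rotation 3x3 matrix (orthogonal for rigid motions; improper, e.g.
#'   `diag(c(1, 1, -1))`, for mirror reflections).
#' @param translation length-3 offset in Angstrom.
#' @param scale positive scalar applied before translation.
#' @return the transformed [closed_curve()].
#' @export
transform_curve <- function(curve, rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  stopifnot(is_closed_curve(curve), scale > 0)
  R <- rotation
  b <- translation
  f <- curve$fun
  newfun <- if (!is.null(f)) {
    function(t, deriv = 0L) {
      m <- scale * f(t, deriv) %*% t(R)
      if (deriv == 0L) m <- sweep(m, 2, b, "+")
      m
    }
  }
  cp <- scale * curve$control_points %*% t(R)
  cp <- sweep(cp, 2, b, "+")
  closed_curve(cp, fun = newfun)
}

#' Minimum distance between non-neighbouring points of a loop
#'
#' Samples the centerline and reports the minimum pairwise distance over all
#' sample pairs separated by more than `exclusion` along the contour. Used to
#' assess steric self-contact of a tube of given thickness.
#'
#' @param curve a [closed_curve()].
#' @param n_samples sample count.
#' @param exclusion contour separation (Angstrom) below which pairs are
#'   considered local neighbours and skipped.
#' @return minimum non-neighbour distance in Angstrom.
#' @export
min_self_distance <- function(curve, n_samples = 400L, exclusion = 40) {
  stopifnot(is_closed_curve(curve))
  s <- curve_samples(curve, n_samples)
  total_len <- mean(s$speed) # = integral of speed over [0,1], to O(1/n^2)
  d <- as.matrix(stats::dist(s$r))
  n <- n_samples
  idx <- abs(outer(seq_len(n), seq_len(n), "-"))
  ## contour separation between samples i, j is (L / n) * cyclic index gap
  arc <- pmin(idx, n - idx) * total_len / n
  keep <- arc > exclusion
  if (!any(keep)) return(Inf)
  min(d[keep])
}
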