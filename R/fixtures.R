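#' Canonical test curves
#'
#' Deterministic generators for the closed-curve fixtures used throughout the
#' package: an exact circle, a figure-8 family with controllable apex
#' separation (writhe tends to +/-1 as the separation vanishes), a smoothly
#' perturbed loop (circle plus a seeded random Fourier perturbation of bounded
#' amplitude), and a straight open rod used for the linear-DNA hydrodynamic
#' model.
#'
#' @param kind one of `"circle"`, `"figure8"`, `"perturbed_loop"`,
#'   `"straight_rod"`.
#' @param contour_length target contour length L in Angstrom.
#' @param n_nodes control points for the returned curve.
#' @param separation (figure8) distance between the two strands at the
#'   crossing, in Angstrom.
#' @param amplitude (perturbed_loop) perturbation amplitude as a fraction of
#'   the circle radius.
#' @param n_modes (perturbed_loop) number of Fourier modes.
#' @param seed (perturbed_loop) RNG seed for the mode coefficients.
#' @return a [closed_curve()], or for `"straight_rod"` an `open_chain`
#'   object (list with a `points` matrix).
#' @export
#' @examples
#' abs(writhe(generate_fixture("figure8", separation = 0.5))) # close to 1
generate_fixture <- function(kind = c("circle", "figure8", "perturbed_loop",
                                      "straight_rod"),
                             contour_length = 2 * pi * 100, n_nodes = 32L,
                             separation = 10, amplitude = 0.05,
                             n_modes = 4L, seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    circle = build_circle(contour_length, n_nodes),
    figure8 = figure8_curve(contour_length, separation, n_nodes),
    perturbed_loop = perturbed_loop(contour_length, amplitude, n_modes,
                                    n_nodes, seed),
    straight_rod = straight_rod(contour_length))
}

## Lemniscate-like figure-8 with its crossing separated by `separation`
## along z; rescaled to the requested contour length.
figure8_curve <- function(contour_length, separation, n_nodes = 32L,
                          handedness = 1) {
  stopifnot(contour_length > 0, separation >= 0, handedness %in% c(-1, 1))
  base <- function(eps) {
    force(eps)
    function(t, deriv = 0L) {
      a <- 2 * pi * t
      switch(deriv + 1L,
        cbind(sin(a), sin(a) * cos(a) / 2, handedness * eps * cos(a)),
        2 * pi * cbind(cos(a), cos(2 * a) / 2, -handedness * eps * sin(a)),
        (2 * pi)^2 * cbind(-sin(a), -sin(2 * a), -handedness * eps * cos(a)))
    }
  }
  unit_len <- function(eps) {
    b <- base(eps)
    pracma::simpadpt(function(t) sqrt(rowSums(b(t, 1L)^2)), 0, 1, tol = 1e-10)
  }
  ## the final curve is S * lemniscate(eps) with S = L / len(eps); choose eps
  ## so the crossing separation 2 * S * eps matches the request.
  eps <- if (separation == 0) 0 else {
    stats::uniroot(function(e) 2 * e * contour_length / unit_len(e) - separation,
                   c(1e-10, 10), tol = 1e-12)$root
  }
  S <- contour_length / unit_len(eps)
  b <- base(eps)
  g <- function(t, deriv = 0L) S * b(t, deriv)
  tt <- seq(0, 1, length.out = n_nodes + 1L)[-(n_nodes + 1L)]
  closed_curve(g(tt), fun = g)
}

## Circle with a seeded, smooth, bounded random Fourier perturbation.
perturbed_loop <- function(contour_length, amplitude, n_modes, n_nodes, seed) {
  R <- contour_length / (2 * pi)
  coef <- withr_seed(seed, function() {
    list(c1 = stats::rnorm(n_modes), s1 = stats::rnorm(n_modes),
         c2 = stats::rnorm(n_modes), s2 = stats::rnorm(n_modes))
  })
  ## normalize so the max radial/vertical excursion is `amplitude * R`
  norm1 <- sum(abs(coef$c1) + abs(coef$s1))
  norm2 <- sum(abs(coef$c2) + abs(coef$s2))
  f <- function(t, deriv = 0L) {
    a <- 2 * pi * t
    dr <- numeric(length(t)); dz <- numeric(length(t))
    dr1 <- numeric(length(t)); dz1 <- numeric(length(t))
    dr2 <- numeric(length(t)); dz2 <- numeric(length(t))
    for (m in seq_len(n_modes)) {
      k <- m + 1L # modes 2..n+1: mode 1 is a rigid translation
      w <- k * 2 * pi
      dr  <- dr  + coef$c1[m] * cos(k * a) + coef$s1[m] * sin(k * a)
      dr1 <- dr1 + w * (-coef$c1[m] * sin(k * a) + coef$s1[m] * cos(k * a))
      dr2 <- dr2 - w^2 * (coef$c1[m] * cos(k * a) + coef$s1[m] * sin(k * a))
      dz  <- dz  + coef$c2[m] * cos(k * a) + coef$s2[m] * sin(k * a)
      dz1 <- dz1 + w * (-coef$c2[m] * sin(k * a) + coef$s2[m] * cos(k * a))
      dz2 <- dz2 - w^2 * (coef$c2[m] * cos(k * a) + coef$s2[m] * sin(k * a))
    }
    if (norm1 > 0) { dr <- dr / norm1; dr1 <- dr1 / norm1; dr2 <- dr2 / norm1 }
    if (norm2 > 0) { dz <- dz / norm2; dz1 <- dz1 / norm2; dz2 <- dz2 / norm2 }
    amp <- amplitude * R
    rad  <- R + amp * dr
    rad1 <- amp * dr1
    rad2 <- amp * dr2
    switch(deriv + 1L,
      cbind(rad * cos(a), rad * sin(a), amp * dz),
      cbind(rad1 * cos(a) - rad * sin(a) * 2 * pi,
            rad1 * sin(a) + rad * cos(a) * 2 * pi,
            amp * dz1),
      cbind(rad2 * cos(a) - 2 * rad1 * sin(a) * 2 * pi - rad * cos(a) * (2 * pi)^2,
            rad2 * sin(a) + 2 * rad1 * cos(a) * 2 * pi - rad * sin(a) * (2 * pi)^2,
            amp * dz2))
  }
  tt <- seq(0, 1, length.out = n_nodes + 1L)[-(n_nodes + 1L)]
  closed_curve(f(tt), fun = f)
}

straight_rod <- function(contour_length) {
  structure(list(points = cbind(x = c(0, contour_length), y = c(0, 0),
                                z = c(0, 0)),
                 length = contour_length),
            class = "open_chain")
}

#' @export
print.open_chain <- function(x, ...) {
  cat(sprintf("<open_chain: length %.1f Angstrom>\n", x$length))
  invisible(x)
}

## Run `fn` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}
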