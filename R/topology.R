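#' Linking-number bookkeeping for a closed DNA loop
#'
#' Collects the topological state of a minicircle: linking number `Lk`, the
#' relaxed reference `Lk0 = length_bp / h` for helical repeat `h`, the deficit
#' `dLk = Lk - Lk0` (which keeps its fractional part), the superhelical
#' density `sigma = dLk / Lk0`, and -- when known -- the partition of `Lk`
#' into twist and writhe (`Lk = Tw + Wr`).
#'
#' For covalently closed species `Lk` is an integer; nicked or linear species
#' may carry non-integer values. Exactly one of `Lk` or `dLk` must be given.
#'
#' @param length_bp loop length in base pairs.
#' @param helical_repeat relaxed helical repeat `h` in bp/turn
#'   (default 10.42, the value in 10 mM CaCl2).
#' @param Lk linking number (turns).
#' @param dLk linking-number deficit `Lk - Lk0` (turns).
#' @param Wr writhe of the centerline (optional).
#' @return an object of class `topology_state` (a named list).
#' @export
#' @examples
#' topology_state(336, Lk = 32)   # relaxed 336 bp: Lk0 = 32.2, dLk = -0.2
topology_state <- function(length_bp, helical_repeat = 10.42,
                           Lk = NULL, dLk = NULL, Wr = NULL) {
  stopifnot(length_bp > 0, helical_repeat > 0)
  Lk0 <- length_bp / helical_repeat
  if (is.null(Lk) && is.null(dLk)) {
    stop("supply either `Lk` or `dLk`.", call. = FALSE)
  }
  if (is.null(Lk)) Lk <- Lk0 + dLk
  dLk <- Lk - Lk0
  out <- list(length_bp = length_bp, helical_repeat = helical_repeat,
              Lk = Lk, Lk0 = Lk0, dLk = dLk, sigma = dLk / Lk0,
              Wr = Wr, Tw = if (!is.null(Wr)) Lk - Wr else NULL)
  structure(out, class = "topology_state")
}

#' @export
print.topology_state <- function(x, ...) {
  cat(sprintf(
    "<topology_state: %d bp, h = %.2f bp/turn, Lk = %.3f, Lk0 = %.3f, dLk = %+.3f, sigma = %+.4f>\n",
    x$length_bp, x$helical_repeat, x$Lk, x$Lk0, x$dLk, x$sigma))
  if (!is.null(x$Wr)) cat(sprintf("  Tw = %.4f, Wr = %+.4f\n", x$Tw, x$Wr))
  invisible(x)
}

#' Writhe of a closed curve
#'
#' Evaluates the Gauss double integral for the writhe of the centerline by
#' approximating the curve with straight segments and summing the exact
#' solid-angle contribution of every segment pair (the Levitt segment-pair
#' closed form), which avoids the singularities of a direct quadrature of the
#' Gauss integrand. The result is invariant under rigid motions and uniform
#' scaling and flips sign under mirror reflection. Right-handed crossings
#' count positive; negatively supercoiled loops have negative writhe.
#'
#' @param curve a [closed_curve()].
#' @param n_segments number of straight segments used (default 200).
#' @return the writhe (dimensionless).
#' @export
writhe <- function(curve, n_segments = 200L) {
  if (!is_closed_curve(curve)) {
    stop("writhe is defined for closed curves only.", call. = FALSE)
  }
  stopifnot(n_segments >= 8L)
  p <- curve_eval(curve, seq(0, 1, length.out = n_segments + 1L)[-(n_segments + 1L)], 0L)
  polygon_writhe(p)
}

## Writhe of a closed polygon given its vertices (n x 3), Levitt's
## segment-pair solid-angle formula summed over non-adjacent pairs.
.writhe_pair_cache <- new.env(parent = emptyenv())

writhe_pairs <- function(n) {
  key <- as.character(n)
  hit <- .writhe_pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  ii <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  gap <- jj - ii
  keep <- gap >= 2L & gap <= n - 2L
  out <- list(i = ii[keep], j = jj[keep])
  .writhe_pair_cache[[key]] <- out
  out
}

polygon_writhe <- function(p) {
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  ## all non-adjacent ordered pairs i < j (adjacency includes the wrap pair);
  ## flat component vectors to keep the inner loop allocation-light
  pr <- writhe_pairs(n)
  i <- pr$i; j <- pr$j
  ax <- p[, 1]; ay <- p[, 2]; az <- p[, 3]
  bx <- ax[nxt]; by <- ay[nxt]; bz <- az[nxt]

  r1x <- ax[i]; r1y <- ay[i]; r1z <- az[i]
  r2x <- bx[i]; r2y <- by[i]; r2z <- bz[i]
  r3x <- ax[j]; r3y <- ay[j]; r3z <- az[j]
  r4x <- bx[j]; r4y <- by[j]; r4z <- bz[j]

  c13x <- r3x - r1x; c13y <- r3y - r1y; c13z <- r3z - r1z
  c14x <- r4x - r1x; c14y <- r4y - r1y; c14z <- r4z - r1z
  c23x <- r3x - r2x; c23y <- r3y - r2y; c23z <- r3z - r2z
  c24x <- r4x - r2x; c24y <- r4y - r2y; c24z <- r4z - r2z

  n1x <- c13y * c14z - c13z * c14y
  n1y <- c13z * c14x - c13x * c14z
  n1z <- c13x * c14y - c13y * c14x
  n2x <- c14y * c24z - c14z * c24y
  n2y <- c14z * c24x - c14x * c24z
  n2z <- c14x * c24y - c14y * c24x
  n3x <- c24y * c23z - c24z * c23y
  n3y <- c24z * c23x - c24x * c23z
  n3z <- c24x * c23y - c24y * c23x
  n4x <- c23y * c13z - c23z * c13y
  n4y <- c23z * c13x - c23x * c13z
  n4z <- c23x * c13y - c23y * c13x

  ## degenerate (collinear/coplanar) connector pairs: the cross products are
  ## pure roundoff; normalizing them would inject noise, so suppress any
  ## normal whose magnitude is negligible relative to its factors
  l13 <- c13x * c13x + c13y * c13y + c13z * c13z
  l14 <- c14x * c14x + c14y * c14y + c14z * c14z
  l23 <- c23x * c23x + c23y * c23y + c23z * c23z
  l24 <- c24x * c24x + c24y * c24y + c24z * c24z
  inv_or_zero <- function(nx, ny, nz, scale2) {
    n2 <- nx * nx + ny * ny + nz * nz
    out <- 1 / sqrt(n2)
    out[n2 <= 1e-18 * scale2] <- 0
    out
  }
  i1 <- inv_or_zero(n1x, n1y, n1z, l13 * l14)
  i2 <- inv_or_zero(n2x, n2y, n2z, l14 * l24)
  i3 <- inv_or_zero(n3x, n3y, n3z, l24 * l23)
  i4 <- inv_or_zero(n4x, n4y, n4z, l23 * l13)

  omega <- asin(clamp1((n1x * n2x + n1y * n2y + n1z * n2z) * i1 * i2)) +
           asin(clamp1((n2x * n3x + n2y * n3y + n2z * n3z) * i2 * i3)) +
           asin(clamp1((n3x * n4x + n3y * n4y + n3z * n4z) * i3 * i4)) +
           asin(clamp1((n4x * n1x + n4y * n1y + n4z * n1z) * i4 * i1))
  s12x <- r2x - r1x; s12y <- r2y - r1y; s12z <- r2z - r1z
  s34x <- r4x - r3x; s34y <- r4y - r3y; s34z <- r4z - r3z
  cx <- s34y * s12z - s34z * s12y
  cy <- s34z * s12x - s34x * s12z
  cz <- s34x * s12y - s34y * s12x
  sgn <- sign(cx * c13x + cy * c13y + cz * c13z)
  sum(omega * sgn) / (2 * pi)
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Twist from the linking number and writhe
#'
#' Applies the Calugareanu decomposition `Lk = Tw + Wr` to recover the total
#' twist, and reports the residual excess twist density `Omega` implied by a
#' uniform distribution of the excess twist along the rod: the elastic energy
#' is quadratic in `Omega` with no positional coupling, so the minimizer
#' spreads excess twist uniformly, `Omega = 2 pi (Tw - Lk0) / L`.
#'
#' @param topology a [topology_state()] with `Lk` set.
#' @param wr writhe of the centerline.
#' @param contour_length contour length L in Angstrom (for the twist
#'   density; defaults to `length_bp * 3.4`).
#' @return a tibble with columns `Tw` (turns), `Wr`, and `omega`
#'   (excess twist density, radian/Angstrom).
#' @export
#' @examples
#' twist_from_lk(topology_state(336, Lk = 32), wr = 0)
twist_from_lk <- function(topology, wr,
                          contour_length = topology$length_bp * 3.4) {
  stopifnot(inherits(topology, "topology_state"))
  Tw <- topology$Lk - wr
  omega <- 2 * pi * (Tw - topology$Lk0) / contour_length
  tibble::tibble(Tw = Tw, Wr = wr, omega = omega)
}
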