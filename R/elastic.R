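#' Elastic rod parameters
#'
#' Constants of the Kirchhoff rod model of a DNA minicircle: effective
#' bending rigidity `A = kB T P` (persistence length `P`), the geometric
#' torsional stiffness factor `omega` (2/3 for a circular cross-section),
#' the steric thickness `d_s` of the excluded-volume tube, and the contour
#' length `L`. Scaled by `kB T` the energy is dimensionless and the model is
#' fully specified by the aspect ratio `d_s / L` and `omega`.
#'
#' @param contour_length_L contour length in Angstrom.
#' @param persistence_length_P persistence length in Angstrom (default 500,
#'   i.e. about 150 bp).
#' @param torsional_factor_omega dimensionless torsional stiffness factor
#'   (default 2/3).
#' @param steric_thickness_ds steric diameter in Angstrom (default 20).
#' @return an object of class `elastic_params`.
#' @export
elastic_params <- function(contour_length_L,
                           persistence_length_P = 500,
                           torsional_factor_omega = 2 / 3,
                           steric_thickness_ds = 20) {
  stopifnot(contour_length_L > 0, persistence_length_P > 0,
            torsional_factor_omega > 0, steric_thickness_ds > 0)
  if (steric_thickness_ds >= contour_length_L) {
    stop("steric thickness must be smaller than the contour length.",
         call. = FALSE)
  }
  structure(list(L = contour_length_L, P = persistence_length_P,
                 omega = torsional_factor_omega, ds = steric_thickness_ds),
            class = "elastic_params")
}

#' @export
print.elastic_params <- function(x, ...) {
  cat(sprintf(
    "<elastic_params: L = %.1f A, P = %.1f A, omega = %.3f, d_s = %.1f A (d_s/L = %.4f)>\n",
    x$L, x$P, x$omega, x$ds, x$ds / x$L))
  invisible(x)
}

#' Kirchhoff rod energy of a closed twisted loop
#'
#' Bending plus twisting elastic energy of the rod,
#' `E = (1/2) int A (kappa^2 + omega Omega^2) ds`, in units of `kB T`
#' (with `A = kB T P`). The excess twist density is taken uniform at
#' equilibrium, `Omega = 2 pi (dLk - Wr) / L`, because the energy is
#' quadratic in `Omega` with no positional coupling.
#'
#' @param curve a [closed_curve()]; its writhe is computed internally.
#' @param dLk linking-number deficit (turns, fractional part retained).
#' @param params an [elastic_params()].
#' @param n_writhe_segments segments for the writhe evaluation.
#' @param n_samples quadrature samples for the bending integral.
#' @param check_steric error on steric self-overlap (non-neighbour centerline
#'   separation below `d_s`).
#' @return a one-row tibble: `energy_bend`, `energy_twist`, `energy_total`
#'   (kB T), `writhe`, `omega_residual` (rad/Angstrom), `length` (Angstrom).
#' @export
#' @examples
#' p <- elastic_params(336 * 3.4)
#' rod_energy(build_circle(p$L), dLk = 0, p)  # pure bend, 2 pi^2 P / L
rod_energy <- function(curve, dLk, params, n_writhe_segments = 200L,
                       n_samples = 400L, check_steric = TRUE) {
  stopifnot(is_closed_curve(curve), inherits(params, "elastic_params"))
  if (check_steric) {
    dmin <- min_self_distance(curve, exclusion = 2 * params$ds)
    if (dmin < params$ds - 1e-6) {
      stop(sprintf(
        "steric violation: non-neighbour centerline separation %.2f A < d_s = %.2f A.",
        dmin, params$ds), call. = FALSE)
    }
  }
  s <- curve_samples(curve, n_samples)
  len <- mean(s$speed)
  bend <- (params$P / 2) * mean(s$kappa^2 * s$speed)
  wr <- writhe(curve, n_writhe_segments)
  Omega <- 2 * pi * (dLk - wr) / len
  twist <- (params$P * params$omega / 2) * len * Omega^2
  tibble::tibble(energy_bend = bend, energy_twist = twist,
                 energy_total = bend + twist, writhe = wr,
                 omega_residual = Omega, length = len)
}

#' Critical linking-number deficit for writhing (empirical)
#'
#' Threshold `|dLk|` above which a figure-8 (writhed) equilibrium becomes
#' admissible, as a function of the rod aspect ratio:
#' `Lk_crit = sqrt(1 + 23.1 d_s/L)`. Tends to 1 for a vanishingly thin
#' filament and grows with thickness (thicker rods need more torsional
#' stress to stay writhed).
#'
#' @param ds_over_L aspect ratio `d_s / L`, in `[0, 0.1)`.
#' @return `Lk_crit` in turns.
#' @export
#' @examples
#' lk_crit_empirical(0.018)  # 336 bp geometry: 1.19
lk_crit_empirical <- function(ds_over_L) {
  if (any(ds_over_L < 0)) {
    stop("aspect ratio must be non-negative.", call. = FALSE)
  }
  if (any(ds_over_L >= 0.1)) {
    stop("the empirical threshold is calibrated for d_s/L < 0.1.",
         call. = FALSE)
  }
  sqrt(1 + 23.1 * ds_over_L)
}

#' Thickness-independent upper stability limit of the flat circle
#'
#' Above `Lk_max = sqrt(3) / omega` the flat circular shape is no longer an
#' equilibrium and only writhed configurations exist. For a circular
#' cross-section (`omega = 2/3`) this gives 2.6.
#'
#' @param omega torsional stiffness factor (> 0).
#' @return `Lk_max` in turns.
#' @export
lk_max <- function(omega = 2 / 3) {
  if (any(!is.finite(omega)) || any(omega <= 0)) {
    stop("`omega` must be positive.", call. = FALSE)
  }
  sqrt(3) / omega
}

#' Stability regime of a minicircle
#'
#' Classifies the equilibrium landscape at a given linking-number deficit:
#' only the open circle below `Lk_crit(d_s/L)`, coexistence of circle and
#' writhed shapes between `Lk_crit` and `Lk_max = sqrt(3)/omega`, and only
#' writhed shapes above `Lk_max`.
#'
#' @param dLk linking-number deficit (sign ignored).
#' @param params an [elastic_params()].
#' @return one of `"circle_only"`, `"multistable"`, `"writhed_only"`.
#' @export
stability_regime <- function(dLk, params) {
  stopifnot(inherits(params, "elastic_params"))
  x <- abs(dLk)
  crit <- lk_crit_empirical(params$ds / params$L)
  mx <- lk_max(params$omega)
  dplyr::case_when(x < crit ~ "circle_only",
                   x <= mx ~ "multistable",
                   TRUE ~ "writhed_only")
}
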