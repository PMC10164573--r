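#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an equilibrium shape
#'
#' One row per optimization branch (including the analytic flat circle),
#' with energies in kB T.
#'
#' @param x an `equilibrium_shape` from [minimize_shape()].
#' @param ... unused.
#' @export
tidy.equilibrium_shape <- function(x, ...) {
  dplyr::mutate(x$branches, dLk = x$dLk, .before = 1L)
}

#' Summarize an equilibrium shape
#'
#' Besides the energies and contact summary, two measures of how much
#' torsional stress the shape sheds by writhing are reported: `wr_fraction`
#' is the writhe share of the deficit, `Wr / dLk`, and `twist_relaxation`
#' is the fraction of the flat-circle twist energy removed,
#' `1 - ((dLk - Wr) / dLk)^2`. (Both are `NA` at `dLk = 0`.)
#'
#' @param x an `equilibrium_shape` from [minimize_shape()].
#' @param ... unused.
#' @return one-row tibble with the global-minimum energies, writhe,
#'   relaxation metrics, contact summary and convergence flag.
#' @export
glance.equilibrium_shape <- function(x, ...) {
  tibble::tibble(dLk = x$dLk, regime = x$regime, start = x$start,
                 energy_bend = x$energy_bend, energy_twist = x$energy_twist,
                 energy_total = x$energy_total,
                 penalty_residual = x$penalty_residual,
                 writhe = x$writhe,
                 wr_fraction = if (x$dLk != 0) x$writhe / x$dLk else NA_real_,
                 twist_relaxation = if (x$dLk != 0) {
                   1 - ((x$dLk - x$writhe) / x$dLk)^2
                 } else NA_real_,
                 n_contacts = x$n_contacts,
                 contact_type = x$contact_type,
                 min_distance = x$min_distance, converged = x$converged,
                 seed = x$seed)
}

#' Tidy a hydrodynamic-thickness calibration
#'
#' @param x a `dh_calibration` from [calibrate_dh()].
#' @param ... unused.
#' @return the per-measurement residual table.
#' @export
tidy.dh_calibration <- function(x, ...) x$residuals

#' Summarize a hydrodynamic-thickness calibration
#'
#' @param x a `dh_calibration` from [calibrate_dh()].
#' @param ... unused.
#' @export
glance.dh_calibration <- function(x, ...) {
  tibble::tibble(dh = x$dh, rss = x$rss, n = nrow(x$residuals))
}

#' Tidy a pipeline report
#'
#' @param x a `pipeline_report` from [run_pipeline()].
#' @param ... unused.
#' @return the per-species prediction table.
#' @export
tidy.pipeline_report <- function(x, ...) x$species

#' Summarize a pipeline report
#'
#' @param x a `pipeline_report` from [run_pipeline()].
#' @param ... unused.
#' @return the dominant-species headline row with the seed and reference
#'   radius attached.
#' @export
glance.pipeline_report <- function(x, ...) {
  dplyr::mutate(x$headline, Rh0 = x$Rh0, seed = x$seed,
                length_bp = x$config$length_bp)
}
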