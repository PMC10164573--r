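#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Curvature profile of an equilibrium shape
#'
#' Curvature along the loop (position measured around the centerline), with
#' the constant open-circle curvature `2 pi / L` as a reference line.
#'
#' @param object an `equilibrium_shape`.
#' @param n_samples samples along the loop.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.equilibrium_shape <- function(object, n_samples = 256L, ...) {
  prof <- curvature_profile(object$curve, n_samples)
  L <- arclength(object$curve)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$position, y = .data$kappa)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 2 * pi / L, linetype = "dashed") +
    ggplot2::labs(x = "position along loop",
                  y = expression(kappa ~ (ring(A)^-1)),
                  title = sprintf("dLk = %+.2f, Wr = %+.2f", object$dLk,
                                  object$writhe)) +
    ggplot2::theme_minimal()
}

#' Writhe of minimizing shapes against the linking-number deficit
#'
#' @param object a `writhe_dlk_curve` from [writhe_vs_dlk_curve()].
#' @param ... unused.
#' @return a ggplot of `|Wr|` against `|dLk|` coloured by stability regime.
#' @export
autoplot.writhe_dlk_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = abs(.data$dLk), y = abs(.data$writhe),
                               colour = .data$regime)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey40") +
    ggplot2::labs(x = "|dLk| (turns)", y = "|Wr|") +
    ggplot2::theme_minimal()
}

#' Diffusion against sedimentation for a pipeline report
#'
#' @param object a `pipeline_report`.
#' @param ... unused.
#' @return a ggplot of predicted D against s, one point per species.
#' @export
autoplot.pipeline_report <- function(object, ...) {
  ggplot2::ggplot(object$species,
                  ggplot2::aes(x = .data$s, y = .data$D,
                               label = .data$dLk_nominal)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "s (S)", y = expression(D ~ (mu * m^2 / s)),
                  title = sprintf("%d bp minicircle predictions",
                                  object$config$length_bp)) +
    ggplot2::theme_minimal()
}

#' Planar projections of a centerline
#'
#' Quick diagnostic rendering of a 3-D shape as its three coordinate-plane
#' projections.
#'
#' @param curve a [closed_curve()].
#' @param n_samples samples along the loop.
#' @return a ggplot with one facet per projection plane.
#' @export
plot_curve_projections <- function(curve, n_samples = 256L) {
  t <- seq(0, 1, length.out = n_samples + 1L)
  r <- curve_eval(curve, t, 0L)
  df <- dplyr::bind_rows(
    tibble::tibble(plane = "x-y", u = r[, 1], v = r[, 2]),
    tibble::tibble(plane = "x-z", u = r[, 1], v = r[, 3]),
    tibble::tibble(plane = "y-z", u = r[, 2], v = r[, 3]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~plane) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
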