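#' Read and write centerline curves
#'
#' CSV curves are three columns `x,y,z` in Angstrom, one row per control
#' point, closed implicitly. JSON curves are records
#' `{control_points, length_bp, dLk, labels}`.
#'
#' @param curve a [closed_curve()].
#' @param path file path.
#' @name curve_io
NULL

#' @rdname curve_io
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(is_closed_curve(curve))
  utils::write.csv(as.data.frame(curve$control_points), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname curve_io
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(df))) {
    stop("curve CSV needs columns x, y, z.", call. = FALSE)
  }
  closed_curve(as.matrix(df[, c("x", "y", "z")]))
}

#' @rdname curve_io
#' @param length_bp,dLk,labels optional metadata stored in the JSON record.
#' @export
write_curve_json <- function(curve, path, length_bp = NULL, dLk = NULL,
                             labels = NULL) {
  stopifnot(is_closed_curve(curve))
  rec <- list(control_points = unname(apply(curve$control_points, 1,
                                            as.numeric, simplify = FALSE)),
              length_bp = length_bp, dLk = dLk, labels = labels)
  jsonlite::write_json(rec[!vapply(rec, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname curve_io
#' @export
read_curve_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  cp <- rec$control_points
  if (is.list(cp)) cp <- do.call(rbind, cp)
  curve <- closed_curve(cp)
  attr(curve, "length_bp") <- rec$length_bp
  attr(curve, "dLk") <- rec$dLk
  attr(curve, "labels") <- rec$labels
  curve
}

#' Export a bead model or centerline as pseudo-atoms
#'
#' `write_beads_pdb()` writes one HETATM pseudo-atom per bead with the bead
#' diameter in the occupancy column; `write_beads_xyz()` writes plain XYZ.
#' Both accept a [build_bead_model()] or a [closed_curve()] (sampled at
#' `n_beads` points with zero diameter).
#'
#' @param x a `bead_model` or `closed_curve`.
#' @param path output file.
#' @param n_beads sampling used when `x` is a curve.
#' @name bead_export
NULL

bead_centers <- function(x, n_beads) {
  if (inherits(x, "bead_model")) {
    list(centers = x$centers, dh = x$dh)
  } else if (is_closed_curve(x)) {
    t <- seq(0, 1, length.out = n_beads + 1L)[-(n_beads + 1L)]
    list(centers = curve_eval(x, t, 0L), dh = 0)
  } else stop("expected a bead_model or closed_curve.", call. = FALSE)
}

#' @rdname bead_export
#' @export
write_beads_pdb <- function(x, path, n_beads = 100L) {
  bc <- bead_centers(x, n_beads)
  ctr <- bc$centers
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK  bead centerline model; occupancy = bead diameter (Angstrom)",
             con)
  for (i in seq_len(nrow(ctr))) {
    writeLines(sprintf(
      "HETATM%5d  C   DNA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      i, i, ctr[i, 1], ctr[i, 2], ctr[i, 3], bc$dh, 0), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname bead_export
#' @export
write_beads_xyz <- function(x, path, n_beads = 100L) {
  bc <- bead_centers(x, n_beads)
  ctr <- bc$centers
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(ctr)), con)
  writeLines(sprintf("bead centerline, diameter %.2f Angstrom", bc$dh), con)
  writeLines(sprintf("C %12.4f %12.4f %12.4f", ctr[, 1], ctr[, 2], ctr[, 3]),
             con)
  invisible(path)
}
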