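#' Configuration of the Monte Carlo shape minimizer
#'
#' Controls the simulated-annealing search for elastic-energy minimizing
#' shapes. Defaults follow the reference computation: 16 spline nodes with
#' enforced two-fold (dihedral subgroup) symmetry, 200 segments for the
#' writhe, and `ceiling(20 L / d_s)` steric sample points.
#'
#' @param n_nodes spline control points (even; default 16).
#' @param enforce_symmetry constrain the shape to be invariant under a
#'   two-fold rotation (the symmetry of the figure-8/interwound family);
#'   halves the number of free nodes.
#' @param n_writhe_segments segments for the writhe evaluation (default 200).
#' @param n_steric_samples points used to track self-intersections; default
#'   `ceiling(20 L / d_s)` (capped at 1200).
#' @param n_energy_samples quadrature points for the bending integral.
#' @param steric_penalty_weight final quadratic penalty weight
#'   (kB T / Angstrom^2) for pair overlaps below `d_s`; ramped up tenfold
#'   over the annealing stages.
#' @param mc_steps total Monte Carlo proposals per start.
#' @param n_stages annealing stages.
#' @param t_start,t_end start/end Metropolis temperatures (kB T).
#' @param step_start,step_end proposal standard deviation as a fraction of
#'   the loop radius `L / 2 pi`.
#' @param quench_maxit iterations of the final local (Nelder-Mead) quench.
#' @param rng_seed integer seed; fixed seed gives bit-reproducible shapes.
#' @return an object of class `minimizer_config`.
#' @export
minimizer_config <- function(n_nodes = 16L, enforce_symmetry = TRUE,
                             n_writhe_segments = 200L,
                             n_steric_samples = NULL,
                             n_energy_samples = 200L,
                             steric_penalty_weight = 50,
                             mc_steps = 1200L, n_stages = 5L,
                             t_start = 1.0, t_end = 0.005,
                             step_start = 0.08, step_end = 0.004,
                             quench_maxit = 200L, rng_seed = 1L) {
  stopifnot(n_nodes >= 8L, n_nodes %% 2L == 0L, n_writhe_segments >= 16L,
            n_energy_samples >= 32L, mc_steps > 0L, n_stages >= 2L,
            steric_penalty_weight >= 0, t_start > t_end, t_end > 0,
            step_start >= step_end, step_end > 0, quench_maxit >= 0L)
  structure(list(n_nodes = as.integer(n_nodes),
                 enforce_symmetry = isTRUE(enforce_symmetry),
                 n_writhe_segments = as.integer(n_writhe_segments),
                 n_steric_samples = n_steric_samples,
                 n_energy_samples = as.integer(n_energy_samples),
                 steric_penalty_weight = steric_penalty_weight,
                 mc_steps = as.integer(mc_steps),
                 n_stages = as.integer(n_stages),
                 t_start = t_start, t_end = t_end,
                 step_start = step_start, step_end = step_end,
                 quench_maxit = as.integer(quench_maxit),
                 rng_seed = as.integer(rng_seed)),
            class = "minimizer_config")
}

#' Study-scale minimizer settings
#'
#' The configuration used for the package's study-scale computations
#' (reference shape predictions and the reproduction scripts): the published
#' discretization for shape and writhe (16 nodes, 200 writhe segments) with
#' a contact-tracking grid of 400 points and a step budget sized so one
#' minimization completes in a few minutes on one core.
#'
#' @param seed RNG seed.
#' @return a [minimizer_config()].
#' @export
study_minimizer_config <- function(seed = 1L) {
  minimizer_config(n_nodes = 16L, n_writhe_segments = 200L,
                   n_energy_samples = 160L, n_steric_samples = 400L,
                   mc_steps = 1200L, quench_maxit = 200L, rng_seed = seed)
}

## Two-fold symmetry operation: rotation by pi about the y axis. The seed
## circle (x-z plane) and the figure-8 family are invariant under
## p(t + 1/2) = S p(t).
.SYM <- diag(c(-1, 1, -1))

## Build the full control polygon from the free nodes.
expand_nodes <- function(free, symmetric) {
  if (symmetric) rbind(free, free %*% .SYM) else free
}

## Non-adjacent pair index sets for a closed polygon of n vertices, in
## stats::dist condensed order; `keep` marks pairs whose contour separation
## exceeds `exclusion`.
steric_pairs <- function(n, L, exclusion) {
  ii <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  gap <- jj - ii
  cyc <- pmin(gap, n - gap)
  cyc * (L / n) > exclusion
}

## Penalized dimensionless objective for the minimizer. Returns a closure
## over the problem constants; the closure takes the free-node vector and
## a steric weight and returns the energy decomposition.
make_objective <- function(dLk, params, config) {
  n <- config$n_nodes
  m <- if (config$enforce_symmetry) n %/% 2L else n
  L <- params$L; P <- params$P; om <- params$omega; ds <- params$ds
  n_en <- config$n_energy_samples
  n_wr <- config$n_writhe_segments
  ## contact tracking grid: 20 L / d_s sample points, capped -- beyond a
  ## spacing of ~d_s/10 further refinement changes the penalty negligibly
  n_st <- config$n_steric_samples %||% min(600L, as.integer(ceiling(20 * L / ds)))
  keep <- steric_pairs(n_st, L, 2 * ds)
  t_en <- seq(0, 1, length.out = n_en + 1L)[-(n_en + 1L)]
  t_wr <- seq(0, 1, length.out = n_wr + 1L)[-(n_wr + 1L)]
  t_st <- seq(0, 1, length.out = n_st + 1L)[-(n_st + 1L)]
  tk <- seq(0, 1, length.out = n + 1L)

  function(free_vec, w_steric) {
    cp <- expand_nodes(matrix(free_vec, ncol = 3L), config$enforce_symmetry)
    sfx <- stats::splinefun(tk, c(cp[, 1L], cp[1L, 1L]), method = "periodic")
    sfy <- stats::splinefun(tk, c(cp[, 2L], cp[1L, 2L]), method = "periodic")
    sfz <- stats::splinefun(tk, c(cp[, 3L], cp[1L, 3L]), method = "periodic")
    x1 <- sfx(t_en, 1L); y1 <- sfy(t_en, 1L); z1 <- sfz(t_en, 1L)
    x2 <- sfx(t_en, 2L); y2 <- sfy(t_en, 2L); z2 <- sfz(t_en, 2L)
    sp2 <- x1 * x1 + y1 * y1 + z1 * z1
    speed <- sqrt(sp2)
    len <- mean(speed) # periodic rectangle rule (spectrally accurate)
    sc <- L / len      # rescale the candidate to the prescribed length
    crx <- y1 * z2 - z1 * y2
    cry <- z1 * x2 - x1 * z2
    crz <- x1 * y2 - y1 * x2
    kappa <- sqrt(crx * crx + cry * cry + crz * crz) / (sp2 * speed) / sc
    bend <- (P / 2) * mean(kappa * kappa * speed) * sc
    wr <- polygon_writhe(cbind(sfx(t_wr), sfy(t_wr), sfz(t_wr)))
    twist <- 2 * pi^2 * om * P * (dLk - wr)^2 / L
    ## steric penalty on the rescaled curve
    dd <- stats::dist(sc * cbind(sfx(t_st), sfy(t_st), sfz(t_st)))
    viol <- keep & (dd < ds)
    pen <- if (any(viol)) w_steric * sum((ds - dd[viol])^2) else 0
    ## tube self-overlap through curvature: radius of curvature >= d_s / 2
    kex <- pmax(kappa - 2 / ds, 0)
    pen <- pen + w_steric * L * mean(kex * kex * speed * sc) * ds^2
    list(value = bend + twist + pen, bend = bend, twist = twist,
         writhe = wr, penalty = pen, scale = sc)
  }
}

## Seed configurations (control polygons) for the two starts.
start_nodes <- function(start, dLk, params, config) {
  n <- config$n_nodes
  curve <- switch(start,
    circle = build_circle(params$L, n),
    figure8 = figure8_curve(params$L, separation = 1.5 * params$ds,
                            n_nodes = n,
                            handedness = if (dLk < 0) -1 else 1))
  cp <- curve$control_points
  m <- if (config$enforce_symmetry) n %/% 2L else n
  cp[seq_len(m), , drop = FALSE]
}

#' Elastic-energy minimizing shape at a given linking-number deficit
#'
#' Searches for the lowest-energy closed-rod shape at deficit `dLk` by
#' simulated annealing of the spline control points from two starts (flat
#' circle and analytic figure-8), followed by a local Nelder-Mead quench,
#' under a prescribed-length constraint (exact rescaling) and a ramped
#' quadratic steric penalty. In the multistable band both branches are
#' retained in the `branches` table. Deterministic for a fixed
#' `config$rng_seed`.
#'
#' @param dLk linking-number deficit (turns; fractional part retained).
#' @param params an [elastic_params()].
#' @param config a [minimizer_config()].
#' @param length_bp,helical_repeat optional base-pair bookkeeping used to
#'   attach a [topology_state()] to the result.
#' @return an object of class `equilibrium_shape`: fields `curve`,
#'   `dLk`, `topology` (or `NULL`), `energy_bend`, `energy_twist`,
#'   `energy_total`, `penalty_residual` (kB T), `writhe`, `n_contacts`,
#'   `contact_type`, `min_distance`, `regime`, `converged`, `seed`,
#'   and a `branches` tibble (one row per optimization start plus the
#'   analytic flat circle).
#' @export
minimize_shape <- function(dLk, params, config = minimizer_config(),
                           length_bp = NULL, helical_repeat = 10.42) {
  stopifnot(inherits(params, "elastic_params"),
            inherits(config, "minimizer_config"), is.finite(dLk))
  regime <- stability_regime(dLk, params)
  if (regime == "circle_only") {
    return(circle_shape(dLk, params, config, length_bp, helical_repeat))
  }
  obj <- make_objective(dLk, params, config)
  R <- params$L / (2 * pi)

  run_start <- function(start, do_quench = TRUE) {
    free <- start_nodes(start, dLk, params, config)
    x <- as.vector(free)
    w_final <- config$steric_penalty_weight
    stages <- config$n_stages
    temps <- exp(seq(log(config$t_start), log(config$t_end), length.out = stages))
    sigmas <- R * exp(seq(log(config$step_start), log(config$step_end),
                          length.out = stages))
    weights <- w_final / 10^seq(1, 0, length.out = stages)
    per_stage <- ceiling(config$mc_steps / stages)
    m <- length(x) / 3L
    cur <- obj(x, weights[1L])
    best_x <- x
    best_final <- obj(x, w_final)$value
    for (s in seq_len(stages)) {
      w <- weights[s]; Tm <- temps[s]; sg <- sigmas[s]
      cur <- obj(x, w)
      for (k in seq_len(per_stage)) {
        node <- sample.int(m, 1L)
        prop <- x
        idx <- node + c(0L, m, 2L * m)
        prop[idx] <- prop[idx] + stats::rnorm(3L, sd = sg)
        cand <- obj(prop, w)
        if (cand$value < cur$value ||
            stats::runif(1L) < exp((cur$value - cand$value) / Tm)) {
          x <- prop; cur <- cand
        }
      }
      vf <- obj(x, w_final)$value
      if (vf < best_final) { best_final <- vf; best_x <- x }
    }
    last_gain <- Inf
    if (do_quench && config$quench_maxit > 0L) {
      ## gradient quench: the descent from a writhed start to the interwound
      ## minimum is barrier-free, so quasi-Newton iterations do the heavy
      ## lifting; repeated cycles restart the quench until the energy stops
      ## improving, which doubles as the convergence criterion.
      for (cyc in 1:3) {
        opt <- stats::optim(best_x, function(p) obj(p, w_final)$value,
                            method = "BFGS",
                            control = list(maxit = config$quench_maxit,
                                           reltol = 1e-12))
        last_gain <- best_final - opt$value
        if (opt$value < best_final) { best_final <- opt$value; best_x <- opt$par }
        if (last_gain < 1e-6 * max(1, abs(best_final))) break
      }
    }
    fin <- obj(best_x, w_final)
    list(start = start, x = best_x, value = fin$value, bend = fin$bend,
         twist = fin$twist, writhe = fin$writhe, penalty = fin$penalty,
         scale = fin$scale,
         converged = fin$penalty < 1e-2 &&
           last_gain <= 1e-4 * max(1, abs(best_final)))
  }

  results <- withr_seed(config$rng_seed, function() {
    if (regime == "writhed_only") {
      ## above Lk_max the flat circle is not even a local equilibrium: the
      ## circle start contributes exploration only, so quench it only when
      ## its annealed state undercuts the quenched figure-8 branch
      r8 <- run_start("figure8")
      rc <- run_start("circle", do_quench = FALSE)
      if (rc$value < r8$value) rc <- run_start("circle")
      list(rc, r8)
    } else {
      lapply(c("circle", "figure8"), run_start)
    }
  })

  ## analytic flat-circle branch (admissible below Lk_max)
  circ_E <- flat_circle_energy(dLk, params)
  branches <- dplyr::bind_rows(
    purrr::map_dfr(results, function(r) {
      tibble::tibble(start = r$start, energy_bend = r$bend,
                     energy_twist = r$twist,
                     energy_total = r$bend + r$twist,
                     writhe = r$writhe, penalty = r$penalty)
    }),
    tibble::tibble(start = "flat_circle_analytic",
                   energy_bend = circ_E$bend, energy_twist = circ_E$twist,
                   energy_total = circ_E$bend + circ_E$twist,
                   writhe = 0, penalty = 0))

  vals <- vapply(results, function(r) r$value, numeric(1))
  best <- results[[which.min(vals)]]
  if (regime == "multistable" && circ_E$bend + circ_E$twist < min(vals)) {
    ## the circle is the global minimum: return it, keep the writhed branch
    out <- circle_shape(dLk, params, config, length_bp, helical_repeat)
    out$branches <- branches
    return(out)
  }
  if (!best$converged) {
    warning("minimizer did not meet the convergence criteria; ",
            "returning the best shape found.", call. = FALSE)
  }

  cp <- expand_nodes(matrix(best$x, ncol = 3L), config$enforce_symmetry)
  cp <- cp * best$scale
  cp <- sweep(cp, 2, colMeans(cp))
  curve <- closed_curve(cp)
  contact <- classify_contacts(curve, params, config)
  topo <- if (!is.null(length_bp)) {
    topology_state(length_bp, helical_repeat, dLk = dLk, Wr = best$writhe)
  }
  structure(list(curve = curve, dLk = dLk, topology = topo,
                 energy_bend = best$bend, energy_twist = best$twist,
                 energy_total = best$bend + best$twist,
                 penalty_residual = best$penalty, writhe = best$writhe,
                 n_contacts = contact$n_contacts,
                 contact_type = contact$type,
                 min_distance = contact$min_distance,
                 regime = regime, converged = best$converged,
                 seed = config$rng_seed, start = best$start,
                 branches = branches),
            class = "equilibrium_shape")
}

## Closed-form energy decomposition of the flat circle at deficit dLk.
flat_circle_energy <- function(dLk, params) {
  list(bend = 2 * pi^2 * params$P / params$L,
       twist = 2 * pi^2 * params$omega * params$P * dLk^2 / params$L)
}

## Equilibrium-shape record for the analytic flat circle (no search needed).
circle_shape <- function(dLk, params, config = minimizer_config(),
                         length_bp = NULL, helical_repeat = 10.42) {
  E <- flat_circle_energy(dLk, params)
  curve <- build_circle(params$L, config$n_nodes)
  topo <- if (!is.null(length_bp)) {
    topology_state(length_bp, helical_repeat, dLk = dLk, Wr = 0)
  }
  structure(list(curve = curve, dLk = dLk, topology = topo,
                 energy_bend = E$bend, energy_twist = E$twist,
                 energy_total = E$bend + E$twist, penalty_residual = 0,
                 writhe = 0, n_contacts = 0L, contact_type = "none",
                 min_distance = Inf,
                 regime = stability_regime(dLk, params), converged = TRUE,
                 seed = config$rng_seed, start = "flat_circle_analytic",
                 branches = tibble::tibble(
                   start = "flat_circle_analytic", energy_bend = E$bend,
                   energy_twist = E$twist, energy_total = E$bend + E$twist,
                   writhe = 0, penalty = 0)),
            class = "equilibrium_shape")
}

## Count self-contact regions of a tube of diameter d_s around the curve.
classify_contacts <- function(curve, params, config) {
  n <- config$n_steric_samples %||%
    min(1200L, as.integer(ceiling(20 * params$L / params$ds)))
  s <- curve_samples(curve, n)
  L <- mean(s$speed)
  dm <- as.matrix(stats::dist(s$r))
  gap <- abs(outer(seq_len(n), seq_len(n), "-"))
  cyc <- pmin(gap, n - gap)
  dm[cyc * (L / n) <= 2 * params$ds] <- Inf
  dmin <- min(dm)
  thr <- params$ds * 1.10
  near <- apply(dm, 1L, min) < thr
  if (!any(near)) {
    return(list(n_contacts = 0L, type = "none", min_distance = dmin))
  }
  ## contiguous cyclic runs of contacting samples
  r <- rle(near)
  n_runs <- sum(r$values)
  if (near[1L] && near[n] && n_runs > 1L) n_runs <- n_runs - 1L
  max_run <- max(r$lengths[r$values])
  extent <- max_run * L / n
  type <- if (extent > 3 * params$ds) "line" else "point"
  ## contacts pair up two arcs touching each other
  list(n_contacts = max(1L, n_runs %/% 2L), type = type, min_distance = dmin)
}

#' @export
print.equilibrium_shape <- function(x, ...) {
  cat(sprintf(
    "<equilibrium_shape: dLk = %+.2f, regime = %s, start = %s>\n",
    x$dLk, x$regime, x$start))
  cat(sprintf(
    "  E = %.2f kT (bend %.2f + twist %.2f), Wr = %+.3f, contacts: %d (%s)\n",
    x$energy_total, x$energy_bend, x$energy_twist, x$writhe, x$n_contacts,
    x$contact_type))
  if (!x$converged) cat("  [not converged]\n")
  invisible(x)
}

#' Writhe and energies of minimizing shapes across a deficit grid
#'
#' Runs the shape minimizer over a grid of linking-number deficits and
#' tabulates the writhe and energy decomposition of the global minimum at
#' each deficit. Below the critical deficit the flat circle is returned
#' without a search.
#'
#' @param params an [elastic_params()].
#' @param dlk_grid numeric vector of deficits.
#' @param config a [minimizer_config()].
#' @return a tibble with one row per deficit: `dLk`, `regime`, `writhe`,
#'   `energy_bend`, `energy_twist`, `energy_total`, `n_contacts`,
#'   `contact_type`, `converged`. Class `writhe_dlk_curve`.
#' @export
writhe_vs_dlk_curve <- function(params, dlk_grid, config = minimizer_config()) {
  rows <- purrr::map_dfr(dlk_grid, function(d) {
    sh <- minimize_shape(d, params, config)
    tibble::tibble(dLk = d, regime = sh$regime, writhe = sh$writhe,
                   energy_bend = sh$energy_bend,
                   energy_twist = sh$energy_twist,
                   energy_total = sh$energy_total,
                   n_contacts = sh$n_contacts,
                   contact_type = sh$contact_type,
                   converged = sh$converged)
  })
  class(rows) <- c("writhe_dlk_curve", class(rows))
  rows
}
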