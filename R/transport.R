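#' Molecular specification of an analyte
#'
#' @param molar_mass_kDa anhydrous molar mass in kDa.
#' @param psv_ml_g (apparent) partial specific volume in ml/g.
#' @param label sample label.
#' @return an object of class `molecular_spec`.
#' @export
molecular_spec <- function(molar_mass_kDa, psv_ml_g = 0.482, label = "") {
  stopifnot(molar_mass_kDa > 0, psv_ml_g > 0, psv_ml_g < 1.5)
  structure(list(M_kDa = molar_mass_kDa, vbar = psv_ml_g, label = label),
            class = "molecular_spec")
}

#' Diffusion coefficient from the hydrodynamic radius
#'
#' Stokes-Einstein relation `D = kB T / (6 pi eta R_h)`.
#'
#' @param Rh hydrodynamic radius in Angstrom.
#' @param env a [hydro_environment()].
#' @return diffusion coefficient in um^2/s.
#' @export
#' @examples
#' diffusion_from_rh(129.9)  # 16.1 um^2/s in the AUC buffer
diffusion_from_rh <- function(Rh, env = hydro_environment()) {
  stopifnot(all(Rh > 0))
  D <- .kB * env$T / (6 * pi * env$eta * Rh * .ANGSTROM) # m^2/s
  D * 1e12
}

#' Hydrodynamic radius from the diffusion coefficient
#'
#' Exact inverse of [diffusion_from_rh()].
#'
#' @param D diffusion coefficient in um^2/s.
#' @param env a [hydro_environment()].
#' @return hydrodynamic radius in Angstrom.
#' @export
rh_from_diffusion <- function(D, env = hydro_environment()) {
  stopifnot(all(D > 0))
  .kB * env$T / (6 * pi * env$eta * D * 1e-12) / .ANGSTROM
}

#' Sedimentation coefficient from the Svedberg relation
#'
#' `s = M (1 - vbar rho) D / (N kB T)`, reported in svedbergs
#' (1 S = 1e-13 s).
#'
#' @param D diffusion coefficient in um^2/s.
#' @param spec a [molecular_spec()].
#' @param env a [hydro_environment()].
#' @return sedimentation coefficient in S.
#' @export
#' @examples
#' svedberg_s(17.2, molecular_spec(207.576))  # 7.5 S
svedberg_s <- function(D, spec, env = hydro_environment()) {
  stopifnot(inherits(spec, "molecular_spec"), all(D > 0))
  buoy <- 1 - spec$vbar * env$rho
  if (buoy <= 0) {
    stop("vbar * rho >= 1: the particle is neutrally buoyant or floats.",
         call. = FALSE)
  }
  M <- spec$M_kDa * 1000 # g/mol
  s <- M * 1e-3 * buoy * (D * 1e-12) / (.NA * .kB * env$T) # seconds
  s / 1e-13
}

#' Apparent partial specific volume from measured s and D
#'
#' Rearranged Svedberg relation
#' `vbar' = (1/rho) (1 - N s kB T / (M D))`; the exact algebraic inverse of
#' [svedberg_s()]. "Apparent" because counterion binding is unresolved: the
#' value is only constant for one solvent at fixed temperature and pressure.
#'
#' @param s sedimentation coefficient in S.
#' @param D diffusion coefficient in um^2/s.
#' @param spec a [molecular_spec()] (only the molar mass is used).
#' @param env a [hydro_environment()].
#' @return apparent PSV in ml/g.
#' @export
apparent_psv <- function(s, D, spec, env = hydro_environment()) {
  stopifnot(inherits(spec, "molecular_spec"), all(s > 0), all(D > 0))
  M <- spec$M_kDa * 1000
  arg <- 1 - .NA * (s * 1e-13) * .kB * env$T / (M * 1e-3 * D * 1e-12)
  if (any(arg <= 0)) {
    warning("non-physical apparent PSV (s/D too large for this molar mass).",
            call. = FALSE)
  }
  arg / env$rho
}

#' Frictional ratio
#'
#' Anisotropy measure `f/f0 = Rh / R0`, where `R0 = (3 M vbar / (4 pi N))^(1/3)`
#' is the radius of the sphere holding the analyte's PSV-defined volume.
#' Equals 1 for a sphere and exceeds 1 for any non-spherical shape.
#'
#' @param Rh hydrodynamic radius in Angstrom.
#' @param spec a [molecular_spec()].
#' @return dimensionless frictional ratio.
#' @export
frictional_ratio <- function(Rh, spec) {
  stopifnot(inherits(spec, "molecular_spec"), all(Rh > 0))
  M <- spec$M_kDa * 1000            # g/mol
  vol <- M * spec$vbar / .NA        # ml = cm^3 per molecule
  R0 <- (3 * vol / (4 * pi))^(1 / 3) * 1e-2 / .ANGSTROM # cm -> Angstrom
  Rh / R0
}

#' Correct s and D to standard conditions (water, 20 C)
#'
#' `s_20w = s_TB (1 - vbar rho)_20w / (1 - vbar rho)_TB * eta_TB / eta_20w`
#' and `D_20w = D_TB (T20 / T) (eta_TB / eta_20w)`, with water-at-20C
#' constants eta = 1.0016 cP and rho = 0.99823 g/ml. The identity when the
#' experimental conditions already are water at 20 C.
#'
#' @param s_TB,D_TB observed values (S, um^2/s).
#' @param env_TB experimental conditions, a [hydro_environment()].
#' @param vbar partial specific volume in ml/g (assumed condition
#'   independent for the correction).
#' @return a one-row tibble: `s_20w` (S), `D_20w` (um^2/s).
#' @export
standard_conditions <- function(s_TB, D_TB, env_TB = hydro_environment(),
                                vbar = 0.482) {
  stopifnot(all(s_TB > 0), all(D_TB > 0), vbar > 0)
  visc <- env_TB$eta_cP / .eta_20w_cP
  s20 <- s_TB * (1 - vbar * .rho_20w) / (1 - vbar * env_TB$rho) * visc
  D20 <- D_TB * (293.15 / env_TB$T) * visc
  tibble::tibble(s_20w = s20, D_20w = D20)
}

#' Transport observables from a hydrodynamic radius
#'
#' Bundles the Stokes-Einstein, Svedberg and frictional-ratio conversions
#' into a single prediction record.
#'
#' @param Rh hydrodynamic radius in Angstrom.
#' @param spec a [molecular_spec()].
#' @param env a [hydro_environment()].
#' @return a one-row tibble: `Rh` (Angstrom), `D` (um^2/s), `s` (S),
#'   `f_over_f0`, `vbar`, `label`.
#' @export
transport_predict <- function(Rh, spec, env = hydro_environment()) {
  D <- diffusion_from_rh(Rh, env)
  tibble::tibble(Rh = Rh, D = D, s = svedberg_s(D, spec, env),
                 f_over_f0 = frictional_ratio(Rh, spec),
                 vbar = spec$vbar, label = spec$label)
}

#' Published AUC summary for the 336/672 bp minicircle study
#'
#' Measured and predicted sedimentation-velocity observables for the
#' minicircle samples in the AUC buffer (eta = 1.02667 cP, rho = 1.00682
#' g/ml, 20 C): diffusion and sedimentation coefficients per sample
#' (predicted values refer to the dominant topoisomer of each mixture) and
#' the per-sample apparent PSV. Used as calibration and cross-check inputs.
#'
#' @return a tibble with columns `sample`, `length_bp`, `topology`,
#'   `dLk_dominant` (nominal, NA for linear), `D_predicted`, `D_measured`
#'   (um^2/s), `s_predicted`, `s_measured` (S), `psv` (ml/g).
#' @export
minicircle_auc_table <- function() {
  tibble::tibble(
    sample = c("336 linear", "336 relaxed", "336 nicked", "336 supercoiled",
               "336 hypernegatively supercoiled", "672 nicked",
               "672 supercoiled"),
    length_bp = c(336L, 336L, 336L, 336L, 336L, 672L, 672L),
    topology = c("linear", "relaxed", "nicked", "supercoiled",
                 "hypernegative", "nicked", "supercoiled"),
    dLk_dominant = c(NA, 0, 0, -3, -6, 0, -4),
    D_predicted = c(14.7, 17.2, 17.2, 20.5, 21.9, 9.9, 12.4),
    D_measured = c(14.5, 16.2, 16.1, 19.0, 20.1, 10.3, 12.5),
    s_predicted = c(6.4, 7.5, 7.5, 9.0, 9.6, 8.7, 10.9),
    s_measured = c(6.40, 7.26, 7.25, 8.28, 8.89, 8.77, 10.72),
    psv = c(0.479, 0.470, 0.469, 0.488, 0.479, 0.495, 0.494))
}

#' Molar masses of the study minicircles
#'
#' Sequence-derived anhydrous molar masses: 207.576 kDa (336 bp) and
#' 415.152 kDa (672 bp).
#'
#' @param length_bp 336 or 672.
#' @return molar mass in kDa.
#' @export
minicircle_molar_mass <- function(length_bp) {
  m <- c(`336` = 207.576, `672` = 415.152)
  key <- as.character(length_bp)
  if (!all(key %in% names(m))) {
    ## scale from the 336 bp sequence mass for other lengths
    return(207.576 / 336 * length_bp)
  }
  unname(m[key])
}
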