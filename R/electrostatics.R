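#' Electrostatic screening parameters
#'
#' Inputs for the order-of-magnitude electrostatic estimates that justify the
#' stiff-beam treatment of minicircles: ionic strength, the Debye-length
#' prefactor `kappa0` (`1/R_D = kappa0 sqrt(Cs)`), the Bjerrum length, the
#' charge content of the loop, and the intrinsic persistence length.
#'
#' @param ionic_strength_Cs molar ionic strength (mol/l).
#' @param kappa0 Debye prefactor in 1/Angstrom * sqrt(l/mol) (default 0.329).
#' @param bjerrum_length_lB Bjerrum length in Angstrom (default 7.1, water at
#'   about 20 C).
#' @param charge_q charge per site in elementary charges (default 1).
#' @param n_charges_N number of charged sites (two per base pair for DNA).
#' @param intrinsic_P_in intrinsic persistence length in Angstrom
#'   (default 500).
#' @return an object of class `electrostatic_params`.
#' @export
electrostatic_params <- function(ionic_strength_Cs, kappa0 = 0.329,
                                 bjerrum_length_lB = 7.1, charge_q = 1,
                                 n_charges_N = NULL, intrinsic_P_in = 500) {
  if (!is.numeric(ionic_strength_Cs) || ionic_strength_Cs <= 0) {
    stop("ionic strength must be positive.", call. = FALSE)
  }
  stopifnot(kappa0 > 0, bjerrum_length_lB > 0, intrinsic_P_in > 0)
  structure(list(Cs = ionic_strength_Cs, kappa0 = kappa0,
                 lB = bjerrum_length_lB, q = charge_q, N = n_charges_N,
                 P_in = intrinsic_P_in),
            class = "electrostatic_params")
}

#' Debye screening length
#'
#' Ionic-strength-based estimate `R_D = 1 / (kappa0 sqrt(Cs))`.
#'
#' @param params an [electrostatic_params()].
#' @return Debye length in Angstrom.
#' @export
#' @examples
#' debye_length(electrostatic_params(0.23))  # 6.34 A
debye_length <- function(params) {
  stopifnot(inherits(params, "electrostatic_params"))
  1 / (params$kappa0 * sqrt(params$Cs))
}

#' Total and electrostatic persistence length
#'
#' Odijk-Skolnick-Fixman electrostatic persistence length
#' `P_el = R_D^2 / (4 lB)` added to the intrinsic part, `P = P_in + P_el`.
#'
#' @param params an [electrostatic_params()].
#' @return a one-row tibble: `R_D`, `P_el`, `P_total` (Angstrom).
#' @export
persistence_length <- function(params) {
  stopifnot(inherits(params, "electrostatic_params"))
  RD <- debye_length(params)
  Pel <- RD^2 / (4 * params$lB)
  tibble::tibble(R_D = RD, P_el = Pel, P_total = params$P_in + Pel)
}

#' Effective bending and twisting energy scales of a circular loop
#'
#' Scaling estimates of the elastic energy stored in a circular loop:
#' `E_bend = 4 pi^2 P / L` and `E_twist = 6 pi^2 dLk^2 P / L`, both in units
#' of kB T. `P` and `L` may be given in the same unit (base pairs or
#' Angstrom); only their ratio enters. These diagnostic scales exceed kB T by
#' an order of magnitude for minicircles of a few hundred bp, which is what
#' licenses treating the minimal-energy shape as rigid.
#'
#' @param dLk linking-number deficit (turns).
#' @param length_L loop length (bp or Angstrom).
#' @param P persistence length (same unit as `length_L`).
#' @return a one-row tibble: `E_bend`, `E_twist` (kB T).
#' @export
#' @examples
#' loop_energy_scales(2, 336, 150)  # about 17 and 105 kB T
loop_energy_scales <- function(dLk, length_L, P = 150) {
  stopifnot(length_L > 0, P > 0)
  tibble::tibble(E_bend = 4 * pi^2 * P / length_L,
                 E_twist = 6 * pi^2 * dLk^2 * P / length_L)
}

#' Long-range screened electrostatic energy of a loop
#'
#' Screened interaction energy of `N` charges `q` held at a typical mutual
#' distance of the loop radius `L / 2 pi`:
#' `E_lr = (q^2 N lB / 2 L) exp(-L / (2 pi R_D))` in kB T (the Bjerrum
#' length absorbs the solvent permittivity). Negligibly small for
#' minicircles at physiological ionic strength because `L >> R_D`.
#'
#' @param params an [electrostatic_params()] (needs `n_charges_N`).
#' @param L loop contour length in Angstrom.
#' @return energy in kB T.
#' @export
long_range_electrostatic_energy <- function(params, L) {
  stopifnot(inherits(params, "electrostatic_params"), L > 0)
  if (is.null(params$N)) {
    stop("`n_charges_N` must be set for the long-range estimate.",
         call. = FALSE)
  }
  RD <- debye_length(params)
  params$q^2 * params$N * params$lB / (2 * L) * exp(-L / (2 * pi * RD))
}

#' Summary table of electrostatic estimates
#'
#' @param ionic_strength molar ionic strength (mol/l).
#' @param length_bp loop length in bp.
#' @param dLk linking-number deficit.
#' @param rise_per_bp helix rise in Angstrom/bp (default 3.4).
#' @param P_bp persistence length in bp (default 150).
#' @inheritParams electrostatic_params
#' @return a one-row tibble with `R_D`, `P_el`, `P_total`, `E_bend`,
#'   `E_twist`, `E_lr`.
#' @export
electrostatic_estimates <- function(ionic_strength, length_bp, dLk,
                                    rise_per_bp = 3.4, P_bp = 150,
                                    bjerrum_length_lB = 7.1) {
  par <- electrostatic_params(ionic_strength,
                              bjerrum_length_lB = bjerrum_length_lB,
                              n_charges_N = 2L * length_bp,
                              intrinsic_P_in = P_bp * rise_per_bp)
  pl <- persistence_length(par)
  es <- loop_energy_scales(dLk, length_bp, P_bp)
  dplyr::bind_cols(pl, es,
                   tibble::tibble(E_lr = long_range_electrostatic_energy(
                     par, length_bp * rise_per_bp)))
}
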