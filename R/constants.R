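# Physical constants (SI, 2019 redefinition) and unit conversions.
.kB <- 1.380649e-23      # J/K
.NA <- 6.02214076e23     # 1/mol

# Water at 20 C, used for standard-condition corrections of s and D.
# Kestin et al. (1978) viscosity; CRC handbook density.
.eta_20w_cP <- 1.0016
.rho_20w <- 0.99823      # g/ml

.ANGSTROM <- 1e-10       # m

cP_to_Pas <- function(eta_cP) eta_cP * 1e-3

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
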