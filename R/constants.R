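## Physical constants in the package's working units
## (energies kJ/mol, distances nm, charges e, temperature K).

#' Molar gas constant in kJ mol^-1 K^-1
#' @keywords internal
R_GAS <- 0.008314463

## Coulomb conversion factor f = 1/(4 pi eps0) in kJ mol^-1 nm e^-2,
## the value used by the major biomolecular force fields.
F_COULOMB <- 138.935458

#' Thermal energy RT in kJ/mol
#'
#' @param temperature Temperature in K.
#' @return RT in kJ/mol.
#' @examples
#' kT(300) # ~2.494 kJ/mol
#' @export
kT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  R_GAS * temperature
}
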