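#' Physical constants used throughout the package
#'
#' Engine-style molecular units are used everywhere: lengths in nm, time in
#' ps, temperature in K, energies in kJ/mol, charges in e, pressure in bar.
#'
#' @return A named list with components:
#' \describe{
#'   \item{R_kJ}{molar gas constant, kJ mol^-1 K^-1 (8.31446e-3)}
#'   \item{R_J}{molar gas constant, J mol^-1 K^-1 (8.31446)}
#'   \item{k_e}{Coulomb constant, kJ mol^-1 nm e^-2 (138.935458)}
#'   \item{enm_to_debye}{debye per e nm (48.032047)}
#'   \item{debye_to_enm}{e nm per debye (0.0208194)}
#'   \item{bar_per_kJmolnm3}{pressure unit conversion: bar per kJ mol^-1 nm^-3}
#'   \item{M_H2O2, M_H2O}{molar masses, g mol^-1}
#'   \item{m_O, m_H}{atomic masses, g mol^-1}
#'   \item{amu_to_kg}{kg per g mol^-1 particle mass (1/N_A / 1000)}
#' }
#' @export
#' @examples
#' phys_constants()$k_e
phys_constants <- function() {
  N_A <- 6.02214076e23
  list(
    R_kJ = 8.31446e-3,
    R_J = 8.31446,
    k_e = 138.935458,
    enm_to_debye = 48.032047,
    debye_to_enm = 0.0208194,
    # 1 kJ mol^-1 nm^-3 = 1000 J / (N_A * 1e-27 m^3) = 16.6054 bar
    bar_per_kJmolnm3 = 1000 / (N_A * 1e-27) / 1e5,
    M_H2O2 = 34.0147,
    M_H2O = 18.0153,
    m_O = 15.9994,
    m_H = 1.00794,
    amu_to_kg = 1e-3 / N_A
  )
}
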