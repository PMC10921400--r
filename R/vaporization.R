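#' Enthalpy of vaporization
#'
#' Delta H_vap(T) = U_g(T) - U_l(T) + RT, where U_g is the potential energy
#' of an isolated gas molecule and U_l the liquid potential energy per
#' molecule. For a flexible 4-site molecule U_g(T) = U_g^min + 3RT (see
#' \code{\link{gas_internal_energy}}); for a rigid reference molecule
#' (e.g. SPC/E water) U_g is a constant, selected with \code{rigid = TRUE}.
#' Assumes negligible liquid specific volume and equal kinetic energies in
#' the two phases; no quantum corrections.
#'
#' @param U_l_per_molecule liquid potential energy per molecule, kJ/mol.
#' @param T temperature, K (positive).
#' @param ref a \code{\link{gas_reference}}.
#' @param rigid if TRUE, U_g(T) = u_g_min independent of T.
#' @return Delta H_vap, kJ/mol.
#' @export
#' @examples
#' enthalpy_of_vaporization(-40, 300, gas_reference(114.9, -1.53))
enthalpy_of_vaporization <- function(U_l_per_molecule, T, ref, rigid = FALSE) {
  if (any(T <= 0)) stop("temperature must be positive")
  U_g <- if (rigid) ref$u_g_min else gas_internal_energy(T, ref)
  U_g - U_l_per_molecule + phys_constants()$R_kJ * T
}

#' Self-polarization energy correction
#'
#' E_pol = k_e (mu_model - mu_gas)^2 / (2 alpha'), the energy invested in
#' polarizing a molecule from its gas-phase dipole to the effective liquid
#' dipole of a nonpolarizable model. The default polarizability volume for
#' H2O2 is 30 percent above the 1.444e-3 nm^3 value used for SPC/E water.
#'
#' @param mu_model liquid-phase model dipole, debye.
#' @param mu_gas experimental gas-phase dipole, debye.
#' @param alpha_volume polarizability volume, nm^3.
#' @return E_pol, kJ/mol.
#' @export
#' @examples
#' self_polarization_correction(2.69, 2.05)  # upper bound of the correction
self_polarization_correction <- function(mu_model, mu_gas,
                                         alpha_volume = 1.3 * 1.444e-3) {
  if (alpha_volume <= 0) stop("polarizability volume must be positive")
  k <- phys_constants()
  dmu <- (mu_model - mu_gas) * k$debye_to_enm
  k$k_e * dmu^2 / (2 * alpha_volume)
}
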