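#' Expand the RB scale into the six Ryckaert-Bellemans coefficients
#'
#' The dihedral potential is a constrained Ryckaert-Bellemans expansion with
#' a single free scale c2: c0 = 0.312 c2, c1 = -c2, c3 = 0.300 c2,
#' c4 = c5 = 0.
#'
#' @param c2 RB scale, kJ/mol (strictly positive).
#' @return Named numeric vector \code{c0..c5}, kJ/mol.
#' @export
#' @examples
#' expand_rb_coefficients(26.91)
expand_rb_coefficients <- function(c2) {
  if (!is.finite(c2) || c2 <= 0) stop("c2 must be finite and strictly positive")
  c(c0 = 0.312 * c2, c1 = -c2, c2 = c2, c3 = 0.300 * c2, c4 = 0, c5 = 0)
}

#' Ryckaert-Bellemans dihedral energy
#'
#' Evaluates V = sum_n c_n cos^n(psi) with psi = a_d - 180 degrees, where
#' a_d is the IUPAC dihedral (cis = 0, trans = +/-180). The function is
#' periodic and even in a_d.
#'
#' @param a_d dihedral angle(s), degrees (IUPAC convention).
#' @param coeffs six RB coefficients, kJ/mol (e.g. from
#'   \code{\link{expand_rb_coefficients}}).
#' @return Energy, kJ/mol (vectorized over \code{a_d}).
#' @export
#' @examples
#' rb_energy(90, expand_rb_coefficients(26.91))
rb_energy <- function(a_d, coeffs) {
  if (length(coeffs) != 6 || any(!is.finite(coeffs)))
    stop("coeffs must be six finite RB coefficients")
  x <- cos((a_d - 180) * pi / 180)
  unname(coeffs[1] + x * (coeffs[2] + x * (coeffs[3] + x * (coeffs[4] +
    x * (coeffs[5] + x * coeffs[6])))))
}

# Stationary points of the constrained RB cubic in x = cos(psi).
# f(x) = 0.312 - x + x^2 + 0.3 x^3 (per unit c2); f'(x) = -1 + 2x + 0.9x^2.
rb_interior_minimum <- function(c2) {
  x <- (-2 + sqrt(4 + 3.6)) / 1.8        # root of f'(x) in (-1, 1)
  psi <- acos(x) * 180 / pi
  list(a_d_min = 180 - psi,
       v_min = rb_energy(180 - psi, expand_rb_coefficients(c2)))
}

#' Dihedral energy profile and stationary points
#'
#' Scans the intramolecular energy versus dihedral at equilibrium bonds and
#' angles, then refines the interior minima by golden-section search. For
#' any positive c2 the profile has a large cis barrier at a_d = 0, a small
#' trans barrier at a_d = +/-180, and two symmetric interior minima.
#'
#' @param params \code{\link{model_parameters}}.
#' @param fc \code{\link{force_constants}} (bonds/angles are at equilibrium,
#'   so they contribute nothing; kept for interface symmetry).
#' @param policy \code{\link{exclusion_policy}}; under \code{"opls_14_half"}
#'   the 1-4 H-H Coulomb term is included in the profile.
#' @param grid_step grid spacing, degrees, in (0, 10].
#' @return A list with \code{profile} (data.frame a_d, energy over
#'   [-180, 180]), \code{a_d_min} (positive branch, degrees; the minimum is
#'   at +/- a_d_min), \code{v_min}, \code{cis_barrier} = V(0) - V(min) and
#'   \code{trans_barrier} = V(180) - V(min), kJ/mol.
#' @export
dihedral_profile <- function(params, fc = force_constants(),
                             policy = exclusion_policy(), grid_step = 0.5) {
  if (grid_step <= 0 || grid_step > 10)
    stop("grid_step must lie in (0, 10] degrees")
  energy_at <- function(a) vapply(a, function(ai)
    intramolecular_energy(build_conformation(params, ai), params, fc,
                          policy)$total, numeric(1))
  a <- seq(-180, 180, by = grid_step)
  e <- energy_at(a)
  # refine on the positive branch; ties broken toward smaller |a_d|
  pos <- a > 0 & a < 180
  i <- which(pos)[which.min(e[pos])]
  lo <- max(a[i] - grid_step, 0); hi <- min(a[i] + grid_step, 180)
  opt <- stats::optimize(function(x) energy_at(x), c(lo, hi),
                         tol = .Machine$double.eps^0.5)
  list(profile = data.frame(a_d = a, energy = e),
       a_d_min = opt$minimum,
       v_min = opt$objective,
       cis_barrier = energy_at(0) - opt$objective,
       trans_barrier = energy_at(180) - opt$objective)
}

#' Isolated-molecule (gas-phase) energy minimum
#'
#' Minimizes the intramolecular energy over the dihedral with bonds and
#' angles at equilibrium. Under \code{"exclude_all_intra"} this is the
#' minimum of the RB term alone.
#'
#' @inheritParams dihedral_profile
#' @return A \code{\link{gas_reference}} with the minimum location (positive
#'   branch, degrees) and value (kJ/mol).
#' @export
gas_minimum <- function(params, fc = force_constants(),
                        policy = exclusion_policy()) {
  prof <- dihedral_profile(params, fc, policy, grid_step = 0.5)
  gas_reference(prof$a_d_min, prof$v_min)
}

#' Internal energy of an isolated gas molecule at temperature T
#'
#' U_g(T) = U_g^min + RT (3 N_sites - 6 - N_c) / 2 with N_sites = 4 and no
#' constraints (N_c = 0), i.e. U_g(T) = U_g^min + 3RT.
#'
#' @param T temperature, K (non-negative; vectorized).
#' @param ref \code{\link{gas_reference}}.
#' @return Energy, kJ/mol.
#' @export
gas_internal_energy <- function(T, ref) {
  if (any(T < 0)) stop("temperature must be non-negative")
  ref$u_g_min + 3 * phys_constants()$R_kJ * T
}
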