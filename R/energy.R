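#' Intramolecular energy of one H2O2 molecule
#'
#' Sums harmonic bond terms (1/2 k (r - r0)^2 for O-O and both O-H bonds),
#' harmonic angle terms (1/2 k (theta - theta0)^2 for both H-O-O angles, in
#' radians), the Ryckaert-Bellemans dihedral, and the intramolecular Coulomb
#' energy allowed by the exclusion policy. Internal Lennard-Jones is always
#' excluded; under \code{"exclude_all_intra"} intramolecular Coulomb is zero,
#' under \code{"opls_14_half"} only the 1-4 H-H pair survives, scaled by
#' \code{fudge_qq}.
#'
#' @param conf a \code{conformation}.
#' @param params \code{\link{model_parameters}}.
#' @param fc \code{\link{force_constants}}.
#' @param policy \code{\link{exclusion_policy}}.
#' @return A list of class \code{energy_breakdown}: \code{bond},
#'   \code{angle}, \code{dihedral}, \code{intra_coulomb}, \code{total}
#'   (kJ/mol), with \code{total} the exact sum of components.
#' @export
intramolecular_energy <- function(conf, params, fc = force_constants(),
                                  policy = exclusion_policy()) {
  conf <- as_conformation(conf)
  ic <- measure_internal_coordinates(conf)
  bond <- 0.5 * fc$kb_OO * (ic$d_OO - params$d_OO)^2 +
    0.5 * fc$kb_OH * ((ic$d_OH1 - params$d_OH)^2 + (ic$d_OH2 - params$d_OH)^2)
  th0 <- params$a_HOO * pi / 180
  angle <- 0.5 * fc$ka_HOO * ((ic$a_HOO1 * pi / 180 - th0)^2 +
                              (ic$a_HOO2 * pi / 180 - th0)^2)
  dihedral <- rb_energy(ic$a_d, expand_rb_coefficients(params$c2))
  intra_coulomb <- 0
  if (policy$mode == "opls_14_half") {
    r_hh <- sqrt(sum((conf["H1", ] - conf["H2", ])^2))
    intra_coulomb <- policy$fudge_qq * phys_constants()$k_e *
      params$q_H^2 / r_hh
  }
  structure(list(bond = bond, angle = angle, dihedral = dihedral,
                 intra_coulomb = intra_coulomb,
                 total = bond + angle + dihedral + intra_coulomb),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "bond %.6g  angle %.6g  dihedral %.6g  intra_coulomb %.6g  total %.6g kJ/mol\n",
    x$bond, x$angle, x$dihedral, x$intra_coulomb, x$total))
  invisible(x)
}

#' Intermolecular pair energy of two H2O2 molecules
#'
#' Lennard-Jones acts between the oxygen sites only,
#' 4 eps [(sigma/r)^12 - (sigma/r)^6]; Coulomb acts between all 16
#' intermolecular site pairs with charges +q_H on hydrogens and -q_H on
#' oxygens. No periodicity and no cutoff: plain two-molecule energies.
#'
#' @param confA,confB \code{conformation}s.
#' @param params \code{\link{model_parameters}}.
#' @return Energy, kJ/mol (symmetric in A, B).
#' @export
intermolecular_energy <- function(confA, confB, params) {
  confA <- as_conformation(confA); confB <- as_conformation(confB)
  q <- c(H1 = params$q_H, O1 = -params$q_H, O2 = -params$q_H, H2 = params$q_H)
  ke <- phys_constants()$k_e
  e <- 0
  for (i in rownames(confA)) for (j in rownames(confB)) {
    r <- sqrt(sum((confA[i, ] - confB[j, ])^2))
    if (r < 1e-12) stop("coincident sites: intermolecular energy is singular")
    e <- e + ke * q[[i]] * q[[j]] / r
    if (i %in% c("O1", "O2") && j %in% c("O1", "O2")) {
      sr6 <- (params$sigma_OO / r)^6
      e <- e + 4 * params$eps_OO * (sr6^2 - sr6)
    }
  }
  e
}
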