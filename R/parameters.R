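#' Physical parameters of the H2O2 model
#'
#' The model is defined by seven physical parameters: the Ryckaert-Bellemans
#' scale \code{c2} (the remaining coefficients follow from fixed constraints,
#' see \code{\link{expand_rb_coefficients}}), the hydrogen partial charge
#' \code{q_H} (each oxygen carries \code{-q_H}), the oxygen-oxygen
#' Lennard-Jones parameters \code{sigma_OO} and \code{eps_OO} (LJ acts on
#' oxygen sites only), and the equilibrium geometry \code{d_OO}, \code{d_OH},
#' \code{a_HOO}. Defaults are the optimized parameter set.
#'
#' @param c2 RB scale, kJ/mol.
#' @param q_H hydrogen partial charge, e.
#' @param sigma_OO LJ size, nm.
#' @param eps_OO LJ well depth, kJ/mol.
#' @param d_OO O-O bond length, nm.
#' @param d_OH O-H bond length, nm.
#' @param a_HOO H-O-O angle, degrees.
#' @return An object of class \code{model_parameters} (named list).
#' @export
#' @examples
#' p <- model_parameters()
#' p$c2
model_parameters <- function(c2 = 26.91, q_H = 0.4323, sigma_OO = 0.29989,
                             eps_OO = 0.8912, d_OO = 0.1463, d_OH = 0.0979,
                             a_HOO = 95.79) {
  p <- list(c2 = c2, q_H = q_H, sigma_OO = sigma_OO, eps_OO = eps_OO,
            d_OO = d_OO, d_OH = d_OH, a_HOO = a_HOO)
  validate_model_parameters(p)
  structure(p, class = "model_parameters")
}

validate_model_parameters <- function(p) {
  vals <- unlist(p[param_names()])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all model parameters must be finite and strictly positive")
  if (p$a_HOO <= 0 || p$a_HOO >= 180)
    stop("a_HOO must lie in (0, 180) degrees")
  invisible(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("H2O2 model parameters\n")
  cat(sprintf("  c2       = %g kJ/mol (RB scale)\n", x$c2))
  cat(sprintf("  q_H      = %g e (O carries -q_H)\n", x$q_H))
  cat(sprintf("  sigma_OO = %g nm, eps_OO = %g kJ/mol\n", x$sigma_OO, x$eps_OO))
  cat(sprintf("  d_OO     = %g nm, d_OH = %g nm, a_HOO = %g deg\n",
              x$d_OO, x$d_OH, x$a_HOO))
  invisible(x)
}

#' Canonical ordering of the seven physical parameters
#'
#' @return Character vector of length 7.
#' @export
param_names <- function() {
  c("c2", "q_H", "sigma_OO", "eps_OO", "d_OO", "d_OH", "a_HOO")
}

#' Sweep ranges for the seven physical parameters
#'
#' Defaults are the ranges swept during parametrization: c2 in [25.5, 36.0]
#' kJ/mol, q_H in [0.43, 0.47] e, sigma_OO in [0.296, 0.300] nm, eps_OO in
#' [0.7, 0.9] kJ/mol, d_OO in [0.145, 0.148] nm, d_OH in [0.094, 0.099] nm,
#' a_HOO in [94, 102] degrees.
#'
#' @param lower,upper named numeric vectors over \code{\link{param_names}}.
#' @return An object of class \code{parameter_ranges} with \code{lower} and
#'   \code{upper} components.
#' @export
parameter_ranges <- function(
    lower = c(c2 = 25.5, q_H = 0.43, sigma_OO = 0.296, eps_OO = 0.7,
              d_OO = 0.145, d_OH = 0.094, a_HOO = 94),
    upper = c(c2 = 36.0, q_H = 0.47, sigma_OO = 0.300, eps_OO = 0.9,
              d_OO = 0.148, d_OH = 0.099, a_HOO = 102)) {
  lower <- lower[param_names()]; upper <- upper[param_names()]
  if (any(is.na(lower)) || any(is.na(upper)))
    stop("ranges must name all seven parameters: ",
         paste(param_names(), collapse = ", "))
  if (any(lower >= upper)) stop("each lower bound must be below its upper bound")
  structure(list(lower = lower, upper = upper), class = "parameter_ranges")
}

#' @export
print.parameter_ranges <- function(x, ...) {
  cat("Parameter sweep ranges\n")
  for (nm in param_names())
    cat(sprintf("  %-8s [%g, %g]\n", nm, x$lower[[nm]], x$upper[[nm]]))
  invisible(x)
}

#' Bonded force constants
#'
#' Harmonic bond and angle force constants. The published model takes the
#' O-O constant from the OPLS N-O single bond and the O-H constant from the
#' TIP4F water model; the numeric values live in the model topology (itp)
#' file and are treated here as configuration inputs.
#'
#' @param kb_OO O-O harmonic bond constant, kJ mol^-1 nm^-2.
#' @param kb_OH O-H harmonic bond constant, kJ mol^-1 nm^-2.
#' @param ka_HOO H-O-O harmonic angle constant, kJ mol^-1 rad^-2.
#' @return An object of class \code{force_constants}.
#' @export
force_constants <- function(kb_OO = 2.7e5, kb_OH = 4.6e5, ka_HOO = 400) {
  if (any(c(kb_OO, kb_OH, ka_HOO) <= 0))
    stop("force constants must be strictly positive")
  structure(list(kb_OO = kb_OO, kb_OH = kb_OH, ka_HOO = ka_HOO),
            class = "force_constants")
}

#' Intramolecular nonbonded exclusion policy
#'
#' Internal Lennard-Jones interactions are always excluded. Under
#' \code{"exclude_all_intra"} (the default) intramolecular Coulomb
#' interactions are excluded as well; under \code{"opls_14_half"} the 1-4
#' H-H Coulomb pair survives, scaled by \code{fudge_qq}.
#'
#' @param mode \code{"exclude_all_intra"} or \code{"opls_14_half"}.
#' @param fudge_qq 1-4 Coulomb scale in [0, 1]; only used under
#'   \code{"opls_14_half"}.
#' @return An object of class \code{exclusion_policy}.
#' @export
exclusion_policy <- function(mode = c("exclude_all_intra", "opls_14_half"),
                             fudge_qq = 0.5) {
  mode <- match.arg(mode)
  if (fudge_qq < 0 || fudge_qq > 1) stop("fudge_qq must lie in [0, 1]")
  structure(list(mode = mode, fudge_qq = fudge_qq), class = "exclusion_policy")
}

#' Gas-phase reference energy of an isolated molecule
#'
#' Holds the location of the isolated-molecule energy minimum over the
#' dihedral and its value, U_g^min. The minimum computed from the model's
#' main energy terms is available via \code{\link{gas_minimum}}; the value
#' can also be set directly (the published model reports
#' U_g^min = -1.53 kJ/mol, which includes topology-level terms beyond the
#' bare RB expansion).
#'
#' @param a_d_min dihedral of the energy minimum, degrees (reported as
#'   +/- a_d_min by symmetry).
#' @param u_g_min minimum isolated-molecule potential energy, kJ/mol.
#' @return An object of class \code{gas_reference}.
#' @export
gas_reference <- function(a_d_min, u_g_min) {
  if (a_d_min <= 0 || a_d_min >= 180)
    stop("a_d_min must lie in (0, 180) degrees")
  structure(list(a_d_min = a_d_min, u_g_min = u_g_min),
            class = "gas_reference")
}

#' Coerce model parameters to a named 7-vector in canonical order
#'
#' @param p a \code{\link{model_parameters}} object or anything unlisting to
#'   a vector naming all seven parameters.
#' @return Named numeric vector in \code{\link{param_names}} order.
#' @export
as_param_vector <- function(p) {
  if (inherits(p, "model_parameters")) unlist(p[param_names()])
  else {
    v <- unlist(p)[param_names()]
    if (any(is.na(v))) stop("parameter vector must name all seven parameters")
    v
  }
}
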