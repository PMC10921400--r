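#' Thermal expansion coefficient from a cubic fit of density vs temperature
#'
#' Fits a cubic polynomial to rho(T) and evaluates
#' alpha_P = -(1/rho) (d rho / d T)_P at each input temperature. The fit is
#' performed on centered temperatures, so results are invariant under a
#' constant temperature shift.
#'
#' @param rho_vs_T data.frame with columns \code{T} (K) and \code{rho}
#'   (any fixed density unit).
#' @return data.frame with columns \code{T}, \code{rho_fit}, \code{alpha_P}
#'   (K^-1).
#' @export
alpha_p_from_fit <- function(rho_vs_T) {
  T <- rho_vs_T$T; rho <- rho_vs_T$rho
  if (length(unique(T)) < 4)
    stop("alpha_P cubic fit needs at least 4 distinct temperatures")
  tc <- T - mean(T)
  fit <- stats::lm(rho ~ tc + I(tc^2) + I(tc^3))
  b <- stats::coef(fit)
  rho_fit <- b[1] + b[2] * tc + b[3] * tc^2 + b[4] * tc^3
  drho <- b[2] + 2 * b[3] * tc + 3 * b[4] * tc^2
  data.frame(T = T, rho_fit = as.numeric(rho_fit),
             alpha_P = as.numeric(-drho / rho_fit))
}

#' Fluctuation estimators in the NPT ensemble
#'
#' From volume and enthalpy fluctuations:
#' kappa_T = <dV^2> / (<V> k_B T), alpha_P = <dV dH> / (<V> k_B T^2),
#' C_P = <dH^2> / (k_B T^2). The series carries whole-box energies in
#' kJ/mol, so k_B T is taken as RT; C_P is reported per mole of molecules.
#' Estimates are block averages (default 10 blocks) with blocks more than
#' three standard deviations from the mean discarded.
#'
#' @param ts a \code{\link{thermo_series}} (at nominally constant T, P).
#' @param n_blocks number of blocks for error analysis.
#' @return A list with \code{alpha_P} (K^-1), \code{kappa_T} (bar^-1),
#'   \code{C_P} (kJ mol^-1 K^-1 per mole of molecules), each a
#'   \code{list(value, error, n_blocks_used, discarded)}.
#' @export
npt_fluctuations <- function(ts, n_blocks = 10) {
  if (nrow(ts) < 1000) stop("need at least 1000 frames for fluctuation estimates")
  n_mol <- attr(ts, "n_molecules")
  RT <- phys_constants()$R_kJ * mean(ts$T)
  Tm <- mean(ts$T)
  conv <- phys_constants()$bar_per_kJmolnm3
  est <- function(idx) {
    V <- ts$V[idx]; H <- ts$H[idx]
    dV <- V - mean(V); dH <- H - mean(H)
    m <- length(idx)
    c(kappa_T = (sum(dV^2) / m) / (mean(V) * RT) / conv,
      alpha_P = (sum(dV * dH) / m) / (mean(V) * RT * Tm),
      C_P = (sum(dH^2) / m) / (RT * Tm) / n_mol)
  }
  blocks <- t(vapply(block_indices(nrow(ts), n_blocks), est, numeric(3)))
  out <- lapply(c(kappa_T = "kappa_T", alpha_P = "alpha_P", C_P = "C_P"),
                function(nm) block_summary(blocks[, nm]))
  if (all(abs(blocks) < .Machine$double.eps^0.5)) {
    warning("zero fluctuations: all NPT response estimates are 0")
    out <- lapply(out, function(o) { o$value <- 0; o })
  }
  out
}

#' Heat capacity at constant volume and adiabatic compressibility
#'
#' C_V = C_P - T V alpha_P^2 / kappa_T (per mole of molecules) and
#' kappa_S = kappa_T C_V / C_P. C_V must come out positive: a non-positive
#' C_V would imply kappa_T < 0 and a second-law violation.
#'
#' @param alpha_P thermal expansion coefficient, K^-1.
#' @param kappa_T isothermal compressibility, bar^-1.
#' @param C_P isobaric heat capacity, kJ mol^-1 K^-1 per mole of molecules.
#' @param T temperature, K.
#' @param V mean box volume, nm^3.
#' @param n_molecules molecules in the box (to put the T V alpha^2 / kappa
#'   term on the same per-mole basis as C_P).
#' @return A list of class \code{response_set} with \code{alpha_P},
#'   \code{kappa_T}, \code{kappa_S} (bar^-1), \code{C_P}, \code{C_V}.
#' @export
derived_caloric <- function(alpha_P, kappa_T, C_P, T, V, n_molecules = 1) {
  if (kappa_T <= 0) stop("kappa_T must be positive")
  if (C_P <= 0) stop("C_P must be positive")
  conv <- phys_constants()$bar_per_kJmolnm3   # bar per kJ mol^-1 nm^-3
  # T V alpha^2 / kappa: K nm^3 K^-2 / bar^-1 -> kJ/mol per K via conv
  dC <- T * V * alpha_P^2 / kappa_T / conv / n_molecules
  C_V <- C_P - dC
  if (C_V <= 0)
    stop("inconsistent inputs: C_V <= 0 would imply kappa_T < 0 ",
         "(second-law violation)")
  structure(list(alpha_P = alpha_P, kappa_T = kappa_T,
                 kappa_S = kappa_T * C_V / C_P, C_P = C_P, C_V = C_V),
            class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("alpha_P %.4g /K  kappa_T %.4g /bar  kappa_S %.4g /bar\n",
              x$alpha_P, x$kappa_T, x$kappa_S))
  cat(sprintf("C_P %.4g  C_V %.4g kJ/mol/K  (C_V/C_P = %.4g)\n",
              x$C_P, x$C_V, x$C_V / x$C_P))
  invisible(x)
}

#' Relative dielectric constant from box-dipole fluctuations
#'
#' eps = 1 + 4 pi k_e (<M^2> - <M>^2) / (3 <V> R T), with M in e nm and V
#' in nm^3; the mean is subtracted per component. Assumes conducting
#' (tin-foil) Ewald boundary conditions, the engine default. Block-averaged
#' with the three-sigma block-discard rule.
#'
#' @param ds a \code{\link{dipole_series}}.
#' @param n_blocks number of blocks.
#' @return \code{list(value, error, n_blocks_used, discarded)}.
#' @export
dielectric_constant <- function(ds, n_blocks = 10) {
  n <- nrow(ds$M)
  if (n < 1) stop("empty dipole series")
  if (n < 1000) stop("need at least 1000 frames for the dielectric constant")
  ke <- phys_constants()$k_e
  est <- function(idx) {
    M <- ds$M[idx, , drop = FALSE]
    varM <- sum(colMeans(M^2) - colMeans(M)^2)
    RT <- phys_constants()$R_kJ * mean(ds$T[idx])
    1 + 4 * pi * ke * varM / (3 * mean(ds$V[idx]) * RT)
  }
  block_summary(vapply(block_indices(n, n_blocks), est, numeric(1)))
}
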