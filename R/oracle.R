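#' Synthetic parameter-to-property oracle
#'
#' A smooth deterministic stand-in for the simulation pipeline that produced
#' the parameter-to-property training tables. Each of the 22 properties is a
#' quadratic-plus-pairwise-interaction polynomial in the normalized
#' parameters, built as x_e_j (1 + d' A_j d) with d the offset from a
#' constructed optimum p* and A_j a seeded positive-semidefinite matrix, so
#' the default target function is globally minimized (F = 0) exactly at p*.
#' Optional Gaussian relative noise emulates simulation scatter.
#'
#' @param seed integer seed fixing the polynomial coefficients.
#' @param p_star the constructed optimum (physical 7-vector); defaults to
#'   the optimized model parameters.
#' @param ranges \code{\link{parameter_ranges}}.
#' @param layout \code{\link{property_layout}} supplying references and
#'   labels.
#' @param amplitude scale of the quadratic response (relative deviation at
#'   unit normalized offset).
#' @param noise_rel per-property relative noise standard deviations; by
#'   default 2 percent, 5 percent for viscosity (the noisiest observable).
#' @return An object of class \code{oracle_spec}.
#' @export
oracle_spec <- function(seed = 42, p_star = model_parameters(),
                        ranges = parameter_ranges(),
                        layout = property_layout(), amplitude = 0.25,
                        noise_rel = NULL) {
  u_star <- normalize_params(p_star, ranges)
  set.seed(seed)
  A <- lapply(seq_len(nrow(layout)), function(j) {
    G <- matrix(stats::rnorm(49), 7, 7)
    crossprod(G) / 7 * amplitude
  })
  if (is.null(noise_rel))
    noise_rel <- ifelse(layout$property == "mu", 0.05, 0.02)
  structure(list(seed = seed, u_star = u_star, ranges = ranges,
                 layout = layout, A = A, noise_rel = noise_rel),
            class = "oracle_spec")
}

#' Evaluate the synthetic oracle
#'
#' @param p physical 7-vector or n x 7 matrix (within the oracle's ranges).
#' @param spec an \code{\link{oracle_spec}}.
#' @param noisy add Gaussian relative noise (per-property sigma from the
#'   spec).
#' @param seed seed for the noise draw (required when \code{noisy}).
#' @return 22-vector (or n x 22 matrix) of property values, labeled.
#' @export
oracle_properties <- function(p, spec, noisy = FALSE, seed = 1) {
  U <- normalize_params(if (is.matrix(p)) p else
    matrix(as_param_vector(p), nrow = 1,
           dimnames = list(NULL, param_names())), spec$ranges)
  D <- sweep(U, 2, spec$u_star)
  Y <- vapply(seq_along(spec$A), function(j)
    spec$layout$x_e[j] * (1 + rowSums((D %*% spec$A[[j]]) * D)),
    numeric(nrow(U)))
  Y <- matrix(Y, nrow = nrow(U), dimnames = list(NULL, spec$layout$label))
  if (noisy) {
    set.seed(seed)
    noise <- matrix(stats::rnorm(length(Y)), nrow(Y)) *
      matrix(spec$noise_rel, nrow(Y), ncol(Y), byrow = TRUE)
    Y <- Y * (1 + noise)
  }
  if (is.matrix(p)) Y else drop(Y)
}

#' Sample training and validation tables from the oracle
#'
#' Rows are drawn uniformly in the parameter ranges and labeled with noisy
#' oracle properties. Default sizes are 1000 training and 300 validation
#' determinations.
#'
#' @param spec an \code{\link{oracle_spec}}.
#' @param n_train,n_val table sizes.
#' @param seed integer seed.
#' @param noisy add simulation-like noise to the property columns.
#' @return \code{list(train, validation)} of \code{\link{training_table}}s.
#' @export
make_training_tables <- function(spec, n_train = 1000, n_val = 300,
                                 seed = 1, noisy = TRUE) {
  if (n_train < 1 || n_val < 1) stop("table sizes must be at least 1")
  set.seed(seed)
  draw <- function(n) {
    U <- matrix(stats::runif(n * 7), ncol = 7)
    denormalize_params(U, spec$ranges)
  }
  p_tr <- draw(n_train); p_va <- draw(n_val)
  y_tr <- oracle_properties(p_tr, spec, noisy = noisy, seed = seed + 1)
  y_va <- oracle_properties(p_va, spec, noisy = noisy, seed = seed + 2)
  list(train = training_table(p_tr, y_tr, spec$ranges),
       validation = training_table(p_va, y_va, spec$ranges))
}

#' Synthetic trajectory series with known response properties
#'
#' Inverts each estimator's formula: a correlated Gaussian (V, H) series
#' whose moments yield the requested kappa_T, alpha_P and C_P; an isotropic
#' Gaussian box-dipole series for the requested dielectric constant;
#' Gaussian random walks for the requested diffusion coefficient; and a
#' noisy stationary velocity-profile amplitude for the requested viscosity.
#' The noise is uncorrelated frame to frame (the fluctuation estimators
#' depend on sample moments only).
#'
#' @param targets list with any of \code{kappa_T} (bar^-1), \code{alpha_P}
#'   (K^-1), \code{C_P} (kJ/mol/K per mole of molecules), \code{epsilon},
#'   \code{D} (m^2/s), \code{eta} (cP).
#' @param conditions list: \code{T} (K), \code{V} (nm^3), \code{n_frames},
#'   \code{n_molecules}, plus \code{n_walkers}, \code{n_steps}, \code{dt}
#'   (ps) for diffusion and \code{A} (nm/ps^2), \code{rho} (kg/m^3),
#'   \code{L_z} (nm), \code{v_noise_rel}, \code{n_v} for viscosity.
#' @param seed integer seed.
#' @return A list with \code{thermo} (\code{\link{thermo_series}}),
#'   \code{dipole} (\code{\link{dipole_series}}), \code{walk}
#'   (\code{list(positions, dt)}) and \code{v_amplitudes}, populated for the
#'   targets requested.
#' @export
gen_fluctuation_series <- function(targets, conditions, seed = 1) {
  set.seed(seed)
  k <- phys_constants()
  T0 <- conditions$T; V0 <- conditions$V
  out <- list()
  if (!is.null(targets$kappa_T)) {
    n <- conditions$n_frames; n_mol <- conditions$n_molecules
    RT <- k$R_kJ * T0
    var_V <- targets$kappa_T * k$bar_per_kJmolnm3 * V0 * RT
    cov_VH <- targets$alpha_P * V0 * k$R_kJ * T0^2
    var_H <- targets$C_P * n_mol * k$R_kJ * T0^2
    if (var_V < 0 || var_H < 0 || cov_VH^2 > var_V * var_H)
      stop("infeasible covariance: requested (kappa_T, alpha_P, C_P) are ",
           "not jointly realizable")
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    V <- V0 + sqrt(var_V) * z1
    H0 <- -45 * n_mol
    H <- if (var_V > 0)
      H0 + (cov_VH / sqrt(var_V)) * z1 +
        sqrt(max(var_H - cov_VH^2 / var_V, 0)) * z2
      else H0 + sqrt(var_H) * z2
    out$thermo <- thermo_series(time = seq_len(n), U = H - 16.6 * V, V = V,
                                H = H, T = rep(T0, n), P = rep(1, n),
                                n_molecules = n_mol)
  }
  if (!is.null(targets$epsilon)) {
    n <- conditions$n_frames
    sigma2 <- (targets$epsilon - 1) * V0 * k$R_kJ * T0 / (4 * pi * k$k_e)
    M <- matrix(stats::rnorm(3 * n, sd = sqrt(sigma2)), ncol = 3)
    out$dipole <- dipole_series(seq_len(n), M, V0, T0)
  }
  if (!is.null(targets$D)) {
    nw <- conditions$n_walkers; ns <- conditions$n_steps
    dt <- conditions$dt
    D_nm <- targets$D * 1e6                      # m^2/s -> nm^2/ps
    step_sd <- sqrt(2 * D_nm * dt)
    pos <- array(0, c(ns, nw, 3))
    for (ax in 1:3)
      pos[, , ax] <- apply(matrix(stats::rnorm((ns - 1) * nw, sd = step_sd),
                                  ns - 1, nw), 2,
                           function(s) c(0, cumsum(s)))
    out$walk <- list(positions = pos, dt = dt)
  }
  if (!is.null(targets$eta)) {
    kk <- 2 * pi / conditions$L_z
    v_true <- conditions$A * conditions$rho * 1e-3 / (targets$eta * kk^2)
    n_v <- if (is.null(conditions$n_v)) 5000 else conditions$n_v
    rel <- if (is.null(conditions$v_noise_rel)) 0.05 else conditions$v_noise_rel
    out$v_amplitudes <- v_true * (1 + rel * stats::rnorm(n_v))
  }
  out
}

#' Synthetic vapor-liquid coexistence fixtures with known critical point
#'
#' Inverts the rectilinear-diameters/scaling forms and the
#' Clausius-Clapeyron relation: rho_{l,v}(T) = rho_c + A (T_c - T) +/-
#' B (T_c - T)^beta / 2, P_v(T) from exp(-dhvap / RT + const), and
#' two-interface tanh slab profiles consistent with each table row.
#'
#' @param truth list with \code{T_c} (K), \code{rho_c} (kg/m^3), \code{A},
#'   \code{B}.
#' @param T_grid temperatures, K, all below T_c.
#' @param dhvap enthalpy of vaporization driving P_v(T), kJ/mol.
#' @param noise relative Gaussian noise on the densities (0 = exact).
#' @param seed integer seed.
#' @param beta critical exponent.
#' @param P_ref,T_ref anchor for the vapor-pressure curve (defaults: 1.013
#'   bar at the median grid temperature).
#' @param L_z,width slab geometry for the generated profiles (nm).
#' @return A list with \code{coex} (data.frame T, rho_l, rho_v),
#'   \code{pv_table} (data.frame T, P_v) and \code{profiles} (one tanh
#'   profile data.frame per temperature).
#' @export
gen_coexistence_fixtures <- function(truth, T_grid, dhvap = 45, noise = 0,
                                     seed = 1, beta = 0.32, P_ref = 1.013,
                                     T_ref = NULL, L_z = 18, width = 0.4) {
  if (any(T_grid >= truth$T_c)) stop("all grid temperatures must be below T_c")
  set.seed(seed)
  dT <- truth$T_c - T_grid
  mid <- truth$rho_c + truth$A * dT
  del <- truth$B * dT^beta
  rho_l <- mid + del / 2
  rho_v <- mid - del / 2
  if (noise > 0) {
    rho_l <- rho_l * (1 + noise * stats::rnorm(length(T_grid)))
    rho_v <- rho_v * (1 + noise * stats::rnorm(length(T_grid)))
  }
  if (is.null(T_ref)) T_ref <- stats::median(T_grid)
  R <- phys_constants()$R_kJ
  P_v <- P_ref * exp(-dhvap / R * (1 / T_grid - 1 / T_ref))
  z <- seq(0.05, L_z - 0.05, by = 0.1)
  profiles <- lapply(seq_along(T_grid), function(i)
    data.frame(z = z, rho = rho_v[i] + (rho_l[i] - rho_v[i]) / 2 *
                 (tanh((z - L_z / 3) / width) -
                  tanh((z - 2 * L_z / 3) / width))))
  list(coex = data.frame(T = T_grid, rho_l = rho_l, rho_v = rho_v),
       pv_table = data.frame(T = T_grid, P_v = P_v),
       profiles = profiles)
}
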