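#' Vapor pressure from the virial or ideal-gas route
#'
#' The virial route reports the mean normal pressure component <P_zz> of the
#' slab. Below 2 bar its relative error grows quickly, so the ideal-gas
#' route is used instead: P_v = sum_s (rho_s / M_s) R T over the vapor
#' species (molar masses 34.0147 g/mol for H2O2, 18.0153 for H2O). When both
#' inputs are supplied the route switches to ideal for P < 2 bar.
#'
#' @param P_zz mean normal pressure component, bar (virial route), or NULL.
#' @param rho_v named vector of vapor partial densities (\code{H2O2},
#'   \code{H2O}), kg/m^3, or a single unnamed value taken as pure H2O2.
#' @param T temperature, K (ideal route).
#' @param switch_bar route-switch threshold, bar.
#' @return \code{list(P_v, route)} with \code{route} \code{"virial"} or
#'   \code{"ideal"}.
#' @export
#' @examples
#' vapor_pressure(rho_v = c(H2O2 = 1), T = 423)
vapor_pressure <- function(P_zz = NULL, rho_v = NULL, T = NULL,
                           switch_bar = 2) {
  ideal <- NULL
  if (!is.null(rho_v)) {
    if (any(rho_v < 0)) stop("vapor densities must be non-negative")
    if (is.null(T) || T <= 0) stop("ideal route needs a positive temperature")
    k <- phys_constants()
    if (is.null(names(rho_v))) names(rho_v) <- "H2O2"
    M <- c(H2O2 = k$M_H2O2, H2O = k$M_H2O)[names(rho_v)] * 1e-3  # kg/mol
    ideal <- sum(rho_v / M) * k$R_J * T / 1e5                    # Pa -> bar
  }
  if (!is.null(P_zz)) {
    if (P_zz >= switch_bar || is.null(ideal))
      return(list(P_v = P_zz, route = "virial"))
  }
  if (is.null(ideal)) stop("supply P_zz and/or (rho_v, T)")
  list(P_v = ideal, route = "ideal")
}

#' Surface tension from the pressure-tensor anisotropy (virial route)
#'
#' lambda = (L_z / 2) [ <P_zz> - (<P_xx> + <P_yy>)/2 ]; the factor 1/2
#' accounts for the two interfaces of the slab. Positive when the normal
#' component exceeds the lateral mean.
#'
#' @param P_diag mean pressure-tensor diagonal \code{c(P_xx, P_yy, P_zz)},
#'   bar.
#' @param L_z box height, nm.
#' @return Surface tension, mN/m.
#' @export
#' @examples
#' surface_tension(c(0, 0, 100), 18)
surface_tension <- function(P_diag, L_z) {
  if (L_z <= 0) stop("L_z must be positive")
  if (length(P_diag) != 3) stop("P_diag must be c(P_xx, P_yy, P_zz)")
  # bar nm -> mN/m: 1e5 Pa * 1e-9 m = 1e-4 N/m = 0.1 mN/m
  (L_z / 2) * (P_diag[3] - (P_diag[1] + P_diag[2]) / 2) * 0.1
}

#' Boiling temperature from low-pressure vapor-pressure data
#'
#' Fits a second-order polynomial to P_v(T) over the lowest-pressure points
#' bracketing atmospheric pressure and returns the crossing with
#' P_v = 1.013 bar.
#'
#' @param pv_table data.frame with columns \code{T} (K) and \code{P_v}
#'   (bar).
#' @param P_target crossing pressure, bar.
#' @param n_low number of lowest-pressure points to fit (at least 3; grown
#'   automatically until the points bracket \code{P_target}).
#' @return Boiling temperature, K.
#' @export
boiling_temperature <- function(pv_table, P_target = 1.013, n_low = 3) {
  tab <- pv_table[order(pv_table$P_v), ]
  n <- max(3, n_low)
  repeat {
    sel <- tab[seq_len(min(n, nrow(tab))), ]
    if (min(sel$P_v) <= P_target && max(sel$P_v) >= P_target) break
    if (n >= nrow(tab)) break
    n <- n + 1
  }
  if (nrow(sel) < 3 || min(sel$P_v) > P_target || max(sel$P_v) < P_target)
    stop("no bracketing of P_v = ", P_target, " bar in the data")
  tc <- sel$T - mean(sel$T)
  fit <- stats::lm(P_v ~ tc + I(tc^2), data = cbind(sel, tc = tc))
  b <- stats::coef(fit)
  roots <- if (abs(b[3]) < 1e-14) (P_target - b[1]) / b[2] else {
    disc <- b[2]^2 - 4 * b[3] * (b[1] - P_target)
    if (disc < 0) numeric(0)
    else (-b[2] + c(-1, 1) * sqrt(disc)) / (2 * b[3])
  }
  roots <- roots + mean(sel$T)
  span <- range(sel$T)
  inside <- roots[roots >= span[1] - 1e-9 & roots <= span[2] + 1e-9]
  if (length(inside) == 0)
    stop("fitted quadratic does not cross P_v = ", P_target,
         " bar inside the data range")
  inside[which.min(abs(inside - mean(span)))]
}

#' Critical point from coexisting densities
#'
#' Simultaneous least squares of the law of rectilinear diameters,
#' (rho_l + rho_v)/2 = rho_c + A (T_c - T), and the scaling law
#' rho_l - rho_v = B (T_c - T)^beta with the critical exponent fixed at
#' beta = 0.32. T_c is profiled: for each trial T_c the remaining
#' parameters are linear. When a vapor-pressure table is supplied, P_c is
#' obtained by extrapolating a linear fit of ln P_v vs 1/T to T_c.
#'
#' @param coex data.frame with columns \code{T} (K), \code{rho_l},
#'   \code{rho_v} (kg/m^3); at least 4 temperatures, all below T_c.
#' @param pv_table optional data.frame with columns \code{T}, \code{P_v}
#'   (bar).
#' @param beta critical exponent (fixed, not fitted).
#' @return A list of class \code{critical_fit}: \code{T_c} (K), \code{rho_c}
#'   (kg/m^3), \code{A}, \code{B}, \code{beta}, \code{P_c} (bar or NA),
#'   \code{rss}.
#' @export
critical_point <- function(coex, pv_table = NULL, beta = 0.32) {
  if (nrow(coex) < 4) stop("need at least 4 coexistence temperatures")
  if (any(coex$rho_l <= coex$rho_v))
    stop("rho_l must exceed rho_v at every temperature ",
         "(columns swapped or single phase?)")
  T <- coex$T
  mid <- (coex$rho_l + coex$rho_v) / 2
  del <- coex$rho_l - coex$rho_v
  rss_at <- function(Tc) {
    dT <- Tc - T
    rect <- stats::lm(mid ~ dT)
    B <- sum(del * dT^beta) / sum(dT^(2 * beta))
    sum(stats::resid(rect)^2) + sum((del - B * dT^beta)^2)
  }
  span <- diff(range(T))
  opt <- stats::optimize(rss_at, c(max(T) + 1e-6, max(T) + 10 * span),
                         tol = 1e-8)
  Tc <- opt$minimum
  if (Tc > max(T) + 9.99 * span)
    stop("critical fit did not converge: T_c ran to the search bound ",
         "(densities may not close toward a critical point)")
  dT <- Tc - T
  rect <- stats::lm(mid ~ dT)
  B <- sum(del * dT^beta) / sum(dT^(2 * beta))
  P_c <- NA_real_
  if (!is.null(pv_table)) {
    if (any(pv_table$P_v <= 0)) stop("vapor pressures must be positive")
    cc <- stats::lm(log(P_v) ~ I(1 / T), data = pv_table)
    P_c <- exp(sum(stats::coef(cc) * c(1, 1 / Tc)))
  }
  structure(list(T_c = Tc, rho_c = unname(stats::coef(rect)[1]),
                 A = unname(stats::coef(rect)[2]), B = B, beta = beta,
                 P_c = P_c, rss = opt$objective),
            class = "critical_fit")
}

#' @export
print.critical_fit <- function(x, ...) {
  cat(sprintf("T_c = %.2f K  rho_c = %.1f kg/m^3  P_c = %s bar  (beta = %g)\n",
              x$T_c, x$rho_c,
              if (is.na(x$P_c)) "NA" else sprintf("%.1f", x$P_c), x$beta))
  invisible(x)
}

#' Enthalpy of vaporization from the Clausius-Clapeyron relation
#'
#' ln(P_v1 / P_v2) = Delta H_vap (1/T_2 - 1/T_1) / R. Two points give the
#' closed form; more give -R times the slope of ln P_v vs 1/T.
#'
#' @param pv_table data.frame with columns \code{T} (K, distinct) and
#'   \code{P_v} (bar, positive).
#' @return Delta H_vap, kJ/mol.
#' @export
clausius_clapeyron_dhvap <- function(pv_table) {
  T <- pv_table$T; P <- pv_table$P_v
  if (length(unique(T)) < length(T) || length(T) < 2)
    stop("need at least two distinct temperatures")
  if (any(P <= 0)) stop("pressures must be positive")
  R <- phys_constants()$R_kJ
  if (length(T) == 2)
    return(R * log(P[1] / P[2]) / (1 / T[2] - 1 / T[1]))
  -R * unname(stats::coef(stats::lm(log(P) ~ I(1 / T)))[2])
}
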