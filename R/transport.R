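#' Mean squared displacement from particle trajectories
#'
#' Multi-origin MSD: for each requested lag the squared displacement is
#' averaged over strided time origins and all particles.
#'
#' @param positions array of dimension (frames, particles, 3), nm.
#' @param dt frame spacing, ps.
#' @param lags integer lag counts at which to evaluate the MSD.
#' @param origin_stride spacing between time origins, frames.
#' @return data.frame with columns \code{time} (ps) and \code{msd} (nm^2).
#' @export
msd_curve <- function(positions, dt, lags, origin_stride = NULL) {
  d <- dim(positions)
  n <- d[1]
  if (is.null(origin_stride)) origin_stride <- max(1L, n %/% 100L)
  X <- matrix(positions, nrow = n)        # frames x (particles*3)
  msd <- vapply(lags, function(L) {
    origins <- seq(1L, n - L, by = origin_stride)
    disp <- X[origins + L, , drop = FALSE] - X[origins, , drop = FALSE]
    # sum squared displacement over the 3 components, mean over the rest
    sum(disp^2) / (length(origins) * d[2])
  }, numeric(1))
  data.frame(time = lags * dt, msd = msd)
}

#' Diffusion coefficient from the Einstein relation
#'
#' Fits the long-time linear regime of the mean squared displacement,
#' <|r(t) - r(0)|^2> = 6 D t, by least squares over a time window and
#' converts the slope from nm^2/ps to m^2/s.
#'
#' @param msd_or_positions either a data.frame with columns \code{time} (ps)
#'   and \code{msd} (nm^2), or a list with \code{positions} (an array of
#'   dimension frames x particles x 3, nm) and \code{dt} (ps).
#' @param fit_window \code{c(t_lo, t_hi)} in ps; defaults to 10--50 percent
#'   of the series length.
#' @return A list with \code{D} (m^2 s^-1), the fitted \code{slope}
#'   (nm^2/ps), \code{n_points}, and \code{flagged} (TRUE when the fitted
#'   slope was negative and D was clamped to 0).
#' @export
diffusion_einstein <- function(msd_or_positions, fit_window = NULL) {
  if (is.data.frame(msd_or_positions)) {
    msd <- msd_or_positions
  } else {
    pos <- msd_or_positions$positions
    dt <- msd_or_positions$dt
    n <- dim(pos)[1]
    if (is.null(fit_window)) fit_window <- c(0.1, 0.5) * (n - 1) * dt
    lags <- unique(round(seq(max(1, fit_window[1] / dt),
                             min(n - 1, fit_window[2] / dt),
                             length.out = 25)))
    msd <- msd_curve(pos, dt, lags)
  }
  t_all <- msd$time
  if (is.null(fit_window))
    fit_window <- c(0.1, 0.5) * max(t_all)
  sel <- t_all >= fit_window[1] & t_all <= fit_window[2]
  if (sum(sel) < 10) stop("need at least 10 MSD points inside the fit window")
  fit <- stats::lm(msd ~ time, data = msd[sel, ])
  slope <- stats::coef(fit)[["time"]]
  flagged <- FALSE
  if (slope < 0) {
    warning("negative MSD slope; D clamped to 0 and flagged")
    flagged <- TRUE
  }
  D <- max(slope, 0) / 6 * 1e-6   # nm^2/ps -> m^2/s
  list(D = D, slope = slope, n_points = sum(sel), flagged = flagged)
}

#' Shear viscosity from the cosine-acceleration (periodic perturbation) flow
#'
#' A sinusoidal acceleration profile of amplitude A along the box produces a
#' stationary velocity profile of amplitude v_max with
#' eta = A rho / (v_max k^2), k = 2 pi / L_z. The time-averaged amplitude of
#' the stationary profile is used and the result converted to cP.
#'
#' @param v_amplitude_series stationary velocity-profile amplitudes, nm/ps
#'   (one value per analysis frame).
#' @param A acceleration amplitude, nm/ps^2.
#' @param rho mass density, kg/m^3.
#' @param L_z box height, nm.
#' @return A list with \code{eta} (cP), \code{v_max} (nm/ps) and its
#'   standard error.
#' @export
viscosity_cosine_flow <- function(v_amplitude_series, A, rho, L_z) {
  if (A <= 0) stop("acceleration amplitude must be positive")
  if (L_z <= 0) stop("box height must be positive")
  v_max <- mean(v_amplitude_series)
  if (v_max <= 0) stop("non-positive mean velocity amplitude")
  k <- 2 * pi / L_z
  # A rho / (v k^2): (nm/ps^2)(kg/m^3)/((nm/ps)(1/nm^2)) = 1e-6 Pa s = 1e-3 cP
  eta <- A * rho / (v_max * k^2) * 1e-3
  se <- if (length(v_amplitude_series) > 1)
    stats::sd(v_amplitude_series) / sqrt(length(v_amplitude_series)) else NA_real_
  list(eta = eta, v_max = v_max, v_max_se = se)
}
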