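#' Mass-density profiles along the long axis of a slab configuration
#'
#' Bins site masses along z and normalizes by bin volume to kg/m^3, per
#' species and total. Binning is per site, so the profile integrates exactly
#' to the total mass in the box.
#'
#' @param config a \code{\link{site_configuration}} (orthorhombic box, long
#'   axis = z).
#' @param n_bins number of uniform z bins.
#' @return A list of class \code{slab_profile}: \code{z} (bin centers, nm),
#'   \code{rho} (data.frame with one column per species plus \code{total},
#'   kg/m^3), \code{box}, \code{bin_volume} (nm^3).
#' @export
slab_density_profiles <- function(config, n_bins = 100) {
  s <- config$sites; box <- config$box
  if (nrow(s) == 0) stop("empty site selection")
  k <- phys_constants()
  mass <- ifelse(s$element == "O", k$m_O, k$m_H)      # g/mol
  z <- s$z %% box[3]
  bin <- pmin(floor(z / (box[3] / n_bins)) + 1L, n_bins)
  bin_volume <- box[1] * box[2] * box[3] / n_bins     # nm^3
  to_kgm3 <- k$amu_to_kg / (bin_volume * 1e-27)
  species <- sort(unique(s$species))
  rho <- as.data.frame(lapply(species, function(sp) {
    m <- tapply(mass[s$species == sp], factor(bin[s$species == sp],
                                              levels = seq_len(n_bins)), sum)
    ifelse(is.na(m), 0, m) * to_kgm3
  }))
  names(rho) <- species
  rho$total <- rowSums(rho)
  structure(list(z = (seq_len(n_bins) - 0.5) * box[3] / n_bins,
                 rho = rho, box = box, bin_volume = bin_volume),
            class = "slab_profile")
}

#' Partition a slab density profile into coexisting phases
#'
#' Fits the standard two-interface hyperbolic-tangent form
#' rho(z) = rho_v + (rho_l - rho_v)/2 [tanh((z - z1)/w) - tanh((z - z2)/w)]
#' and returns the bulk plateau densities and interface geometry.
#'
#' @param profile a \code{\link{slab_profile}}, or a data.frame with columns
#'   \code{z} and \code{rho}.
#' @param column which density column to fit when a \code{slab_profile} is
#'   given (default \code{"total"}).
#' @return A list with \code{rho_l}, \code{rho_v} (kg/m^3), \code{z1},
#'   \code{z2} (interface positions, nm), \code{width} (nm) and the fit.
#' @export
partition_phases <- function(profile, column = "total") {
  if (inherits(profile, "slab_profile")) {
    df <- data.frame(z = profile$z, rho = profile$rho[[column]])
  } else df <- profile[, c("z", "rho")]
  lo <- min(df$rho); hi <- max(df$rho)
  if (hi - lo < 0.05 * max(hi, 1))
    stop("single-phase input: no density contrast along z")
  mid <- (lo + hi) / 2
  dense <- df$z[df$rho > mid]
  start <- list(rho_l = hi, rho_v = lo, z1 = min(dense), z2 = max(dense),
                w = diff(range(df$z)) / 40)
  fit <- try(minpack.lm::nlsLM(
    rho ~ rho_v + (rho_l - rho_v) / 2 * (tanh((z - z1) / w) - tanh((z - z2) / w)),
    data = df, start = start,
    lower = c(rho_l = 0, rho_v = 0, z1 = min(df$z), z2 = min(df$z), w = 1e-4),
    upper = c(rho_l = Inf, rho_v = Inf, z1 = max(df$z), z2 = max(df$z),
              w = diff(range(df$z))),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("interface fit failed: ", attr(fit, "condition")$message)
  cf <- as.list(stats::coef(fit))
  list(rho_l = cf$rho_l, rho_v = cf$rho_v, z1 = cf$z1, z2 = cf$z2,
       width = cf$w, fit = fit)
}

#' Weight percent of peroxide in each coexisting phase
#'
#' @param rho_l,rho_v named numeric vectors with components \code{H2O2} and
#'   \code{H2O} (partial mass densities in each phase, kg/m^3).
#' @return \code{list(wt_l, wt_v)} in percent.
#' @export
phase_weight_percent <- function(rho_l, rho_v) {
  wt <- function(r) {
    if (any(r < 0)) stop("densities must be non-negative")
    tot <- sum(r[c("H2O2", "H2O")])
    if (!is.finite(tot) || tot <= 0)
      stop("undefined composition: both species zero in a phase")
    100 * r[["H2O2"]] / tot
  }
  list(wt_l = wt(rho_l), wt_v = wt(rho_v))
}
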