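#' Labeled site configuration in a periodic box
#'
#' @param sites data.frame with columns \code{molecule} (id), \code{species}
#'   (\code{"H2O2"} or \code{"H2O"}), \code{name} (site label),
#'   \code{element} (\code{"O"} or \code{"H"}), \code{x}, \code{y}, \code{z}
#'   (nm).
#' @param box orthorhombic box lengths \code{c(Lx, Ly, Lz)}, nm.
#' @return A list of class \code{site_configuration}.
#' @export
site_configuration <- function(sites, box) {
  need <- c("molecule", "species", "name", "element", "x", "y", "z")
  if (!all(need %in% names(sites)))
    stop("sites must have columns: ", paste(need, collapse = ", "))
  if (length(box) != 3 || any(box <= 0))
    stop("box must be three positive lengths")
  structure(list(sites = sites, box = as.numeric(box)),
            class = "site_configuration")
}

#' Geometric hydrogen-bond criterion
#'
#' @param r_cut donor-acceptor O...O distance cutoff, nm.
#' @param theta_cut angle cutoff, degrees, in (0, 90).
#' @return A list of class \code{hbond_criterion}.
#' @export
hbond_criterion <- function(r_cut = 0.35, theta_cut = 30) {
  if (r_cut <= 0) stop("r_cut must be positive")
  if (theta_cut <= 0 || theta_cut >= 90)
    stop("theta_cut must lie in (0, 90) degrees")
  structure(list(r_cut = r_cut, theta_cut = theta_cut),
            class = "hbond_criterion")
}

min_image <- function(d, box) d - box * round(d / box)

#' Count geometric hydrogen bonds
#'
#' A bond is counted when the donor-oxygen to acceptor-oxygen distance is at
#' most \code{r_cut} (minimum image in an orthorhombic box) and the
#' hydrogen-donor-acceptor angle (vertex at the donor oxygen) is at most
#' \code{theta_cut}. Each hydrogen is covalently assigned to the nearest
#' oxygen of its own molecule. Set \code{angle_vertex = "hydrogen"} to use
#' the donor-hydrogen-acceptor angle (vertex at H, cutoff then means
#' deviation from linearity, 180 - theta).
#'
#' @param config a \code{\link{site_configuration}}.
#' @param crit an \code{\link{hbond_criterion}}.
#' @param angle_vertex \code{"donor"} (default) or \code{"hydrogen"}.
#' @return A list with \code{counts} (peroxide_peroxide, water_water, cross,
#'   total) and \code{n_h} normalizations: \code{per_peroxide_O}
#'   (peroxide-peroxide and cross bonds per peroxide oxygen),
#'   \code{water_per_molecule} (water-water bonds per water molecule),
#'   \code{per_total_O} (all bonds per oxygen atom).
#' @export
hydrogen_bonds <- function(config, crit = hbond_criterion(),
                           angle_vertex = c("donor", "hydrogen")) {
  angle_vertex <- match.arg(angle_vertex)
  s <- config$sites; box <- config$box
  O <- s[s$element == "O", ]
  Hs <- s[s$element == "H", ]
  if (nrow(Hs) == 0 || nrow(O) == 0) stop("configuration lacks O or H sites")
  Opos <- as.matrix(O[, c("x", "y", "z")])
  # covalent assignment: nearest same-molecule oxygen for each hydrogen
  h_owner <- vapply(seq_len(nrow(Hs)), function(i) {
    cand <- which(O$molecule == Hs$molecule[i])
    if (length(cand) == 0) stop("hydrogen without an oxygen in its molecule")
    d2 <- rowSums((Opos[cand, , drop = FALSE] -
                   matrix(unlist(Hs[i, c("x", "y", "z")]), length(cand), 3,
                          byrow = TRUE))^2)
    cand[which.min(d2)]
  }, integer(1))
  counts <- c(peroxide_peroxide = 0, water_water = 0, cross = 0, total = 0)
  cosmin <- cos(crit$theta_cut * pi / 180)
  for (ih in seq_len(nrow(Hs))) {
    id <- h_owner[ih]
    hd <- as.numeric(Hs[ih, c("x", "y", "z")])
    dpos <- Opos[id, ]
    for (ia in seq_len(nrow(O))) {
      if (O$molecule[ia] == O$molecule[id]) next
      dda <- min_image(Opos[ia, ] - dpos, box)
      r <- sqrt(sum(dda^2))
      if (r > crit$r_cut) next
      if (angle_vertex == "donor") {
        dh <- min_image(hd - dpos, box)
        ct <- sum(dh * dda) / sqrt(sum(dh^2)) / r
        ok <- ct >= cosmin
      } else {
        ha <- min_image(Opos[ia, ] - hd, box)
        hdv <- min_image(dpos - hd, box)
        ang <- vec_angle(ha, hdv)
        ok <- (180 - ang) <= crit$theta_cut
      }
      if (!ok) next
      pair <- sort(c(O$species[id], O$species[ia]))
      key <- if (all(pair == "H2O2")) "peroxide_peroxide"
             else if (all(pair == "H2O")) "water_water" else "cross"
      counts[key] <- counts[key] + 1
      counts["total"] <- counts["total"] + 1
    }
  }
  n_perox_O <- sum(O$species == "H2O2")
  n_water_mol <- length(unique(s$molecule[s$species == "H2O"]))
  list(counts = as.list(counts),
       n_h = list(
         per_peroxide_O = if (n_perox_O > 0)
           (counts[["peroxide_peroxide"]] + counts[["cross"]]) / n_perox_O
           else NA_real_,
         water_per_molecule = if (n_water_mol > 0)
           counts[["water_water"]] / n_water_mol else NA_real_,
         per_total_O = counts[["total"]] / nrow(O)))
}
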