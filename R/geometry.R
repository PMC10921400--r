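#' Construct the Cartesian conformation of one H2O2 molecule
#'
#' Builds the four sites of the H1-O1-O2-H2 bonded chain from the model's
#' internal coordinates with the dihedral set to \code{a_d}. O1 sits at the
#' origin, O2 on the +x axis, H1 in the xy plane (positive y); the sign of
#' \code{a_d} sets the chirality.
#'
#' @param params \code{\link{model_parameters}} supplying d_OO, d_OH, a_HOO.
#' @param a_d dihedral angle, degrees (IUPAC: cis = 0, trans = +/-180).
#' @return An object of class \code{conformation}: a 4 x 3 matrix (nm) with
#'   rows H1, O1, O2, H2.
#' @export
#' @examples
#' conf <- build_conformation(model_parameters(), 104)
#' measure_internal_coordinates(conf)$a_d
build_conformation <- function(params, a_d) {
  validate_model_parameters(params)
  a <- params$a_HOO * pi / 180
  phi <- a_d * pi / 180
  O1 <- c(0, 0, 0)
  O2 <- c(params$d_OO, 0, 0)
  H1 <- params$d_OH * c(cos(a), sin(a), 0)
  # O2 -> H2 makes angle a_HOO with O2 -> O1 (-x); its perpendicular
  # component is rotated by the dihedral about the O-O axis.
  H2 <- O2 + params$d_OH * c(-cos(a), sin(a) * cos(phi), sin(a) * sin(phi))
  conf <- rbind(H1 = H1, O1 = O1, O2 = O2, H2 = H2)
  colnames(conf) <- c("x", "y", "z")
  structure(conf, class = c("conformation", "matrix", "array"))
}

as_conformation <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4, 3)) || any(!is.finite(m)))
    stop("a conformation is a finite 4 x 3 matrix (rows H1, O1, O2, H2)")
  if (is.null(rownames(m))) rownames(m) <- c("H1", "O1", "O2", "H2")
  m
}

vec_angle <- function(u, v) {
  acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# signed IUPAC dihedral for the chain p1-p2-p3-p4 (cis = 0)
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-24 || sum(n2^2) < 1e-24)
    stop("undefined dihedral: collinear O-O-H geometry")
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  atan2(y, x) * 180 / pi
}

#' Measure internal coordinates of a conformation
#'
#' Inverse of \code{\link{build_conformation}}: recovers bond lengths, the
#' two H-O-O angles and the signed dihedral from Cartesian coordinates.
#'
#' @param conf a \code{conformation} (4 x 3 matrix, rows H1, O1, O2, H2).
#' @return A list with \code{d_OO}, \code{d_OH1}, \code{d_OH2} (nm),
#'   \code{a_HOO1}, \code{a_HOO2} (degrees) and the signed dihedral
#'   \code{a_d} in (-180, 180].
#' @export
measure_internal_coordinates <- function(conf) {
  conf <- as_conformation(conf)
  H1 <- conf["H1", ]; O1 <- conf["O1", ]; O2 <- conf["O2", ]; H2 <- conf["H2", ]
  list(d_OO = sqrt(sum((O2 - O1)^2)),
       d_OH1 = sqrt(sum((H1 - O1)^2)),
       d_OH2 = sqrt(sum((H2 - O2)^2)),
       a_HOO1 = vec_angle(H1 - O1, O2 - O1),
       a_HOO2 = vec_angle(H2 - O2, O1 - O2),
       a_d = dihedral_angle(H1, O1, O2, H2))
}

#' Molecular dipole moment
#'
#' mu = q_H (r_H1 + r_H2 - r_O1 - r_O2). At equilibrium bonds and angles the
#' magnitude has the closed form 2 q_H d_OH sin(a_HOO) |cos(a_d / 2)|, so it
#' vanishes at trans and grows monotonically as |a_d| decreases.
#'
#' @param conf a \code{conformation}.
#' @param q_H hydrogen partial charge, e.
#' @return A list with \code{mu} (vector, e nm), \code{magnitude_enm} and
#'   \code{magnitude_D} (debye).
#' @export
#' @examples
#' molecular_dipole(build_conformation(model_parameters(), 115), 0.4323)
molecular_dipole <- function(conf, q_H) {
  conf <- as_conformation(conf)
  mu <- q_H * (conf["H1", ] + conf["H2", ] - conf["O1", ] - conf["O2", ])
  m <- sqrt(sum(mu^2))
  list(mu = mu, magnitude_enm = m,
       magnitude_D = m * phys_constants()$enm_to_debye)
}

#' Closed-form dipole magnitude at equilibrium bonds and angles
#'
#' @param params \code{\link{model_parameters}}.
#' @param a_d dihedral, degrees (vectorized).
#' @return Magnitude in debye.
#' @export
dipole_magnitude_closed_form <- function(params, a_d) {
  m <- 2 * params$q_H * params$d_OH * sin(params$a_HOO * pi / 180) *
    abs(cos(a_d * pi / 360))
  m * phys_constants()$enm_to_debye
}
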