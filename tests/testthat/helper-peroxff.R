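# Shared fixtures for the test suite.

# Draw one random physical parameter vector uniformly inside the sweep ranges.
random_params <- function(ranges = parameter_ranges()) {
  u <- stats::runif(7)
  p <- as.list(denormalize_params(u, ranges))
  do.call(model_parameters, p)
}

# A minimal hydrogen-bonded pair: a water donating one bond to a water
# acceptor along +x (O...O distance 0.3 nm, donor H on the O-O axis).
# Exactly one geometric hydrogen bond exists in this configuration.
hb_pair_sites <- function(origin = c(1, 1, 1), species = c("H2O", "H2O")) {
  o <- origin
  data.frame(
    molecule = c(1, 1, 1, 2, 2, 2),
    species = rep(species, each = 3),
    name = c("OW", "HW1", "HW2", "OW", "HW1", "HW2"),
    element = c("O", "H", "H", "O", "H", "H"),
    x = o[1] + c(0, 0.1, 0, 0.3, 0.3, 0.3),
    y = o[2] + c(0, 0, 0.1, 0, -0.1, 0),
    z = o[3] + c(0, 0, 0, 0, 0, -0.1))
}

# Random proper rotation matrix (QR with positive diagonal, det fixed to +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Noise-free two-interface tanh slab profile as a plain data.frame.
tanh_profile <- function(rho_l, rho_v, L_z = 18, width = 0.4, dz = 0.1) {
  z <- seq(dz / 2, L_z - dz / 2, by = dz)
  data.frame(z = z, rho = rho_v + (rho_l - rho_v) / 2 *
               (tanh((z - L_z / 3) / width) - tanh((z - 2 * L_z / 3) / width)))
}
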