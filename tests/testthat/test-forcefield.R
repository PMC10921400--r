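test_that("model parameters validate and default to the optimized set", {
  p <- model_parameters()
  expect_s3_class(p, "model_parameters")
  expect_identical(as.numeric(as_param_vector(p)[c("c2", "q_H")]),
                   c(26.91, 0.4323))
  expect_error(model_parameters(c2 = -1), "positive")
  expect_error(model_parameters(a_HOO = 200), "a_HOO")
  expect_error(parameter_ranges(lower = c(c2 = 30), upper = c(c2 = 26)),
               "seven parameters")
  r <- parameter_ranges()
  expect_true(all(as_param_vector(p) >= r$lower & as_param_vector(p) <= r$upper))
})

test_that("RB coefficient expansion follows the fixed constraints", {
  cf <- expand_rb_coefficients(26.91)
  expect_equal(unname(cf["c0"]), 8.39592)
  expect_equal(unname(cf["c1"]), -26.91)
  expect_equal(unname(cf["c3"]), 0.3 * 26.91)
  expect_identical(unname(cf[c("c4", "c5")]), c(0, 0))
  # linearity in c2
  expect_equal(expand_rb_coefficients(2 * 26.91), 2 * cf)
  expect_error(expand_rb_coefficients(0), "positive")
  expect_error(expand_rb_coefficients(NA_real_), "finite")
})

test_that("RB energy has the known cis/trans values and symmetries", {
  cf <- expand_rb_coefficients(26.91)
  expect_equal(rb_energy(180, cf), 26.91 * 0.612)  # trans: x = 1
  expect_equal(rb_energy(0, cf), 26.91 * 2.012)    # cis: x = -1
  a <- stats::runif(1000, -180, 180)
  # even and 360-periodic in the dihedral
  expect_equal(rb_energy(a, cf), rb_energy(-a, cf), tolerance = 1e-12)
  expect_equal(rb_energy(a, cf), rb_energy(a + 360, cf), tolerance = 1e-10)
  expect_error(rb_energy(90, cf[1:3]), "six")
})

test_that("dihedral profile reproduces the analytic minimum and barriers", {
  prof <- dihedral_profile(model_parameters())
  expect_equal(prof$a_d_min, 114.863, tolerance = 1e-4)
  expect_equal(prof$v_min, 0.09062612 * 26.91, tolerance = 1e-6)
  expect_equal(prof$cis_barrier, 54.14292 - 2.438749, tolerance = 1e-4)
  expect_equal(prof$trans_barrier, 16.46892 - 2.438749, tolerance = 1e-4)
  # barrier ordering is structural: the cis barrier is the large one
  expect_gt(prof$cis_barrier, prof$trans_barrier)
  expect_error(dihedral_profile(model_parameters(), grid_step = 0), "grid_step")
})

test_that("gas reference and internal energy follow U_g(T) = U_g_min + 3RT", {
  ref <- gas_minimum(model_parameters())
  expect_equal(ref$u_g_min, 2.438749, tolerance = 1e-5)
  R <- 8.31446e-3
  expect_equal(gas_internal_energy(300, ref) - gas_internal_energy(0, ref),
               3 * R * 300, tolerance = 1e-10)
  expect_error(gas_internal_energy(-1, ref), "non-negative")
  # the published reference value is configurable, not derived
  ref2 <- gas_reference(114.9, -1.53)
  expect_equal(gas_internal_energy(0, ref2), -1.53)
})

test_that("conformation build/measure is an exact round trip", {
  set.seed(11)
  for (i in 1:50) {
    p <- random_params()
    a_d <- stats::runif(1, -179.5, 179.5)
    ic <- measure_internal_coordinates(build_conformation(p, a_d))
    expect_equal(ic$d_OO, p$d_OO, tolerance = 1e-10)
    expect_equal(ic$d_OH1, p$d_OH, tolerance = 1e-10)
    expect_equal(ic$d_OH2, p$d_OH, tolerance = 1e-10)
    expect_equal(ic$a_HOO1, p$a_HOO, tolerance = 1e-8)
    expect_equal(ic$a_HOO2, p$a_HOO, tolerance = 1e-8)
    expect_equal(ic$a_d, a_d, tolerance = 1e-8)
  }
})

test_that("internal coordinates are invariant under rigid motions", {
  set.seed(12)
  conf <- build_conformation(model_parameters(), 114.9)
  ic0 <- measure_internal_coordinates(conf)
  for (i in 1:20) {
    Rm <- random_rotation()
    t <- stats::rnorm(3)
    moved <- conf %*% t(Rm) + matrix(t, 4, 3, byrow = TRUE)
    rownames(moved) <- rownames(conf)
    ic <- measure_internal_coordinates(moved)
    for (nm in names(ic0)) expect_equal(ic[[nm]], ic0[[nm]], tolerance = 1e-8)
  }
})

test_that("known H-H distances come out of the optimized geometry", {
  p <- model_parameters()
  d_hh <- function(a_d) {
    conf <- build_conformation(p, a_d)
    sqrt(sum((conf["H1", ] - conf["H2", ])^2))
  }
  expect_equal(d_hh(104), 0.2261359, tolerance = 1e-6)
  expect_equal(d_hh(180), 0.2559707, tolerance = 1e-6)
  # the distance grows monotonically from cis to trans
  d <- vapply(seq(0, 180, 5), d_hh, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("site-sum dipole matches the closed form and known value", {
  p <- model_parameters()
  mu <- molecular_dipole(build_conformation(p, 115), p$q_H)
  expect_equal(mu$magnitude_D, 2.173323, tolerance = 1e-5)
  expect_equal(mu$magnitude_D, dipole_magnitude_closed_form(p, 115),
               tolerance = 1e-12)
  # vanishes at trans, maximal at cis
  expect_lt(molecular_dipole(build_conformation(p, 180), p$q_H)$magnitude_D,
            1e-12)
  d <- dipole_magnitude_closed_form(p, seq(0, 180, 5))
  expect_true(all(diff(d) < 0))
})

test_that("intramolecular energy is the RB term at equilibrium geometry", {
  p <- model_parameters()
  for (a_d in c(-170, -90, 0.5, 60, 114.863, 179)) {
    e <- intramolecular_energy(build_conformation(p, a_d), p)
    expect_equal(e$bond, 0, tolerance = 1e-18)
    expect_equal(e$angle, 0, tolerance = 1e-14)
    expect_equal(e$dihedral, rb_energy(a_d, expand_rb_coefficients(p$c2)),
                 tolerance = 1e-9)
    expect_identical(e$intra_coulomb, 0)
    expect_equal(e$total, e$bond + e$angle + e$dihedral + e$intra_coulomb)
  }
})

test_that("the 1-4 exclusion policy adds the scaled H-H Coulomb term", {
  p <- model_parameters()
  pol <- exclusion_policy("opls_14_half")
  e <- intramolecular_energy(build_conformation(p, 115), p, policy = pol)
  expect_equal(e$intra_coulomb, 55.57671, tolerance = 1e-5)
  # half of the full 1-4 interaction by construction
  pol_full <- exclusion_policy("opls_14_half", fudge_qq = 1)
  e_full <- intramolecular_energy(build_conformation(p, 115), p,
                                  policy = pol_full)
  expect_equal(e_full$intra_coulomb, 2 * e$intra_coulomb, tolerance = 1e-12)
  expect_error(exclusion_policy("opls_14_half", fudge_qq = 2), "fudge_qq")
})

test_that("distorted geometries pick up harmonic bond and angle energy", {
  p <- model_parameters()
  fc <- force_constants()
  conf <- build_conformation(p, 115)
  conf["H1", ] <- conf["O1", ] + (conf["H1", ] - conf["O1", ]) *
    (p$d_OH + 0.001) / p$d_OH
  e <- intramolecular_energy(conf, p, fc)
  expect_equal(e$bond, 0.5 * fc$kb_OH * 0.001^2, tolerance = 1e-6)
  expect_equal(e$angle, 0, tolerance = 1e-12)
})

test_that("intermolecular energy is symmetric, neutral and guards overlap", {
  p <- model_parameters()
  A <- build_conformation(p, 115)
  B <- build_conformation(p, -115) + 0.5
  rownames(B) <- rownames(A)
  expect_equal(intermolecular_energy(A, B, p),
               intermolecular_energy(B, A, p), tolerance = 1e-12)
  # charge-neutral molecules: the energy decays faster than a monopole pair
  far <- A + 50
  rownames(far) <- rownames(A)
  e_far <- intermolecular_energy(A, far, p)
  expect_lt(abs(e_far), 1e-4)
  expect_error(intermolecular_energy(A, A, p), "singular")
})
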