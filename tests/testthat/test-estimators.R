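test_that("alpha_P from the density fit recovers a linear rho(T) exactly", {
  T <- seq(270, 340, 10)
  rho <- 2000 - 1.4 * T
  out <- alpha_p_from_fit(data.frame(T = T, rho = rho))
  expect_equal(out$rho_fit, rho, tolerance = 1e-9)
  expect_equal(out$alpha_P, 1.4 / rho, tolerance = 1e-9)
  # invariant under a constant temperature shift of the fit grid
  out2 <- alpha_p_from_fit(data.frame(T = T + 500, rho = rho))
  expect_equal(out2$alpha_P, out$alpha_P, tolerance = 1e-9)
  expect_error(alpha_p_from_fit(data.frame(T = c(1, 2, 3), rho = 1:3)),
               "at least 4")
})

test_that("NPT fluctuation estimators invert the generating moments", {
  targets <- list(kappa_T = 4e-5, alpha_P = 7e-4, C_P = 0.09)
  g <- gen_fluctuation_series(targets,
                              list(T = 293, V = 140, n_frames = 2e5,
                                   n_molecules = 4350), seed = 101)
  fl <- npt_fluctuations(g$thermo)
  expect_equal(fl$kappa_T$value, targets$kappa_T, tolerance = 0.03)
  expect_equal(fl$alpha_P$value, targets$alpha_P, tolerance = 0.03)
  expect_equal(fl$C_P$value, targets$C_P, tolerance = 0.03)
  for (nm in c("kappa_T", "alpha_P", "C_P")) {
    expect_gt(fl[[nm]]$value, 0)
    expect_true(is.finite(fl[[nm]]$error))
    expect_lte(fl[[nm]]$discarded, 10)
  }
})

test_that("degenerate thermo series are rejected or flagged", {
  short <- thermo_series(1:10, rep(1, 10), rep(140, 10), rep(1, 10),
                         rep(293, 10), rep(1, 10), 100)
  expect_error(npt_fluctuations(short), "at least 1000")
  n <- 2000
  flat <- thermo_series(1:n, rep(-100, n), rep(140, n), rep(-100, n),
                        rep(293, n), rep(1, n), 100)
  expect_warning(fl <- npt_fluctuations(flat), "zero fluctuations")
  expect_identical(fl$kappa_T$value, 0)
  expect_error(thermo_series(1:3, 1:3, c(1, -1, 1), 1:3, 1:3, 1:3, 10),
               "positive")
})

test_that("derived caloric quantities satisfy the exact relations", {
  # alpha_P = 0 decouples the ensembles: C_V = C_P and kappa_S = kappa_T
  r0 <- derived_caloric(0, 4e-5, 0.09, 293, 140, 4350)
  expect_identical(r0$C_V, r0$C_P)
  expect_identical(r0$kappa_S, r0$kappa_T)
  r <- derived_caloric(7e-4, 4e-5, 0.09, 293, 140, 4350)
  conv <- 1000 / (6.02214076e23 * 1e-27) / 1e5
  dC <- 293 * 140 * (7e-4)^2 / 4e-5 / conv / 4350
  expect_equal(r$C_V, 0.09 - dC, tolerance = 1e-12)
  expect_equal(r$kappa_S, r$kappa_T * r$C_V / r$C_P, tolerance = 1e-12)
  expect_error(derived_caloric(0.5, 4e-5, 0.09, 293, 140, 4350),
               "C_V <= 0")
  expect_error(derived_caloric(7e-4, -1, 0.09, 293, 140), "kappa_T")
})

test_that("dielectric estimator inverts the generating dipole variance", {
  g <- gen_fluctuation_series(list(epsilon = 25),
                              list(T = 293, V = 140, n_frames = 1e5),
                              seed = 202)
  est <- dielectric_constant(g$dipole)
  expect_equal(est$value, 25, tolerance = 0.05)
  # a frozen box dipole has no fluctuations: eps = 1 exactly
  n <- 2000
  ds <- dipole_series(1:n, matrix(5, n, 3), 140, 293)
  expect_equal(dielectric_constant(ds)$value, 1)
  expect_error(dielectric_constant(dipole_series(1:10, matrix(0, 10, 3),
                                                 140, 293)), "1000")
})

test_that("Einstein diffusion fit is exact on a noiseless MSD line", {
  D <- 1.5e-9                       # m^2/s
  t <- seq(1, 1000, by = 1)         # ps
  msd <- data.frame(time = t, msd = 6 * (D * 1e6) * t)
  out <- diffusion_einstein(msd)
  expect_equal(out$D, D, tolerance = 1e-12)
  expect_false(out$flagged)
  # a decreasing curve is clamped and flagged
  bad <- data.frame(time = t, msd = rev(msd$msd))
  expect_warning(out_bad <- diffusion_einstein(bad), "negative")
  expect_identical(out_bad$D, 0)
  expect_true(out_bad$flagged)
  expect_error(diffusion_einstein(msd[1:12, ], fit_window = c(900, 1000)),
               "at least 10")
})

test_that("diffusion estimator recovers the random-walk input coefficient", {
  D <- 1.5e-9
  g <- gen_fluctuation_series(list(D = D),
                              list(T = 293, V = 140, n_walkers = 512,
                                   n_steps = 1e4, dt = 1), seed = 303)
  out <- diffusion_einstein(g$walk)
  expect_equal(out$D, D, tolerance = 0.03)
})

test_that("MSD curve is exact for ballistic single-particle motion", {
  n <- 200
  pos <- array(0, c(n, 1, 3))
  pos[, 1, 1] <- 0.01 * (seq_len(n) - 1)      # x = v t, v = 0.01 nm/ps
  msd <- msd_curve(pos, dt = 1, lags = c(10, 50, 100))
  expect_equal(msd$msd, (0.01 * c(10, 50, 100))^2, tolerance = 1e-12)
  # immobile particles have identically zero MSD
  msd0 <- msd_curve(array(2, c(n, 3, 3)), dt = 1, lags = c(1, 5))
  expect_identical(msd0$msd, c(0, 0))
})

test_that("cosine-flow viscosity inverts its defining relation", {
  eta <- 1.0; A <- 0.05; rho <- 1440; L_z <- 6
  k <- 2 * pi / L_z
  v <- A * rho * 1e-3 / (eta * k^2)
  out <- viscosity_cosine_flow(rep(v, 100), A, rho, L_z)
  expect_equal(out$eta, eta, tolerance = 1e-12)
  # linear in A at fixed profile amplitude
  expect_equal(viscosity_cosine_flow(rep(v, 10), 2 * A, rho, L_z)$eta,
               2 * eta, tolerance = 1e-12)
  expect_error(viscosity_cosine_flow(rep(v, 10), -1, rho, L_z), "positive")
  expect_error(viscosity_cosine_flow(rep(-v, 10), A, rho, L_z),
               "non-positive")
})

test_that("geometric hydrogen-bond counting matches constructed geometry", {
  crit <- hbond_criterion()
  cfg <- site_configuration(hb_pair_sites(), c(4, 4, 4))
  hb <- hydrogen_bonds(cfg, crit)
  expect_identical(hb$counts$total, 1)
  expect_identical(hb$counts$water_water, 1)
  expect_equal(hb$n_h$water_per_molecule, 0.5)
  # just beyond the distance cutoff: no bond
  s <- hb_pair_sites()
  s$x[4:6] <- s$x[4:6] + 0.06           # O...O = 0.36 > 0.35
  expect_identical(hydrogen_bonds(site_configuration(s, c(4, 4, 4)),
                                  crit)$counts$total, 0)
  # beyond the angular cutoff: no bond
  s2 <- hb_pair_sites()
  s2$x[2] <- s2$x[1]; s2$y[2] <- s2$y[1] + 0.1   # donor H perpendicular
  expect_identical(hydrogen_bonds(site_configuration(s2, c(4, 4, 4)),
                                  crit)$counts$total, 0)
})

test_that("hydrogen-bond counts are translation invariant and use min image", {
  crit <- hbond_criterion()
  base <- hydrogen_bonds(site_configuration(hb_pair_sites(), c(4, 4, 4)), crit)
  shifted <- hydrogen_bonds(site_configuration(
    hb_pair_sites(origin = c(2.7, 0.4, 3.1)), c(4, 4, 4)), crit)
  expect_identical(shifted$counts, base$counts)
  # donor and acceptor on opposite faces of the box: bonded through the wall
  s <- hb_pair_sites(origin = c(0, 0, 0))
  s$x <- c(0.1, 0.0, 0.1, 3.9, 3.9, 3.9)   # O...O naive 3.8, min image 0.2
  s$y[2] <- 0; s$x[2] <- 0.0               # donor H points toward -x
  wrapped <- hydrogen_bonds(site_configuration(s, c(4, 4, 4)), crit)
  expect_identical(wrapped$counts$total, 1)
})

test_that("hydrogen bonds are classified by species pair", {
  s <- hb_pair_sites(species = c("H2O2", "H2O"))
  hb <- hydrogen_bonds(site_configuration(s, c(4, 4, 4)))
  expect_identical(hb$counts$cross, 1)
  expect_identical(hb$counts$water_water, 0)
  expect_equal(hb$n_h$per_peroxide_O, 1)   # one cross bond, one peroxide O
  s2 <- hb_pair_sites(species = c("H2O2", "H2O2"))
  hb2 <- hydrogen_bonds(site_configuration(s2, c(4, 4, 4)))
  expect_identical(hb2$counts$peroxide_peroxide, 1)
  # the hydrogen-vertex variant accepts the same linear bond
  hb3 <- hydrogen_bonds(site_configuration(hb_pair_sites(), c(4, 4, 4)),
                        angle_vertex = "hydrogen")
  expect_identical(hb3$counts$total, 1)
  expect_error(hbond_criterion(theta_cut = 95), "90")
})

test_that("enthalpy of vaporization follows its defining relation", {
  R <- 8.31446e-3
  ref <- gas_reference(114.9, -1.53)
  expect_equal(enthalpy_of_vaporization(-42.5, 300, ref),
               -1.53 + 3 * R * 300 - (-42.5) + R * 300, tolerance = 1e-12)
  # rigid reference drops the 3RT intramolecular term
  expect_equal(enthalpy_of_vaporization(-42.5, 300, ref, rigid = TRUE),
               -1.53 + 42.5 + R * 300, tolerance = 1e-12)
  expect_error(enthalpy_of_vaporization(-42.5, -1, ref), "positive")
})

test_that("self-polarization correction reproduces the known bounds", {
  expect_equal(self_polarization_correction(2.69, 2.05), 6.570054,
               tolerance = 1e-5)
  expect_equal(self_polarization_correction(2.69, 2.26), 2.965827,
               tolerance = 1e-5)
  expect_identical(self_polarization_correction(2.05, 2.05), 0)
  # quadratic in the dipole difference
  expect_equal(self_polarization_correction(2.45, 2.05),
               4 * self_polarization_correction(2.25, 2.05),
               tolerance = 1e-12)
  expect_error(self_polarization_correction(2.69, 2.05, alpha_volume = 0),
               "positive")
})
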