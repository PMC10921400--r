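test_that("slab density profiles conserve mass and find flat plateaus", {
  set.seed(21)
  n_mol <- 200
  sites <- do.call(rbind, lapply(seq_len(n_mol), function(m) {
    base <- c(runif(1, 0, 4), runif(1, 0, 4), runif(1, 0, 6))
    conf <- build_conformation(model_parameters(), 115)
    data.frame(molecule = m, species = "H2O2", name = rownames(conf),
               element = substr(rownames(conf), 1, 1),
               x = base[1] + conf[, 1], y = base[2] + conf[, 2],
               z = base[3] + conf[, 3])
  }))
  cfg <- site_configuration(sites, c(4, 4, 6))
  prof <- slab_density_profiles(cfg, n_bins = 60)
  # binned mass integrates exactly to the box mass (site-wise binning)
  k <- phys_constants()
  total_kg <- sum(prof$rho$total) * prof$bin_volume * 1e-27
  expect_equal(total_kg, n_mol * (2 * k$m_O + 2 * k$m_H) * k$amu_to_kg,
               tolerance = 1e-12)
  expect_named(prof$rho, c("H2O2", "total"))
  expect_error(slab_density_profiles(site_configuration(sites[0, ],
                                                        c(4, 4, 6))),
               "empty")
})

test_that("tanh partition recovers noise-free plateau densities exactly", {
  fit <- partition_phases(tanh_profile(1400, 5))
  expect_equal(fit$rho_l, 1400, tolerance = 1e-6)
  expect_equal(fit$rho_v, 5, tolerance = 1e-4)
  expect_equal(fit$z1, 6, tolerance = 1e-4)
  expect_equal(fit$z2, 12, tolerance = 1e-4)
  expect_equal(fit$width, 0.4, tolerance = 1e-4)
  flat <- data.frame(z = seq(0.05, 17.95, 0.1), rho = 1400)
  expect_error(partition_phases(flat), "single-phase")
})

test_that("phase weight percent is plain composition arithmetic", {
  wt <- phase_weight_percent(c(H2O2 = 900, H2O = 300), c(H2O2 = 1, H2O = 3))
  expect_equal(wt$wt_l, 75)
  expect_equal(wt$wt_v, 25)
  expect_error(phase_weight_percent(c(H2O2 = 0, H2O = 0), c(H2O2 = 1, H2O = 1)),
               "both species zero")
  expect_error(phase_weight_percent(c(H2O2 = -1, H2O = 1), c(H2O2 = 1, H2O = 1)),
               "non-negative")
})

test_that("vapor pressure routes switch at the stated threshold", {
  # ideal-gas route on pure peroxide vapor at 423 K
  out <- vapor_pressure(rho_v = c(H2O2 = 1), T = 423)
  expect_equal(out$P_v, 1.03397, tolerance = 1e-5)
  expect_identical(out$route, "ideal")
  # high pressure: the virial route wins even when both inputs are present
  hi <- vapor_pressure(P_zz = 5, rho_v = c(H2O2 = 5), T = 423)
  expect_identical(hi$route, "virial")
  expect_identical(hi$P_v, 5)
  # low pressure: switches to ideal
  lo <- vapor_pressure(P_zz = 0.9, rho_v = c(H2O2 = 1), T = 423)
  expect_identical(lo$route, "ideal")
  # mixture: partial pressures add
  mix <- vapor_pressure(rho_v = c(H2O2 = 1, H2O = 1), T = 423)
  one <- vapor_pressure(rho_v = c(H2O2 = 1), T = 423)$P_v
  two <- vapor_pressure(rho_v = c(H2O = 1), T = 423)$P_v
  expect_equal(mix$P_v, one + two, tolerance = 1e-12)
  expect_error(vapor_pressure(rho_v = c(H2O2 = -1), T = 423), "non-negative")
  expect_error(vapor_pressure(), "supply")
})

test_that("surface tension is the anisotropy integral of the slab", {
  expect_equal(surface_tension(c(0, 0, 100), 18), 90)
  # isotropic pressure: zero tension; inverted anisotropy: negative
  expect_equal(surface_tension(c(50, 50, 50), 18), 0)
  expect_lt(surface_tension(c(100, 100, 0), 18), 0)
  expect_error(surface_tension(c(0, 0, 100), -1), "positive")
  expect_error(surface_tension(c(0, 100), 18), "P_diag")
})

test_that("boiling temperature is recovered from a Clausius-Clapeyron curve", {
  R <- 8.31446e-3
  T_b <- 423.3; dh <- 45
  T <- seq(380, 460, 10)
  pv <- data.frame(T = T, P_v = 1.013 * exp(-dh / R * (1 / T - 1 / T_b)))
  expect_equal(boiling_temperature(pv), T_b, tolerance = 1 / T_b)
  # all points above atmospheric pressure: no bracketing
  expect_error(boiling_temperature(data.frame(T = T, P_v = pv$P_v + 5)),
               "bracketing")
})

test_that("critical fit inverts noise-free rectilinear/scaling data exactly", {
  truth <- list(T_c = 700, rho_c = 400, A = 0.55, B = 65)
  fx <- gen_coexistence_fixtures(truth, seq(450, 680, length.out = 8),
                                 noise = 0)
  fit <- critical_point(fx$coex, fx$pv_table)
  expect_equal(fit$T_c, truth$T_c, tolerance = 1e-5)
  expect_equal(fit$rho_c, truth$rho_c, tolerance = 1e-5)
  expect_equal(fit$A, truth$A, tolerance = 1e-4)
  expect_equal(fit$B, truth$B, tolerance = 1e-4)
  # the generated pv table is exactly exponential, so P_c extrapolates exactly
  R <- 8.31446e-3
  T_ref <- stats::median(fx$pv_table$T)
  expect_equal(fit$P_c,
               1.013 * exp(-45 / R * (1 / truth$T_c - 1 / T_ref)),
               tolerance = 1e-5)
  swapped <- fx$coex
  names(swapped) <- c("T", "rho_v", "rho_l")
  expect_error(critical_point(swapped), "swapped")
  expect_error(critical_point(fx$coex[1:3, ]), "at least 4")
})

test_that("noisy critical fits cover the truth across seeds", {
  truth <- list(T_c = 700, rho_c = 400, A = 0.55, B = 65)
  err <- vapply(1:20, function(s) {
    fx <- gen_coexistence_fixtures(truth, seq(450, 680, length.out = 8),
                                   noise = 0.01, seed = s)
    critical_point(fx$coex)$T_c
  }, numeric(1))
  expect_lt(abs(mean(err) - truth$T_c),
            2 * stats::sd(err) / sqrt(length(err)) + 2)
  expect_lt(max(abs(err - truth$T_c)) / truth$T_c, 0.02)
})

test_that("Clausius-Clapeyron enthalpy matches the closed form", {
  R <- 8.31446e-3
  two <- data.frame(T = c(400, 450), P_v = c(1, 2))
  expect_equal(clausius_clapeyron_dhvap(two),
               R * log(1 / 2) / (1 / 450 - 1 / 400), tolerance = 1e-12)
  # exact on a perfect exponential with many points
  T <- seq(380, 460, 10)
  pv <- data.frame(T = T, P_v = 0.7 * exp(-45 / R / T))
  expect_equal(clausius_clapeyron_dhvap(pv), 45, tolerance = 1e-9)
  expect_error(clausius_clapeyron_dhvap(data.frame(T = c(400, 400),
                                                   P_v = c(1, 2))),
               "distinct")
  expect_error(clausius_clapeyron_dhvap(data.frame(T = c(400, 450),
                                                   P_v = c(1, -2))),
               "positive")
})

test_that("coexistence fixtures respect their own construction", {
  truth <- list(T_c = 650, rho_c = 380, A = 0.5, B = 60)
  fx <- gen_coexistence_fixtures(truth, seq(420, 600, 30), noise = 0)
  dT <- truth$T_c - fx$coex$T
  expect_equal((fx$coex$rho_l + fx$coex$rho_v) / 2,
               truth$rho_c + truth$A * dT, tolerance = 1e-12)
  expect_equal(fx$coex$rho_l - fx$coex$rho_v, truth$B * dT^0.32,
               tolerance = 1e-12)
  # slab profiles plateau at the tabulated liquid density
  fit <- partition_phases(fx$profiles[[1]])
  expect_equal(fit$rho_l, fx$coex$rho_l[1], tolerance = 1e-4)
  expect_error(gen_coexistence_fixtures(truth, c(500, 660)), "below T_c")
})
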