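test_that("inversion-recovery fit is exact on noiseless data", {
  delays <- seq(0.05, 10, length.out = 12)
  curve <- gen_relaxation_curve("inversion_recovery", rate = 0.5,
                                delays = delays)
  fit <- fit_inversion_recovery(curve)
  expect_equal(fit$rate, 0.5, tolerance = 1e-8)
  expect_equal(fit$inv_efficiency, 1, tolerance = 1e-6)
  # imperfect inversion is absorbed by the efficiency parameter
  curve2 <- gen_relaxation_curve("inversion_recovery", rate = 0.5,
                                 delays = delays, inv_efficiency = 0.93)
  fit2 <- fit_inversion_recovery(curve2)
  expect_equal(fit2$rate, 0.5, tolerance = 1e-8)
  expect_equal(fit2$inv_efficiency, 0.93, tolerance = 1e-6)
})

test_that("inversion-recovery fit recovers the rate within 2% at 1% noise", {
  delays <- seq(0.05, 8, length.out = 16)
  curve <- gen_relaxation_curve("inversion_recovery", rate = 0.8,
                                delays = delays, noise_sd = 0.01, seed = 11)
  fit <- fit_inversion_recovery(curve)
  expect_equal(fit$rate, 0.8, tolerance = 0.02)
})

test_that("degenerate relaxation inputs are rejected", {
  expect_error(relaxation_curve(c(0.1, 0.2, 0.3), c(1, 2, 3)), "at least 4")
  expect_error(relaxation_curve(c(0.1, 0.1, 0.3, 0.4), 1:4), "increasing")
  flat <- relaxation_curve(1:5, rep(2, 5), "inversion_recovery")
  expect_error(fit_inversion_recovery(flat), "constant")
  expect_error(fit_echo_decay(relaxation_curve(1:5, rep(2, 5), "echo_decay")),
               "uninformative")
  # kind mismatch
  c1 <- gen_relaxation_curve("echo_decay", 1, seq(0.1, 2, length.out = 8))
  expect_error(fit_inversion_recovery(c1), "not an inversion-recovery")
})

test_that("echo-decay fit is exact, scale invariant, and needs enough points", {
  delays <- seq(0.05, 3, length.out = 10)
  curve <- gen_relaxation_curve("echo_decay", rate = 2, delays = delays)
  fit <- fit_echo_decay(curve)
  expect_equal(fit$rate, 2, tolerance = 1e-8)
  scaled <- relaxation_curve(delays, curve$intensities * 37.5, "echo_decay")
  expect_equal(fit_echo_decay(scaled)$rate, fit$rate, tolerance = 1e-10)
  expect_error(relaxation_curve(c(0.1, 1), c(1, 0.5), "echo_decay"),
               "at least 4")
})

test_that("CSA R1 matches the extreme-narrowing closed form and scales quadratically", {
  m <- csa_model(sigma_sym_F = 163, nu0_mhz = 202.4)
  w0 <- m$omega0
  tau <- 1e-5 / w0 # deep in the extreme-narrowing regime
  closed <- m$c_sym * (w0 * 163e-6)^2 * tau
  expect_equal(csa_r1(m, tau), closed, tolerance = 1e-9)
  m2 <- csa_model(sigma_sym_F = 326, nu0_mhz = 202.4)
  expect_equal(csa_r1(m2, tau) / csa_r1(m, tau), 4, tolerance = 1e-12)
})

test_that("sym-only R1 peaks at omega0 tau2 = 1", {
  m <- csa_model(sigma_sym_F = 163, nu0_mhz = 202.4)
  taus <- 10^seq(-12, -6, length.out = 2000)
  r1 <- csa_r1(m, taus)
  expect_true(all(r1 > 0))
  peak_tau <- taus[which.max(r1)]
  expect_equal(peak_tau * m$omega0, 1, tolerance = 1e-2)
})

test_that("R1 inversion is the inverse of the forward model on the fast branch", {
  m <- csa_model(sigma_sym_F = 163, nu0_mhz = 202.4)
  w0 <- m$omega0
  for (x in c(1e-3, 1e-2, 0.1, 0.3, 0.5)) {
    tau_true <- x / w0
    inv <- invert_r1_for_tau2(csa_r1(m, tau_true), m)
    expect_equal(inv$tau2, tau_true, tolerance = 1e-8)
    expect_equal(inv$tau1, 3 * inv$tau2)
    expect_identical(inv$branch, "fast")
  }
})

test_that("R1 inversion matches a dense-grid root search and rejects excess rates", {
  m <- csa_model(sigma_sym_F = 163, nu0_mhz = 202.4)
  r1_target <- 1.2
  grid <- 10^seq(-12, log10(1 / m$omega0), length.out = 400000)
  tau_grid <- grid[which.min(abs(csa_r1(m, grid) - r1_target))]
  inv <- invert_r1_for_tau2(r1_target, m)
  expect_equal(inv$tau2, tau_grid, tolerance = 1e-4) # grid resolution bound
  # brute-force refinement to 1e-6 relative around the grid root
  fine <- seq(tau_grid * 0.999, tau_grid * 1.001, length.out = 200001)
  tau_fine <- fine[which.min(abs(csa_r1(m, fine) - r1_target))]
  expect_equal(inv$tau2, tau_fine, tolerance = 1e-6)
  expect_error(invert_r1_for_tau2(1.001 * inv$r1_max, m), "exceeds the maximum")
  expect_warning(invert_r1_for_tau2(0.999 * inv$r1_max, m), "within 1%")
})

test_that("rotational hydrodynamic radius follows the cube-root law", {
  r1x <- tau2_to_hydrodynamic_radius(1e-11, 298, 1e-3)
  r8x <- tau2_to_hydrodynamic_radius(8e-11, 298, 1e-3)
  expect_equal(r8x / r1x, 2, tolerance = 1e-12)
  # constructed identity: tau2 of a 1 Angstrom sphere maps back to 1 Angstrom
  k <- phos_constants()$boltzmann_k
  tau_id <- 4 * pi * 1e-3 * (1e-10)^3 / (3 * k * 298)
  expect_equal(tau2_to_hydrodynamic_radius(tau_id, 298, 1e-3), 1e-10,
               tolerance = 1e-12)
  # frozen desk-arithmetic value: 50 ps in D2O at 298 K
  expect_equal(tau2_to_hydrodynamic_radius(5e-11, 298, 1.095e-3),
               3.552948733e-10, tolerance = 1e-9)
  expect_error(tau2_to_hydrodynamic_radius(-1e-11), "positive")
  # monotone in tau2 and T, decreasing in eta
  expect_gt(tau2_to_hydrodynamic_radius(2e-11, 298, 1e-3),
            tau2_to_hydrodynamic_radius(1e-11, 298, 1e-3))
  expect_gt(tau2_to_hydrodynamic_radius(1e-11, 320, 1e-3),
            tau2_to_hydrodynamic_radius(1e-11, 298, 1e-3))
  expect_lt(tau2_to_hydrodynamic_radius(1e-11, 298, 2e-3),
            tau2_to_hydrodynamic_radius(1e-11, 298, 1e-3))
})

test_that("tau2 is recovered within 3% from noisy inversion-recovery data", {
  m <- csa_model(sigma_sym_F = 163, nu0_mhz = 202.4)
  tau_true <- 2e-10
  r1_true <- csa_r1(m, tau_true)
  delays <- seq(0.05, 5 / r1_true, length.out = 16)
  curve <- gen_relaxation_curve("inversion_recovery", rate = r1_true,
                                delays = delays, noise_sd = 0.01, seed = 303)
  fit <- fit_inversion_recovery(curve)
  tau_hat <- invert_r1_for_tau2(fit$rate, m)$tau2
  expect_equal(tau_hat, tau_true, tolerance = 0.03)
})
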