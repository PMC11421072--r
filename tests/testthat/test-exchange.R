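test_that("two-state populations follow the shift balance exactly", {
  ser <- titration_series(c(0, 0.5, 1), c(0, 0.445, 0.89), adp_conc = 10)
  sol <- two_state_populations(ser, "alpha", delta_f = 0, delta_b = 0.89)
  expect_equal(sol$p_b, c(0, 0.5, 1))
  expect_equal(sol$p_f + sol$p_b, rep(1, 3), tolerance = 1e-12)
  # free endpoint: observed shift at the free value gives p_f = 1
  expect_equal(sol$p_f[1], 1)
  # midpoint of the 0.89 ppm maximum shift change is half bound
  expect_equal(sol$p_b[sol$delta_obs == 0.445], 0.5)
})

test_that("two-state p_b is strictly increasing in the observed shift", {
  obs <- sort(runif(20, 0, 0.89))
  ser <- titration_series(seq_along(obs) / 10, obs, adp_conc = 10)
  sol <- two_state_populations(ser, "alpha", delta_f = 0, delta_b = 0.89)
  expect_true(all(diff(sol$p_b[order(sol$delta_obs)]) > 0))
})

test_that("two-state solver flags degenerate and out-of-model data", {
  ser <- titration_series(c(0, 1, 2, 3), c(0.1, 0.1, 0.1, 0.1), adp_conc = 10)
  expect_error(two_state_populations(ser, "alpha"), "degenerate")
  # small overshoot is clipped with a warning
  ser2 <- titration_series(c(0, 1, 2), c(0, 0.9, 0.89), adp_conc = 10)
  expect_warning(sol <- two_state_populations(ser2, "alpha",
                                              delta_f = 0, delta_b = 0.89),
                 "clipped")
  expect_true(all(sol$p_b >= 0 & sol$p_b <= 1))
  # gross violation is an error, not silently clipped
  ser3 <- titration_series(c(0, 1), c(0, 1.2), adp_conc = 10)
  expect_error(two_state_populations(ser3, "alpha",
                                     delta_f = 0, delta_b = 0.89),
               "outside")
})

test_that("exchange-rate bound has the right arithmetic and units", {
  expect_equal(kex_lower_bound(0, 100)$k_ex_min, 0)
  # 1 ppm at 100 MHz, factor 5: 5 * 2 pi * 100 Hz
  expect_equal(kex_lower_bound(1, 100, factor = 5)$k_ex_min, 3141.592653589793,
               tolerance = 1e-12)
  expect_error(kex_lower_bound(-1, 100), "non-negative")
  expect_error(kex_lower_bound(1, -100), "positive")
})

test_that("three-state solver honors the anchor and free endpoints", {
  ser <- gen_titration(
    adp_conc = 10,
    deltas = list(alpha = c(f = 0, b = 0.89),
                  beta = c(f = -5.60, b1 = -5.16, b2 = -5.30))
  )
  two <- two_state_populations(ser, "alpha")
  sol <- three_state_populations(ser, two$p_f)
  expect_equal(sol$p_b2[sol$mg_equiv == 0.5], 0)
  expect_equal(sol$p_f[sol$mg_equiv == 0], 1)
  expect_equal(sol$p_b1[sol$mg_equiv == 0], 0)
  expect_equal(sol$p_b2[sol$mg_equiv == 0], 0)
  expect_equal(sol$delta_obs_beta[sol$mg_equiv == 0],
               attr(sol, "delta_f_beta"))
  expect_error(three_state_populations(ser, two$p_f, anchor_eq = 0.7),
               "anchor")
})

test_that("noiseless generate-then-solve recovers all three-state constants", {
  set.seed(421)
  for (rep in 1:20) {
    truth <- random_three_state_truth()
    obs_beta <- three_state_forward(truth)
    ser <- titration_series(truth$eq, delta_alpha = truth$eq, # alpha unused
                            delta_beta = obs_beta, adp_conc = 10)
    sol <- three_state_populations(ser, truth$populations[, "p_f"])
    expect_equal(attr(sol, "delta_f_beta"), truth$delta_f, tolerance = 1e-9)
    expect_equal(attr(sol, "delta_b1_beta"), truth$delta_b1, tolerance = 1e-6)
    expect_equal(attr(sol, "delta_b2_beta"), truth$delta_b2, tolerance = 1e-6)
    expect_lt(max(abs(cbind(sol$p_f, sol$p_b1, sol$p_b2) -
                        truth$populations)), 1e-6)
  }
})

test_that("three-state invariants hold on seeded feasible ground truths", {
  set.seed(99)
  for (rep in 1:100) {
    truth <- random_three_state_truth()
    ser <- titration_series(truth$eq, delta_alpha = truth$eq,
                            delta_beta = three_state_forward(truth),
                            adp_conc = 10)
    sol <- three_state_populations(ser, truth$populations[, "p_f"])
    # normalization to 1e-12 at every point
    expect_lt(max(abs(sol$p_f + sol$p_b1 + sol$p_b2 - 1)), 1e-12)
    # stoichiometric cap with 1e-12 slack
    expect_true(all(sol$p_b1 + 2 * sol$p_b2 <= sol$mg_equiv + 1e-12))
    # transferred bound fractions are preserved: p_b1 + p_b2 = p_b
    expect_lt(max(abs(sol$p_b1 + sol$p_b2 -
                        (1 - truth$populations[, "p_f"]))), 1e-9)
    # end-member ordering
    expect_true(attr(sol, "delta_f_beta") < attr(sol, "delta_b2_beta"))
    expect_true(attr(sol, "delta_b2_beta") < attr(sol, "delta_b1_beta"))
  }
})

test_that("two-state data fed to the three-state solver yields p_b2 = 0", {
  ser <- gen_titration(
    adp_conc = 10,
    deltas = list(alpha = c(f = 0, b = 0.89),
                  beta = c(f = -5.60, b = -5.16))
  )
  two <- two_state_populations(ser, "alpha")
  sol <- three_state_populations(ser, two$p_f)
  expect_true(all(abs(sol$p_b2) <= 1e-8))
})

test_that("an infeasible constraint set is reported with the violating points", {
  # doubly-bound character demanded at 1 eq, where the cap leaves no room
  ser <- titration_series(c(0, 0.5, 1),
                          delta_alpha = c(0, 0.445, 0.89),
                          delta_beta = c(-5.60, -5.38, -5.40),
                          adp_conc = 10)
  two <- two_state_populations(ser, "alpha", delta_f = 0, delta_b = 0.89)
  expect_error(three_state_populations(ser, two$p_f), "infeasible.*1")
})
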