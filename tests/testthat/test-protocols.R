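test_that("drug-free availability tracks h_inf and anchors at 1", {
  av <- ss_availability(truth)
  expect_equal(av$y[1], 1)                 # most negative prepulse
  expect_equal(max(av$y), 1)               # normalization exact
  ss <- gate_steady(av$x, truth)
  expect_lt(max(abs(av$y - ss$h_inf / max(ss$h_inf))), 0.02)
  # the simulation engine (dense grid-max peak) agrees with the smooth
  # closed-form fitting fast path to within the sampling resolution
  expect_lt(max(abs(av$y - rdblock:::curve_availability(truth, av$x))), 1e-3)
})

test_that("availability with drug is scaled by the unbound equilibrium fraction", {
  av0 <- ss_availability(truth, drug_free, normalize = FALSE)
  avd <- ss_availability(truth, lido20, normalize = FALSE)
  scale <- 1 - b_inf(av0$x, truth, lido20)
  # binding during the 20 ms test pulse perturbs the ratio by < 1e-2
  expect_lt(max(abs(avd$y / av0$y - scale)), 1e-2)
})

test_that("activation curve saturates and anchors at the depolarized end", {
  ac <- ss_activation(truth)
  expect_equal(max(ac$y), 1)
  expect_equal(ac$y[length(ac$y)], 1, tolerance = 0.02)
  # saturated branch: m_inf^3 itself is flat between neighbouring
  # depolarized potentials; the observable keeps a small residual slope from
  # inactivation developing before the peak
  ssx <- gate_steady(c(15, 20), truth)
  expect_lt(abs(diff(ssx$m_inf^3)), 0.01)
  expect_lt(abs(ac$y[ac$x == 20] - ac$y[ac$x == 15]), 0.02)
  # peak conductance never exceeds the frozen-m bound g <= m_inf(V)^3 * h0
  ac_raw <- ss_activation(truth, normalize = FALSE)
  ss <- gate_steady(ac_raw$x, truth)
  h0 <- gate_steady(-120, truth)$h_inf
  expect_true(all(ac_raw$y <= ss$m_inf^3 * h0 + 1e-12))
})

test_that("time to half inactivation behaves on both branches", {
  # hyperpolarized branch: recovery from h ~ 0 crosses halfway at tau*log(2)
  V <- c(-120, -100, -90)
  th <- time_to_half_inactivation(truth, V)
  expect_equal(th, gate_steady(V, truth)$tau_h * log(2), tolerance = 0.02)
  # depolarized branch: decreasing with depolarization (tau_h shrinks)
  td <- time_to_half_inactivation(truth, c(-40, -20, 0, 20))
  expect_true(all(diff(td) < 0))
  # error when no crossing exists in span
  expect_error(time_to_half_inactivation(truth, -100, span_ms = 0.05),
               "half recovery")
})

test_that("activation_tau equals 1/(alpha_m + beta_m)", {
  V <- seq(-60, 30, by = 10)
  r <- gate_rates(V, truth)
  expect_equal(activation_tau(truth, V), 1 / (r$alpha_m + r$beta_m))
  expect_equal(activation_tau(truth, V), gate_steady(V, truth)$tau_m)
  # decreasing with depolarization on the alpha-dominated branch
  expect_true(all(diff(activation_tau(truth, seq(-20, 40, 10))) < 0))
})

test_that("tonic block matches the equilibrium bound fraction", {
  expect_equal(tonic_block(truth, drug_free), 0)
  tb <- tonic_block(truth, lido20, holding_V = -100)
  expect_equal(tb, b_inf(-100, truth, lido20), tolerance = 0.01)
  tb85 <- tonic_block(truth, lido20, holding_V = -85)
  expect_equal(tb85, b_inf(-85, truth, lido20), tolerance = 0.015)
  # more depolarized holding -> more inactivation -> more tonic block
  expect_gt(tb85, tb)
})

test_that("use-dependent block is null without drug and grows with dose and rate", {
  u0 <- use_dependent_block(truth, drug_free, n_pulses = 5)
  expect_equal(u0$peaks, rep(1, 5))
  expect_equal(u0$udb, 0)
  dose <- udb_dose_scan(truth, lido20, conc = uM(c(5, 20, 80)),
                        n_pulses = 25)
  expect_true(all(diff(dose$y) > 0))
  freqs <- udb_freq_scan(truth, lido20, freqs = c(1, 5, 10), n_pulses = 40)
  expect_true(all(diff(freqs$y) >= 0))
  expect_error(use_dependent_block(truth, lido20, freq = 50, pulse_ms = 25),
               "shorter than the pacing cycle")
})

test_that("recovery from use-dependent block relaxes toward 1 - tonic block", {
  intervals <- c(0, 50, 200, 500, 1000, 2000, 4000)
  rec <- recovery_from_udb(truth, lido20, intervals = intervals,
                           n_pulses = 15)
  expect_true(all(diff(rec$y) >= -1e-9))          # monotone nondecreasing
  lim <- 1 - tonic_block(truth, lido20, holding_V = -100)
  expect_equal(rec$y[length(intervals)], lim, tolerance = 0.02)
  # slow tail time constant ~ tau_b at the recovery potential: fit the tail
  tail_iv <- intervals[intervals >= 200]
  tail_y <- rec$y[intervals >= 200]
  fit <- stats::lm(log(lim - tail_y + 1e-12) ~ tail_iv)
  tau_est <- -1 / unname(stats::coef(fit)[2])
  expect_equal(tau_est, tau_b(-100, truth, lido20), tolerance = 0.1)
})

test_that("sse is the mean of squared differences", {
  expect_equal(sse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(sse(rep(0.6, 7), rep(0.5, 7)), 0.01)
  expect_equal(sse(c(1, 0), c(0, 1)), 1)
  expect_error(sse(1:3, 1:2), "length mismatch")
  expect_equal(sse(c(0, 1), c(1, 1), weight = c(1, 3)), 0.25)
})
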