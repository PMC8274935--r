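test_that("rates evaluate c1 * exp(V/c2) with the documented anchors", {
  r0 <- gate_rates(0, truth)
  expect_equal(r0$alpha_m, truth[["c1_alpha_m"]])
  expect_equal(r0$beta_h, truth[["c1_beta_h"]])
  # one e-fold at V = c2
  re <- gate_rates(truth[["c2_alpha_m"]], truth)
  expect_equal(re$alpha_m, truth[["c1_alpha_m"]] * exp(1))
  # overflow guard engages with a warning and keeps rates finite
  steep <- gating_params(40, 3, 0.13, -3, 2.6e-5, -3, 1.39, 3)
  w <- capture_warnings(r <- gate_rates(200, steep))
  expect_true(any(grepl("capped", w)))
  expect_true(all(is.finite(unlist(r))))
})

test_that("steady states are monotone and anchored on the truth preset", {
  ss <- gate_steady(v_grid, truth)
  expect_true(all(diff(ss$m_inf) > 0))
  expect_true(all(diff(ss$h_inf) < 0))
  expect_true(all(ss$tau_m > 0 & ss$tau_h > 0))
  expect_true(all(ss$m_inf > 0 & ss$m_inf < 1))
  # alpha_h = beta_h at the half-point => h_inf = 0.5 there
  vhalf <- stats::uniroot(function(v) {
    r <- gate_rates(v, truth)
    r$alpha_h - r$beta_h
  }, c(-90, -50), tol = 1e-12)$root
  expect_equal(gate_steady(vhalf, truth)$h_inf, 0.5, tolerance = 1e-9)
  # the anchors that the square-wave theory relies on
  expect_equal(round(gate_steady(-85, truth)$h_inf, 1), 0.9)
  expect_equal(round(gate_steady(20, truth)$h_inf, 1), 0)
})

test_that("current vanishes at the reversal potential and scales linearly", {
  cp <- channel_params(g_max = 1, E_Na = 70)
  s <- channel_state(1, 1, 0)
  expect_equal(na_current(70, s, cp), 0)
  expect_equal(na_current(-20, 0.1, cp), -9)   # f_open given directly
  expect_equal(na_current(-20, channel_state(0, 1, 0), cp), 0)
})

test_that("derivatives vanish at equilibrium and match hand arithmetic", {
  for (V in c(-100, -85, -60, -20, 20)) {
    eq <- equilibrium_state(V, truth, lido20)
    expect_lt(max(abs(state_derivs(V, eq, truth, lido20))), 1e-10)
  }
  # no inactivated channels available: db/dt = 0
  d <- state_derivs(-20, channel_state(0.2, 1, 0), truth, lido20)
  expect_equal(unname(d["db"]), 0)
  # all channels inactivated, none bound: db/dt = k_on [D]
  d2 <- state_derivs(-20, channel_state(0.2, 0, 0), truth, lido20)
  expect_equal(unname(d2["db"]), 250 * 2e-5)   # 5e-3 per ms
  # drug-free: db/dt = -k_off * b <= 0
  d3 <- state_derivs(-20, channel_state(0.2, 0.4, 0.5), truth, drug_free)
  expect_equal(unname(d3["db"]), -drug_free$k_off * 0.5)
})

test_that("tau_b and b_inf evaluate the fixed-voltage binding formulas", {
  # [D] = 0: tau_b = 1/k_off, b_inf = 0
  expect_equal(tau_b(-85, truth, drug_free), 1 / 1.7e-3, tolerance = 1e-12)
  expect_equal(b_inf(-85, truth, drug_free), 0)
  # saturated inactivation (1 - h_inf = 1 to ~1e-6): 20 uM
  expect_equal(tau_b(20, truth, lido20), 1 / 6.7e-3, tolerance = 1e-4)
  expect_equal(b_inf(20, truth, lido20), 5 / 6.7, tolerance = 1e-4)
  # 5 uM
  expect_equal(tau_b(20, truth, lido5), 1 / 2.95e-3, tolerance = 1e-4)
  expect_equal(b_inf(20, truth, lido5), 1.25 / 2.95, tolerance = 1e-4)
  # bound: tau_b <= 1/k_off always
  expect_true(all(tau_b(v_grid, truth, lido20) <= 1 / 1.7e-3 + 1e-12))
  # h_inf = 1 exactly would give equality; drug-free does
  expect_equal(max(tau_b(v_grid, truth, drug_free)), 1 / 1.7e-3)
})

test_that("equilibrium_state composes the three steady states", {
  eq <- equilibrium_state(-70, truth, lido20)
  ss <- gate_steady(-70, truth)
  expect_equal(eq$m, ss$m_inf)
  expect_equal(eq$h, ss$h_inf)
  expect_equal(eq$b, b_inf(-70, truth, lido20))
  expect_equal(equilibrium_state(-70, truth, drug_free)$b, 0)
})
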