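test_that("equilibrium initial state stays constant under constant V", {
  for (V in c(-100, -70)) {
    w <- constant_hold(V, 500, sample_dt = 10)
    tr <- simulate_gating(w, truth, lido20)
    eq <- equilibrium_state(V, truth, lido20)
    expect_lt(max(abs(tr$m - eq$m)), 1e-8)
    expect_lt(max(abs(tr$h - eq$h)), 1e-8)
    expect_lt(max(abs(tr$b - eq$b)), 1e-8)
  }
})

test_that("gates relax with the closed-form exponential under constant V", {
  V <- -60
  s0 <- channel_state(0.9, 0.1, 0)
  tr <- simulate_gating(constant_hold(V, 100, sample_dt = 1), truth,
                        drug_free, state0 = s0)
  ss <- gate_steady(V, truth)
  m_ref <- ss$m_inf + (0.9 - ss$m_inf) * exp(-tr$t_ms / ss$tau_m)
  h_ref <- ss$h_inf + (0.1 - ss$h_inf) * exp(-tr$t_ms / ss$tau_h)
  expect_lt(max(abs(tr$m - m_ref)), 1e-8)
  expect_lt(max(abs(tr$h - h_ref)), 1e-8)
})

test_that("b matches the scalar linear-ODE closed form when h is frozen", {
  V <- -70
  eq <- equilibrium_state(V, truth, lido20)
  s0 <- channel_state(eq$m, eq$h, 0.2)    # h starts at h_inf => frozen
  tr <- simulate_gating(constant_hold(V, 2000, sample_dt = 20), truth, lido20,
                        state0 = s0)
  tb <- tau_b(V, truth, lido20); bi <- b_inf(V, truth, lido20)
  b_ref <- bi + (0.2 - bi) * exp(-tr$t_ms / tb)
  expect_lt(max(abs(tr$b - b_ref)), 1e-8)
  # the same via the forced-RK4 route (genuinely numerical)
  tr2 <- simulate_gating(constant_hold(V, 2000, sample_dt = 20), truth,
                         lido20, state0 = s0, method = "rk4")
  expect_lt(max(abs(tr2$b - b_ref)), 1e-8)
})

test_that("square-wave drive with pinned h matches the piecewise closed form", {
  sq <- square_wave_ap(300, 450)
  env <- binding_env(sq, truth, lido20)
  w <- square_wave_clamp(APD = 300, DI = 450, n_cycles = 3, sample_dt = 5)
  tr <- simulate_gating(w, truth, lido20,
                        state0 = channel_state(0, gate_steady(-85, truth)$h_inf, 0),
                        pin_h = TRUE, method = "rk4")
  # compose the analytic solution segment by segment over the same grid
  segs <- unique(tr$segment)
  seg_label <- tapply(tr$label, tr$segment, `[`, 1)[as.character(segs)]
  seg_t0 <- tapply(tr$t_ms, tr$segment, min)[as.character(segs)]
  b_start <- numeric(length(segs))
  for (k in seq_along(segs)) {
    b_start[k] <- if (k == 1) 0
      else b_transient(if (seg_label[k - 1] == "ap") 300 else 450,
                       seg_label[k - 1], b_start[k - 1], env)
  }
  b_ref <- vapply(seq_len(nrow(tr)), function(i) {
    k <- match(tr$segment[i], segs)
    b_transient(tr$t_ms[i] - seg_t0[k], tr$label[i], b_start[k], env)
  }, numeric(1))
  expect_lt(max(abs(tr$b - b_ref)), 1e-6)
})

test_that("drug-free three-variable run reduces to the two-variable model", {
  w <- step_waveform(c(-100, -20, -100, 0), c(50, 25, 100, 10),
                     sample_dt = 0.5)
  s0 <- channel_state(0.1, 0.9, 0)
  tr <- simulate_gating(w, truth, drug_free, state0 = s0)
  expect_true(all(tr$b == 0))
  # m and h must equal a run that never sees the drug machinery
  tr2 <- simulate_gating(w, truth, drug_params(conc = 0), state0 = s0)
  expect_identical(tr$m, tr2$m)
  expect_identical(tr$h, tr2$h)
})

test_that("box invariance holds across random step waveforms", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    w <- step_waveform(runif(n, -120, 40), runif(n, 1, 300), sample_dt = 2)
    s0 <- channel_state(runif(1), runif(1), runif(1))
    tr <- simulate_gating(w, truth, lido20, state0 = s0)
    expect_true(all(tr$m >= -1e-9 & tr$m <= 1 + 1e-9))
    expect_true(all(tr$h >= -1e-9 & tr$h <= 1 + 1e-9))
    expect_true(all(tr$b >= -1e-9 & tr$b <= 1 + 1e-9))
    expect_true(all(tr$f_open >= -1e-9 & tr$f_open <= 1 + 1e-9))
  }
})

test_that("refining the sampling grid changes the trajectory negligibly", {
  w1 <- step_waveform(c(-100, 20, -85), c(100, 50, 400), sample_dt = 1)
  w2 <- step_waveform(c(-100, 20, -85), c(100, 50, 400), sample_dt = 0.5)
  s0 <- channel_state(0.2, 0.7, 0.1)
  tr1 <- simulate_gating(w1, truth, lido20, state0 = s0)
  tr2 <- simulate_gating(w2, truth, lido20, state0 = s0)
  common <- intersect(tr1$t_ms, tr2$t_ms)
  i1 <- match(common, tr1$t_ms); i2 <- match(common, tr2$t_ms)
  expect_lt(max(abs(tr1$b[i1] - tr2$b[i2])), 1e-3)
  f1 <- attr(tr1, "final_state"); f2 <- attr(tr2, "final_state")
  expect_lt(abs(f1$b - f2$b), 1e-6)
})

test_that("trajectory carries the documented columns and final state", {
  w <- step_waveform(c(-80, 0), c(10, 5), sample_dt = 1)
  tr <- simulate_gating(w, truth, lido20, c = channel_params(2, 65))
  expect_true(all(c("t_ms", "V_mV", "m", "h", "b", "f_open", "I_Na")
                  %in% names(tr)))
  expect_equal(tr$I_Na, 2 * tr$f_open * (tr$V_mV - 65))
  fs <- attr(tr, "final_state")
  expect_s3_class(fs, "channel_state")
  expect_equal(fs$t, 15)
  expect_equal(fs$b, tr$b[nrow(tr)])
})
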