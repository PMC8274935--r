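test_that("b_transient is continuous, bounded, and hits its limits", {
  sq <- square_wave_ap(300, 450)
  env <- binding_env(sq, truth, lido20)
  expect_equal(b_transient(0, "ap", 0.3, env), 0.3)
  expect_equal(b_transient(0, "di", 0.3, env), 0.3)
  expect_equal(b_transient(1e7, "ap", 0.3, env), env$binf_AP)
  expect_equal(b_transient(1e7, "di", 0.3, env), env$binf_DI)
  expect_true(env$A > 0 && env$A < 1 && env$D > 0 && env$D < 1)
})

test_that("full-cycle composition matches the numerically integrated binding ODE", {
  # h pinned per phase (the square-wave approximation the solution assumes)
  grid <- expand.grid(APD = c(150, 300), DI = c(100, 450),
                      conc = c(5e-6, 2e-5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    d <- drug_params(conc = g$conc)
    sq <- square_wave_ap(g$APD, g$DI)
    env <- binding_env(sq, truth, d)
    w <- square_wave_clamp(APD = g$APD, DI = g$DI, n_cycles = 1,
                           sample_dt = g$APD + g$DI)
    b0 <- 0.1
    tr <- simulate_gating(w, truth, d,
                          state0 = channel_state(0, 1, b0),
                          pin_h = TRUE, method = "rk4")
    b_ode <- attr(tr, "final_state")$b
    b_closed <- b_transient(g$DI, "di",
                            b_transient(g$APD, "ap", b0, env), env)
    expect_lt(abs(b_ode - b_closed), 1e-6)
  }
})

test_that("b_star limits, the worked fixed-point value, and convexity hold", {
  # degenerate-phase limits via tiny durations
  sq_ap <- square_wave_ap(1e-9, 450)
  expect_equal(b_star(sq_ap, truth, lido20),
               b_inf(-85, truth, lido20), tolerance = 1e-6)
  sq_di <- square_wave_ap(300, 1e-9)
  expect_equal(b_star(sq_di, truth, lido20),
               b_inf(20, truth, lido20), tolerance = 1e-6)
  expect_equal(b_star(square_wave_ap(300, 450), truth, drug_free), 0)
  # idealized case 1 - h_inf(V_AP) = 1, 1 - h_inf(V_DI) = 0:
  # V_DI = -150 makes the diastolic binding substrate vanish (< 1e-5)
  sq <- square_wave_ap(300, 450, V_AP = 20, V_DI = -150)
  expect_equal(b_star(sq, truth, lido20), 0.3208, tolerance = 1e-3)
  # convex combination of the two phase asymptotes, monotone in [D]
  for (conc in c(1e-6, 5e-6, 2e-5)) {
    d <- drug_params(conc = conc)
    sqc <- square_wave_ap(250, 350)
    bs <- b_star(sqc, truth, d)
    lohi <- range(b_inf(c(20, -85), truth, d))
    expect_within(bs, lohi[1], lohi[2])
  }
  concs <- c(1e-6, 5e-6, 1e-5, 2e-5, 4e-5)
  bvals <- vapply(concs, function(cc)
    b_star(square_wave_ap(250, 350), truth, drug_params(conc = cc)),
    numeric(1))
  expect_true(all(diff(bvals) > 0))
})

test_that("the pacing map contracts geometrically to b_star", {
  sq <- square_wave_ap(300, 450)
  env <- binding_env(sq, truth, lido20)
  bs <- b_star(sq, truth, lido20)
  # fixed point is invariant
  expect_equal(iterate_pacing_map(sq, truth, lido20, b0 = bs, n_cycles = 5),
               rep(bs, 6), tolerance = 1e-12)
  # contraction bound |b_n - b*| <= |b0 - b*| (AD)^n
  seqb <- iterate_pacing_map(sq, truth, lido20, b0 = 0, n_cycles = 30)
  gap <- abs(seqb - bs)
  bound <- gap[1] * (env$A * env$D)^(0:30)
  expect_true(all(gap <= bound + 1e-12))
  # monotone approach after the first cycle
  expect_true(all(diff(seqb[-1]) >= -1e-12) || all(diff(seqb[-1]) <= 1e-12))
})

test_that("closed-form b_star equals the map fixed point on a factorial grid", {
  grid <- expand.grid(APD = c(80, 200, 400), DI = c(60, 300, 700),
                      conc = c(2e-6, 2e-5), k_off = c(1.7e-3, 8e-3))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    d <- drug_params(k_off = g$k_off, conc = g$conc)
    sq <- square_wave_ap(g$APD, g$DI)
    bs <- b_star(sq, truth, d)
    b_end <- tail(iterate_pacing_map(sq, truth, d, b0 = 0.5,
                                     n_cycles = 400), 1)
    expect_lt(abs(bs - b_end), 1e-10)
  }
})

test_that("db_star_dBCL matches central finite differences of b_star", {
  for (preset in c("default", "steep", "flat")) {
    rc <- gen_restitution(preset)
    bcl <- seq(320, 980, by = 60)
    an <- db_star_dBCL(bcl, rc, truth, lido20)
    h <- 1
    num <- (b_star(p = truth, d = lido20, restitution = rc, BCL = bcl + h) -
            b_star(p = truth, d = lido20, restitution = rc, BCL = bcl - h)) /
           (2 * h)
    # central differences carry O(h^2) truncation; compare against a
    # Richardson-extrapolated difference for the 1e-6 relative bound
    num2 <- (b_star(p = truth, d = lido20, restitution = rc,
                    BCL = bcl + h / 2) -
             b_star(p = truth, d = lido20, restitution = rc,
                    BCL = bcl - h / 2)) / h
    rich <- (4 * num2 - num) / 3
    sel <- abs(an) > 1e-9
    expect_lt(max(abs((an[sel] - rich[sel]) / an[sel])), 1e-6)
  }
  # flat restitution: strictly negative since b_inf(V_AP) > b_inf(V_DI)
  rc_flat <- gen_restitution("flat")
  expect_true(all(db_star_dBCL(seq(300, 1000, 50), rc_flat, truth,
                               lido20) < 0))
})

test_that("critical slope is the root of the sensitivity bracket", {
  set.seed(7)
  for (i in 1:1000) {
    A <- runif(1, 0.01, 0.99); D <- runif(1, 0.01, 0.99)
    tAP <- runif(1, 20, 800); tDI <- runif(1, 20, 800)
    s <- rdblock:::critical_slope_from_env(A, D, tAP, tDI)
    expect_within(s, 0, 1)
    bracket <- (1 - D) * A * D / tAP * s - (1 - A) * D / tDI * (1 - s)
    expect_lt(abs(bracket), 1e-10)
  }
  # A -> 0 (long APD): slope -> 1
  expect_equal(rdblock:::critical_slope_from_env(1e-12, 0.5, 300, 300), 1,
               tolerance = 1e-9)
  # D -> 1 (short DI): bracket root approaches 1/(1 + 0) = 1
  expect_equal(rdblock:::critical_slope_from_env(0.5, 1 - 1e-12, 300, 300),
               1, tolerance = 1e-9)
  # substituting the critical slope as f' into the full derivative gives 0
  rc <- gen_restitution("default")
  bcl <- 500
  sc <- critical_slope(bcl, rc, truth, lido20)
  APD <- apd_at(rc, bcl); DI <- bcl - APD
  tAP <- tau_b(20, truth, lido20); tDI <- tau_b(-85, truth, lido20)
  A <- exp(-APD / tAP); D <- exp(-DI / tDI)
  bAP <- b_inf(20, truth, lido20); bDI <- b_inf(-85, truth, lido20)
  deriv_at_sc <- (bAP - bDI) / (1 - A * D)^2 *
    ((1 - D) * A * D / tAP * sc - (1 - A) * D / tDI * (1 - sc))
  expect_lt(abs(deriv_at_sc), 1e-10)
})

test_that("sigma-scaling of binding rates equals time rescaling exactly", {
  sq <- square_wave_ap(300, 450)
  for (sigma in c(0.5, 0.75, 1, 2)) {
    eq <- rate_scaling_check(sigma, sq, truth, lido20)
    expect_lt(abs(eq$b_scaled_rates - eq$b_scaled_time), 1e-12)
  }
})

test_that("scan_b_star reproduces the directional claims", {
  rc <- gen_restitution("default")
  bcl <- seq(320, 1000, by = 40)
  base <- scan_b_star(bcl, rc, truth, lido20)
  expect_true(all(is.finite(base$b_star)))
  # plateau-potential insensitivity: V_AP 20 -> -20 changes b* by < 0.01
  shift <- scan_b_star(bcl, rc, truth, lido20, V_AP = -20)
  expect_lt(max(abs(base$b_star - shift$b_star)), 0.01)
  # raising V_DI by 10 mV increases b* everywhere
  up <- scan_b_star(bcl, rc, truth, lido20, V_DI = -75)
  expect_true(all(up$b_star > base$b_star))
  # steeper restitution yields lower b* at short BCL
  steep <- scan_b_star(bcl, gen_restitution("steep"), truth, lido20)
  short <- bcl <= 500
  expect_true(all(steep$b_star[short] < base$b_star[short]))
  # flat restitution: b* increases as BCL decreases
  flat <- scan_b_star(bcl, gen_restitution("flat"), truth, lido20)
  expect_true(all(diff(flat$b_star) < 0))
  # out-of-domain points are collected, not fatal
  wide <- scan_b_star(c(100, 500), rc, truth, lido20)
  expect_true(is.na(wide$b_star[1]) && is.finite(wide$b_star[2]))
  expect_length(attr(wide, "errors"), 1)
})

test_that("finite-difference voltage sensitivities have the documented signs", {
  rc <- gen_restitution("default")
  # b* insensitive to V_AP (saturated inactivation), sensitive to V_DI rise
  dap <- db_star_dV(750, rc, truth, lido20, which = "V_AP")
  ddi <- db_star_dV(750, rc, truth, lido20, which = "V_DI")
  expect_lt(abs(dap), 1e-4)
  expect_gt(ddi, 1e-3)
})
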