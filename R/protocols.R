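# Voltage-clamp protocol engine.
#
# Every protocol composes piecewise-constant waveforms, runs the model with
# simulate_gating(), and summarizes each sweep by its peak conductance
# g_max * m^3 h (1 - b) during the test pulse (peak |I_Na| is available via
# `measure = "current"`; within a sweep the driving force is constant so the
# two are proportional).  Peaks are located on a dense sampling grid
# (default 0.01 ms) with no interpolation.
#
# By default sweeps start from the analytic drug-and-gating equilibrium at
# the conditioning potential ("analytic equilibration"), which is exact for
# constant holds and avoids simulating the slow (hundreds of ms) approach of
# b to steady state.  Set analytic_init = FALSE to simulate the holds.

sweep_peak <- function(w, p, d, state0, measure = "conductance",
                       cp = channel_params()) {
  traj <- simulate_gating(w, p, d, c = cp, state0 = state0)
  sel <- traj$label == "test"
  pk <- if (measure == "current") max(abs(traj$I_Na[sel]))
        else cp$g_max * max(traj$f_open[sel])
  list(peak = pk, t_peak = traj$t_ms[sel][which.max(
         if (measure == "current") abs(traj$I_Na[sel]) else traj$f_open[sel])],
       final = attr(traj, "final_state"))
}

check_equilibration <- function(prepulse_ms, p, d, V_range, analytic_init) {
  if (analytic_init) return(invisible(TRUE))
  tau_h_max <- max(gate_steady(V_range, p)$tau_h)
  if (prepulse_ms < 5 * tau_h_max)
    warning(sprintf(
      "prepulse %g ms < 5 * max tau_h (%.3g ms): gating may not equilibrate",
      prepulse_ms, tau_h_max), call. = FALSE)
  if (d$conc > 0) {
    tau_b_max <- max(tau_b(V_range, p, d))
    if (prepulse_ms < 5 * tau_b_max)
      warning(sprintf(
        "prepulse %g ms < 5 * tau_b (%.3g ms): drug binding may not equilibrate; consider analytic_init = TRUE",
        prepulse_ms, tau_b_max), call. = FALSE)
  }
  invisible(TRUE)
}

#' Steady-state availability protocol
#'
#' From each conditioning prepulse potential, a test pulse elicits a peak
#' conductance; peaks are normalized to the maximum over sweeps.  Drug-free,
#' with full equilibration, the curve tracks `h_inf` at the prepulse
#' potentials; with drug it is additionally scaled by the equilibrium
#' unbound fraction `1 - b_inf(V_pre)`.
#'
#' @param p a [gating_params()] object.
#' @param d a [drug_params()] object (default drug-free).
#' @param prepulse_V conditioning potentials (mV).
#' @param prepulse_ms conditioning duration (ms); only simulated when
#'   `analytic_init = FALSE`.
#' @param test_V,test_ms test-pulse potential (mV) and duration (ms).
#' @param holding_V holding potential before the prepulse (mV).
#' @param analytic_init start each sweep at the exact equilibrium of the
#'   prepulse potential instead of simulating the hold.
#' @param normalize divide peaks by the maximum over sweeps.
#' @param measure `"conductance"` (default) or `"current"`.
#' @param test_dt dense sampling interval during the test pulse (ms).
#' @return a [clamp_dataset()] (protocol `"availability"`); sweeps with no
#'   detectable peak are flagged in `attr(, "flagged")`.
#' @export
ss_availability <- function(p, d = drug_params(),
                            prepulse_V = seq(-120, -40, by = 5),
                            prepulse_ms = 1000, test_V = -20, test_ms = 20,
                            holding_V = -120, analytic_init = TRUE,
                            normalize = TRUE, measure = "conductance",
                            test_dt = 0.01) {
  check_equilibration(prepulse_ms, p, d, prepulse_V, analytic_init)
  peaks <- vapply(prepulse_V, function(vp) {
    if (analytic_init) {
      w <- step_waveform(test_V, test_ms, sample_dt = test_dt, label = "test")
      s0 <- equilibrium_state(vp, p, d)
    } else {
      w <- step_waveform(c(vp, test_V), c(prepulse_ms, test_ms),
                         sample_dt = c(1, test_dt),
                         label = c("prepulse", "test"))
      s0 <- equilibrium_state(holding_V, p, d)
    }
    sweep_peak(w, p, d, s0, measure)$peak
  }, numeric(1))
  flagged <- peaks < 1e-12 * max(peaks, 1e-300)
  y <- if (normalize) peaks / max(peaks) else peaks
  out <- clamp_dataset(prepulse_V, y, protocol = "availability",
                       x_units = "mV",
                       y_units = if (normalize) "normalized peak" else "peak g",
                       provenance = sprintf("simulated; [D] = %g uM",
                                            d$conc * 1e6))
  attr(out, "flagged") <- flagged
  out
}

#' Steady-state activation protocol
#'
#' Peak conductance at each test potential from a hyperpolarized holding
#' potential, normalized to the overall maximum.  Drug-free, the curve
#' tracks the shape of `m_inf(V)^3`, distorted by the inactivation that
#' develops before the peak is reached.
#'
#' @inheritParams ss_availability
#' @param test_V test potentials swept (mV).
#' @return a [clamp_dataset()] (protocol `"activation"`).
#' @export
ss_activation <- function(p, d = drug_params(),
                          test_V = seq(-60, 20, by = 5), holding_V = -120,
                          test_ms = 20, analytic_init = TRUE,
                          normalize = TRUE, measure = "conductance",
                          test_dt = 0.01) {
  s0 <- equilibrium_state(holding_V, p, d)
  peaks <- vapply(test_V, function(vt) {
    w <- step_waveform(vt, test_ms, sample_dt = test_dt, label = "test")
    sweep_peak(w, p, d, s0, measure)$peak
  }, numeric(1))
  flagged <- peaks < 1e-12 * max(peaks, 1e-300)
  y <- if (normalize) peaks / max(peaks) else peaks
  out <- clamp_dataset(test_V, y, protocol = "activation", x_units = "mV",
                       y_units = if (normalize) "normalized peak" else "peak g",
                       provenance = sprintf("simulated; [D] = %g uM",
                                            d$conc * 1e6))
  attr(out, "flagged") <- flagged
  out
}

#' Time to half inactivation
#'
#' Two-branch observable.  At depolarized potentials
#' (`V > depol_threshold`): the time for the conductance to decay to 50% of
#' its peak during an activation pulse.  At hyperpolarized potentials: the
#' time to reach halfway from the post-conditioning `h` toward the recovered
#' steady state in a recovery time course (conditioning pulse drives `h`
#' toward 0, then the membrane is stepped to `V`).
#'
#' @inheritParams ss_availability
#' @param V potentials at which to evaluate (mV); vectorized.
#' @param depol_threshold branch classifier (mV); default -60.
#' @param cond_V,cond_ms conditioning pulse for the recovery branch.
#' @param span_ms maximum simulated span per branch (ms).
#' @return time(s) in ms.
#' @export
time_to_half_inactivation <- function(p, V, depol_threshold = -60,
                                      holding_V = -120, cond_V = 20,
                                      cond_ms = 50, span_ms = 200,
                                      test_dt = 0.005) {
  vapply(V, function(v) {
    if (v > depol_threshold) {
      w <- step_waveform(v, min(span_ms, 50), sample_dt = test_dt,
                         label = "test")
      traj <- simulate_gating(w, p, state0 = equilibrium_state(holding_V, p))
      g <- traj$f_open
      ip <- which.max(g)
      half <- g[ip] / 2
      below <- which(g[ip:length(g)] <= half)
      if (!length(below))
        stop(sprintf("no 50%% decay within %g ms at V = %g mV",
                     min(span_ms, 50), v))
      j <- ip + below[1] - 1L
      tj <- traj$t_ms
      t_cross <- tj[j - 1L] + (tj[j] - tj[j - 1L]) *
        (g[j - 1L] - half) / (g[j - 1L] - g[j])
      t_cross - tj[ip]
    } else {
      w <- step_waveform(c(cond_V, v), c(cond_ms, span_ms),
                         sample_dt = c(1, test_dt),
                         label = c("cond", "recovery"))
      traj <- simulate_gating(w, p, state0 = equilibrium_state(holding_V, p))
      rec <- traj[traj$label == "recovery", ]
      h0 <- rec$h[1]
      h_target <- (h0 + gate_steady(v, p)$h_inf) / 2
      above <- which(rec$h >= h_target)
      if (!length(above))
        stop(sprintf("no half recovery within %g ms at V = %g mV",
                     span_ms, v))
      j <- above[1]
      if (j == 1L) return(0)
      rec$t_ms[j - 1L] + (rec$t_ms[j] - rec$t_ms[j - 1L]) *
        (h_target - rec$h[j - 1L]) / (rec$h[j] - rec$h[j - 1L]) -
        rec$t_ms[1]
    }
  }, numeric(1))
}

#' Activation time constant
#'
#' `tau_m(V) = 1 / (alpha_m(V) + beta_m(V))` -- identical to the `tau_m`
#' column of [gate_steady()].
#'
#' @param p a [gating_params()] object.
#' @param V potentials (mV); vectorized.
#' @return time constants (ms).
#' @export
activation_tau <- function(p, V) curve_tau_m(p, V)

#' Tonic block
#'
#' Steady-state fraction of channels blocked at rest: one minus the ratio of
#' the peak test-pulse conductance with drug to the drug-free peak under the
#' identical protocol.  With analytic equilibration the result equals
#' `b_inf(holding_V)` up to the small amount of binding that occurs during
#' the test pulse itself.
#'
#' @inheritParams ss_availability
#' @param equilibration_ms hold duration when `analytic_init = FALSE`.
#' @return fraction blocked in \[0, 1\].
#' @export
tonic_block <- function(p, d, holding_V = -100, equilibration_ms = 5000,
                        test_V = -20, test_ms = 20, analytic_init = TRUE,
                        measure = "conductance", test_dt = 0.01) {
  if (!analytic_init && equilibration_ms < 5 * tau_b(holding_V, p, d))
    warning("equilibration shorter than 5 * tau_b at the holding potential",
            call. = FALSE)
  run <- function(dd) {
    if (analytic_init) {
      w <- step_waveform(test_V, test_ms, sample_dt = test_dt, label = "test")
      s0 <- equilibrium_state(holding_V, p, dd)
    } else {
      w <- step_waveform(c(holding_V, test_V), c(equilibration_ms, test_ms),
                         sample_dt = c(5, test_dt),
                         label = c("hold", "test"))
      s0 <- equilibrium_state(holding_V, p, drug_params(dd$k_on, dd$k_off, 0))
    }
    sweep_peak(w, p, dd, s0, measure)$peak
  }
  pk_free <- run(drug_params(d$k_on, d$k_off, 0))
  pk_drug <- run(d)
  1 - pk_drug / pk_free
}

#' Use-dependent block under a pulse train
#'
#' Applies `n_pulses` depolarizing pulses at `freq` Hz from a hyperpolarized
#' holding potential and measures the peak conductance of each pulse.  Peaks
#' are normalized to the first pulse; the use-dependent block level is
#' `UDB = 1 - (steady-state peak) / (first peak)`.
#'
#' @inheritParams ss_availability
#' @param freq pulse frequency (Hz); the cycle `1000/freq` ms must exceed
#'   `pulse_ms`.
#' @param pulse_V,pulse_ms pulse potential (mV) and duration (ms).
#' @param n_pulses train length; a warning is issued if the last two peaks
#'   still differ by more than `1e-4` (relative).
#' @return list with `peaks` (normalized, length `n_pulses`), `udb`, and
#'   `converged`.
#' @export
use_dependent_block <- function(p, d, freq = 5, pulse_V = -20, pulse_ms = 25,
                                holding_V = -100, n_pulses = 25,
                                measure = "conductance", test_dt = 0.01) {
  cycle_ms <- 1000 / freq
  if (cycle_ms <= pulse_ms)
    stop("pulse duration must be shorter than the pacing cycle 1000/freq")
  gap_ms <- cycle_ms - pulse_ms
  s <- equilibrium_state(holding_V, p, d)
  peaks <- numeric(n_pulses)
  for (k in seq_len(n_pulses)) {
    w <- step_waveform(c(pulse_V, holding_V), c(pulse_ms, gap_ms),
                       sample_dt = c(test_dt, min(1, gap_ms / 4)),
                       label = c("test", "gap"))
    sw <- sweep_peak(w, p, d, s, measure)
    peaks[k] <- sw$peak
    s <- sw$final
  }
  converged <- n_pulses < 2 ||
    abs(peaks[n_pulses] - peaks[n_pulses - 1]) <= 1e-4 * peaks[1]
  if (!converged)
    warning("pulse train not converged: last two peaks differ by > 1e-4",
            call. = FALSE)
  norm <- peaks / peaks[1]
  list(peaks = norm, udb = 1 - norm[n_pulses], converged = converged)
}

#' Dose and frequency scans of use-dependent block
#'
#' Wrappers running [use_dependent_block()] over a concentration list at
#' fixed frequency (`udb_dose_scan`) or over a frequency list at fixed
#' concentration (`udb_freq_scan`).
#'
#' @inheritParams use_dependent_block
#' @param conc concentrations (M) for the dose scan.
#' @param freqs frequencies (Hz) for the frequency scan.
#' @param ... passed on to [use_dependent_block()].
#' @return a [clamp_dataset()] of UDB levels.
#' @export
udb_dose_scan <- function(p, d, conc, freq = 5, ...) {
  y <- vapply(conc, function(cc)
    use_dependent_block(p, drug_params(d$k_on, d$k_off, cc),
                        freq = freq, ...)$udb, numeric(1))
  clamp_dataset(conc, y, protocol = "udb_dose", x_units = "M",
                y_units = "UDB fraction",
                provenance = sprintf("simulated; %g Hz", freq))
}

#' @rdname udb_dose_scan
#' @export
udb_freq_scan <- function(p, d, freqs, ...) {
  y <- vapply(freqs, function(ff)
    use_dependent_block(p, d, freq = ff, ...)$udb, numeric(1))
  clamp_dataset(freqs, y, protocol = "udb_freq", x_units = "Hz",
                y_units = "UDB fraction",
                provenance = sprintf("simulated; [D] = %g uM", d$conc * 1e6))
}

#' Recovery from use-dependent block
#'
#' A conditioning train drives block to steady state; after each recovery
#' interval at `recovery_V` a test pulse measures the recovered peak,
#' normalized to the unconditioned drug-free peak.  The slow tail of the
#' recovery time course relaxes with approximately `tau_b(recovery_V)`.
#'
#' @inheritParams use_dependent_block
#' @param recovery_V recovery potential (mV); default -100.
#' @param intervals recovery intervals (ms).
#' @param test_V,test_ms test pulse.
#' @return a [clamp_dataset()] (protocol `"recovery"`), x = interval.
#' @export
recovery_from_udb <- function(p, d, recovery_V = -100,
                              intervals = c(0, 2^(0:11)),
                              freq = 5, pulse_V = -20, pulse_ms = 25,
                              n_pulses = 25, test_V = -20, test_ms = 20,
                              measure = "conductance", test_dt = 0.01) {
  cycle_ms <- 1000 / freq
  gap_ms <- cycle_ms - pulse_ms
  # conditioning train (state carried, no dense sampling needed)
  s <- equilibrium_state(recovery_V, p, d)
  w_cycle <- step_waveform(c(pulse_V, recovery_V), c(pulse_ms, gap_ms),
                           sample_dt = c(0.5, min(1, gap_ms / 4)))
  for (k in seq_len(n_pulses)) s <- final_state(w_cycle, p, d, state0 = s)
  # unconditioned drug-free reference peak
  d0 <- drug_params(d$k_on, d$k_off, 0)
  w_test <- step_waveform(test_V, test_ms, sample_dt = test_dt,
                          label = "test")
  ref <- sweep_peak(w_test, p, d0, equilibrium_state(recovery_V, p, d0),
                    measure)$peak
  y <- vapply(intervals, function(iv) {
    s_iv <- if (iv > 0)
      final_state(step_waveform(recovery_V, iv,
                                sample_dt = max(min(iv / 4, 5), iv / 400)),
                  p, d, state0 = s)
    else s
    sweep_peak(w_test, p, d, s_iv, measure)$peak / ref
  }, numeric(1))
  clamp_dataset(intervals, pmin(y, 1), protocol = "recovery",
                x_units = "ms", y_units = "normalized peak",
                provenance = sprintf(
                  "simulated; [D] = %g uM, recovery at %g mV",
                  d$conc * 1e6, recovery_V))
}
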