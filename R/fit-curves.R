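# Closed-form drug-free protocol curves.
#
# Drug-free sweeps involve only m and h, which relax exponentially within a
# constant-voltage pulse, so every fitted observable can be evaluated in
# vectorized closed form.  These fast paths are what the optimizer calls;
# the simulation-based protocol engine in protocols.R must agree with them
# (asserted in the test suite), so they double as an independent oracle for
# the integrator and vice versa.

# Smooth peak of the closed-form pulse conductance
# g(t) = (m_inf + (m0 - m_inf) e^{-t/tau_m})^3 (h_inf + (h0 - h_inf) e^{-t/tau_h}):
# a coarse grid brackets the maximum and optimize() refines it on the
# continuous function, so the fitted observables are smooth in the
# parameters (grid-max peaks produce kinks that stall gradient optimizers).
pulse_g <- function(m0, h0, m_inf, h_inf, tau_m, tau_h) {
  force(m0); force(h0)
  function(t)
    (m_inf + (m0 - m_inf) * exp(-t / tau_m))^3 *
    (h_inf + (h0 - h_inf) * exp(-t / tau_h))
}

smooth_peak <- function(g, t_max, n_grid = 64L) {
  ts <- seq(0, t_max, length.out = n_grid)
  gv <- g(ts)
  i <- which.max(gv)
  if (i == 1L || i == n_grid) {
    lo <- ts[max(i - 1L, 1L)]; hi <- ts[min(i + 1L, n_grid)]
  } else {
    lo <- ts[i - 1L]; hi <- ts[i + 1L]
  }
  opt <- stats::optimize(g, c(lo, hi), maximum = TRUE, tol = 1e-9)
  if (opt$objective >= gv[i]) c(opt$maximum, opt$objective)
  else c(ts[i], gv[i])
}

peak_conductance_pulse <- function(m0, h0, test_V, p, test_ms, dt = NULL) {
  ss <- steady_fast(test_V, p)
  t_max <- min(test_ms, 15 * (ss$tau_m + ss$tau_h))
  vapply(seq_along(m0), function(i) {
    g <- pulse_g(m0[i], h0[i], ss$m_inf, ss$h_inf, ss$tau_m, ss$tau_h)
    smooth_peak(g, t_max)[2]
  }, numeric(1))
}

curve_availability <- function(p, prepulse_V, test_V = -20, test_ms = 20,
                               dt = 0.02, normalize = TRUE) {
  ss <- steady_fast(prepulse_V, p)
  pk <- peak_conductance_pulse(ss$m_inf, ss$h_inf, test_V, p, test_ms, dt)
  if (normalize) pk <- pk / max(pk)
  pk
}

curve_activation <- function(p, test_V, holding_V = -120, test_ms = 20,
                             dt = 0.02, normalize = TRUE) {
  s0 <- steady_fast(holding_V, p)
  sv <- steady_fast(test_V, p)
  pk <- vapply(seq_along(test_V), function(i) {
    g <- pulse_g(s0$m_inf, s0$h_inf, sv$m_inf[i], sv$h_inf[i],
                 sv$tau_m[i], sv$tau_h[i])
    t_max <- min(test_ms, 15 * (sv$tau_m[i] + sv$tau_h[i]))
    smooth_peak(g, t_max)[2]
  }, numeric(1))
  if (normalize) pk <- pk / max(pk)
  pk
}

curve_t_half <- function(p, V, depol_threshold = -60, holding_V = -120,
                         pulse_ms = 50, on_missing = c("error", "cap")) {
  on_missing <- match.arg(on_missing)
  s0 <- steady_fast(holding_V, p)
  vapply(V, function(v) {
    ss <- steady_fast(v, p)
    if (v <= depol_threshold) {
      # recovery branch: h relaxes from 0 toward h_inf(v); the halfway point
      # of an exponential approach is tau * log(2) exactly
      return(ss$tau_h * log(2))
    }
    t_max <- min(pulse_ms, 20 * (ss$tau_m + ss$tau_h))
    g <- pulse_g(s0$m_inf, s0$h_inf, ss$m_inf, ss$h_inf,
                 ss$tau_m, ss$tau_h)
    pk <- smooth_peak(g, t_max)
    half <- pk[2] / 2
    if (g(t_max) > half) {
      if (on_missing == "error")
        stop(sprintf(
          "no 50%% conductance decay within %g ms at V = %g mV", t_max, v))
      return(t_max)
    }
    root <- stats::uniroot(function(t) g(t) - half, c(pk[1], t_max),
                           tol = 1e-12)$root
    root - pk[1]
  }, numeric(1))
}

curve_tau_m <- function(p, V) steady_fast(V, p)$tau_m

#' Model curve for a clamp dataset under given gating parameters
#'
#' Evaluates the drug-free model observable matching `dataset$protocol` at
#' the dataset's x-values, using the closed-form fast paths that the fitter
#' relies on.  Supported tags: `availability`, `activation`, `t_half`,
#' `tau_m`.
#'
#' @param p a [gating_params()] object.
#' @param dataset a [clamp_dataset()].
#' @param opts optional list of protocol settings (`test_V`, `test_ms`,
#'   `holding_V`, `dt`, `depol_threshold`, `pulse_ms`).
#' @return numeric vector of model values at `dataset$x`.
#' @export
model_curve <- function(p, dataset, opts = list()) {
  stopifnot(inherits(dataset, "clamp_dataset"))
  o <- function(name, default) if (is.null(opts[[name]])) default else opts[[name]]
  switch(dataset$protocol,
    availability = curve_availability(p, dataset$x,
                                      test_V = o("test_V", -20),
                                      test_ms = o("test_ms", 20),
                                      dt = o("dt", 0.02)),
    activation = curve_activation(p, dataset$x,
                                  holding_V = o("holding_V", -120),
                                  test_ms = o("test_ms", 20),
                                  dt = o("dt", 0.02)),
    t_half = curve_t_half(p, dataset$x,
                          depol_threshold = o("depol_threshold", -60),
                          holding_V = o("holding_V", -120),
                          pulse_ms = o("pulse_ms", 50),
                          on_missing = "cap"),
    tau_m = curve_tau_m(p, dataset$x),
    stop("no drug-free model curve for protocol tag '",
         dataset$protocol, "'")
  )
}
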