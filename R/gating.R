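#' Voltage-dependent gating rate constants
#'
#' Evaluates the four rates `alpha_m`, `beta_m`, `alpha_h`, `beta_h` at
#' membrane potential `V`, each as `c1 * exp(V / c2)`.  To guard against
#' overflow during optimizer excursions the exponent is capped at
#' `|V / c2| <= 50` (a warning is issued when the cap engages).
#'
#' @param V membrane potential (mV); vectorized.
#' @param p a [gating_params()] object.
#' @return A list with numeric components `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, each the length of `V` (1/ms).
#' @export
gate_rates <- function(V, p) {
  validate_gating_params(p)
  stopifnot(is.numeric(V), all(is.finite(V)))
  one <- function(c1, c2) {
    ex <- V / c2
    if (any(abs(ex) > 50)) {
      warning("rate exponent |V/c2| > 50 capped at 50", call. = FALSE)
      ex <- pmin(pmax(ex, -50), 50)
    }
    c1 * exp(ex)
  }
  list(alpha_m = one(p[["c1_alpha_m"]], p[["c2_alpha_m"]]),
       beta_m  = one(p[["c1_beta_m"]],  p[["c2_beta_m"]]),
       alpha_h = one(p[["c1_alpha_h"]], p[["c2_alpha_h"]]),
       beta_h  = one(p[["c1_beta_h"]],  p[["c2_beta_h"]]))
}

# validation-free fast path used by the fitting hot loop; exponent cap as in
# gate_rates but silent (optimizer bounds keep |V/c2| < 50 anyway)
steady_fast <- function(V, p) {
  ex <- function(c1, c2) c1 * exp(pmin(pmax(V / c2, -50), 50))
  am <- ex(p[["c1_alpha_m"]], p[["c2_alpha_m"]])
  bm <- ex(p[["c1_beta_m"]],  p[["c2_beta_m"]])
  ah <- ex(p[["c1_alpha_h"]], p[["c2_alpha_h"]])
  bh <- ex(p[["c1_beta_h"]],  p[["c2_beta_h"]])
  qm <- am + bm; qh <- ah + bh
  list(m_inf = am / qm, h_inf = ah / qh, tau_m = 1 / qm, tau_h = 1 / qh)
}

#' Steady states and time constants of the gates
#'
#' For each gate, `x_inf = alpha / (alpha + beta)` and
#' `tau = 1 / (alpha + beta)`.
#'
#' @inheritParams gate_rates
#' @return A data frame with columns `V`, `m_inf`, `h_inf`, `tau_m`, `tau_h`.
#' @export
gate_steady <- function(V, p) {
  r <- gate_rates(V, p)
  data.frame(V = V,
             m_inf = r$alpha_m / (r$alpha_m + r$beta_m),
             h_inf = r$alpha_h / (r$alpha_h + r$beta_h),
             tau_m = 1 / (r$alpha_m + r$beta_m),
             tau_h = 1 / (r$alpha_h + r$beta_h))
}

#' Open, unblocked channel fraction
#'
#' `f_open = m^3 * h * (1 - b)`.
#'
#' @param s a [channel_state()], or the activation gate `m` directly when
#'   `h` and `b` are also given.
#' @param h,b optional inactivation gate and bound fraction (vectorized).
#' @return fraction of channels open and free of drug, in \[0, 1\].
#' @export
f_open <- function(s, h = NULL, b = NULL) {
  if (inherits(s, "channel_state")) return(s$m^3 * s$h * (1 - s$b))
  stopifnot(is.numeric(s), is.numeric(h), is.numeric(b))
  s^3 * h * (1 - b)
}

#' Sodium current
#'
#' Ohmic current `I_Na = g_max * f_open * (V - E_Na)`; zero at the reversal
#' potential.
#'
#' @param V membrane potential (mV).
#' @param s a [channel_state()] (or a numeric `f_open` value).
#' @param c a [channel_params()] object.
#' @return current in `g_max` units times mV (negative = inward).
#' @export
na_current <- function(V, s, c = channel_params()) {
  fo <- if (inherits(s, "channel_state")) f_open(s) else s
  c$g_max * fo * (V - c$E_Na)
}

#' Time derivatives of the three state variables
#'
#' Gating follows first-order Hodgkin-Huxley kinetics,
#' `dm/dt = alpha_m (1 - m) - beta_m m` (and likewise for `h`); drug binding
#' targets inactivated channels only,
#' `db/dt = k_on [D] (1 - h)(1 - b) - k_off b`.
#'
#' @param V membrane potential (mV).
#' @param s a [channel_state()].
#' @param p a [gating_params()] object.
#' @param d a [drug_params()] object.
#' @return named numeric vector `c(dm, dh, db)` in 1/ms.
#' @export
state_derivs <- function(V, s, p, d = drug_params()) {
  r <- gate_rates(V, p)
  c(dm = r$alpha_m * (1 - s$m) - r$beta_m * s$m,
    dh = r$alpha_h * (1 - s$h) - r$beta_h * s$h,
    db = d$k_on * d$conc * (1 - s$h) * (1 - s$b) - d$k_off * s$b)
}

#' Effective binding time constant and asymptote at fixed voltage
#'
#' With `h` held at its steady state, the bound fraction relaxes as a scalar
#' linear ODE with
#' `tau_b(V) = 1 / ((1 - h_inf(V)) [D] k_on + k_off)` and
#' `b_inf(V) = (1 - h_inf(V)) [D] k_on * tau_b(V)`.
#' `tau_b <= 1/k_off` always, with equality iff `h_inf = 1` or `[D] = 0`.
#'
#' @param V membrane potential (mV); vectorized.
#' @param p a [gating_params()] object.
#' @param d a [drug_params()] object.
#' @return `tau_b`: time constant (ms); `b_inf`: asymptotic bound fraction.
#' @export
tau_b <- function(V, p, d) {
  ss <- gate_steady(V, p)
  1 / ((1 - ss$h_inf) * d$conc * d$k_on + d$k_off)
}

#' @rdname tau_b
#' @export
b_inf <- function(V, p, d) {
  ss <- gate_steady(V, p)
  kb <- (1 - ss$h_inf) * d$conc * d$k_on
  kb / (kb + d$k_off)
}

#' Equilibrium state at a holding potential
#'
#' Returns the state `(m_inf, h_inf, b_inf)` at which all three derivatives
#' vanish.
#'
#' @inheritParams state_derivs
#' @return a [channel_state()].
#' @export
equilibrium_state <- function(V, p, d = drug_params()) {
  ss <- gate_steady(V, p)
  channel_state(m = ss$m_inf, h = ss$h_inf, b = b_inf(V, p, d), t = 0)
}
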