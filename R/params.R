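#' Gating rate-coefficient set for the m^3 h sodium-channel model
#'
#' The drug-free channel model has four voltage-dependent rate constants,
#' `alpha_m`, `beta_m`, `alpha_h` and `beta_h`, each of the single-exponential
#' form `c1 * exp(V / c2)` with `c1` in 1/ms and `c2` in mV.  The eight
#' coefficients are the free parameters of the drug-free model.
#'
#' The physiological sign convention is enforced: activation opens with
#' depolarization (`c2_alpha_m > 0`, `c2_beta_m < 0`) and inactivation closes
#' with depolarization (`c2_alpha_h < 0`, `c2_beta_h > 0`), which makes
#' `m_inf(V)` strictly increasing and `h_inf(V)` strictly decreasing.
#'
#' @param c1_alpha_m,c1_beta_m,c1_alpha_h,c1_beta_h positive prefactors (1/ms).
#' @param c2_alpha_m,c2_beta_m,c2_alpha_h,c2_beta_h voltage scales (mV),
#'   finite and nonzero, signed as described above.
#' @return An object of class `gating_params`: a named numeric vector of the
#'   eight coefficients.
#' @seealso [gate_rates()], [gate_steady()], [default_truth()]
#' @export
gating_params <- function(c1_alpha_m, c2_alpha_m, c1_beta_m, c2_beta_m,
                          c1_alpha_h, c2_alpha_h, c1_beta_h, c2_beta_h) {
  p <- c(c1_alpha_m = c1_alpha_m, c2_alpha_m = c2_alpha_m,
         c1_beta_m  = c1_beta_m,  c2_beta_m  = c2_beta_m,
         c1_alpha_h = c1_alpha_h, c2_alpha_h = c2_alpha_h,
         c1_beta_h  = c1_beta_h,  c2_beta_h  = c2_beta_h)
  class(p) <- "gating_params"
  validate_gating_params(p)
  p
}

#' @rdname gating_params
#' @param p object to validate.
#' @export
validate_gating_params <- function(p) {
  stopifnot(is.numeric(p), length(p) == 8L)
  nm <- gating_param_names()
  if (!identical(names(unclass(p)), nm))
    stop("gating_params must carry the 8 named coefficients: ",
         paste(nm, collapse = ", "))
  c1 <- p[grep("^c1_", nm)]
  c2 <- p[grep("^c2_", nm)]
  if (any(!is.finite(p))) stop("gating coefficients must be finite")
  if (any(c1 <= 0)) stop("all c1 coefficients must be > 0")
  if (any(c2 == 0)) stop("all c2 coefficients must be nonzero")
  if (p[["c2_alpha_m"]] <= 0 || p[["c2_beta_m"]] >= 0)
    stop("sign convention violated: need c2_alpha_m > 0 and c2_beta_m < 0")
  if (p[["c2_alpha_h"]] >= 0 || p[["c2_beta_h"]] <= 0)
    stop("sign convention violated: need c2_alpha_h < 0 and c2_beta_h > 0")
  invisible(p)
}

gating_param_names <- function() {
  c("c1_alpha_m", "c2_alpha_m", "c1_beta_m", "c2_beta_m",
    "c1_alpha_h", "c2_alpha_h", "c1_beta_h", "c2_beta_h")
}

#' @export
print.gating_params <- function(x, ...) {
  cat("<gating_params>  rate(V) = c1 * exp(V / c2)\n")
  m <- matrix(unclass(x), nrow = 4, byrow = TRUE,
              dimnames = list(c("alpha_m", "beta_m", "alpha_h", "beta_h"),
                              c("c1 [1/ms]", "c2 [mV]")))
  print(signif(m, 6))
  invisible(x)
}

#' Drug binding parameters
#'
#' Binding kinetics of an inactivated-state sodium-channel blocker.  The
#' defaults are the literature values for neutral lidocaine:
#' `k_on = 250 / M / ms` and `k_off = 1.7e-3 / ms`.  Concentration is stored
#' in molar; use [uM()] for micromolar inputs.
#'
#' @param k_on binding rate constant (1/M/ms), > 0.
#' @param k_off unbinding rate constant (1/ms), > 0.
#' @param conc drug concentration (M), >= 0.
#' @return An object of class `drug_params`.
#' @examples
#' d <- drug_params(conc = uM(20))
#' dissociation_constant(d)   # 6.8e-6 M
#' @export
drug_params <- function(k_on = 250, k_off = 1.7e-3, conc = 0) {
  stopifnot(is.numeric(k_on), is.numeric(k_off), is.numeric(conc),
            length(k_on) == 1L, length(k_off) == 1L, length(conc) == 1L)
  if (!is.finite(k_on) || k_on <= 0) stop("k_on must be finite and > 0")
  if (!is.finite(k_off) || k_off <= 0) stop("k_off must be finite and > 0")
  if (!is.finite(conc) || conc < 0)
    stop("drug concentration must be finite and >= 0 (in molar; see uM())")
  structure(list(k_on = k_on, k_off = k_off, conc = conc),
            class = "drug_params")
}

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf("<drug_params> k_on = %g /M/ms, k_off = %g /ms, [D] = %g uM\n",
              x$k_on, x$k_off, x$conc * 1e6))
  invisible(x)
}

#' Convert micromolar to molar
#' @param x concentration in micromolar.
#' @return concentration in molar.
#' @export
uM <- function(x) x * 1e-6

#' Maximal conductance and reversal potential
#'
#' @param g_max maximal conductance (arbitrary units; 1 = normalized), > 0.
#' @param E_Na sodium reversal potential (mV).
#' @return An object of class `channel_params`.
#' @export
channel_params <- function(g_max = 1, E_Na = 70) {
  stopifnot(is.numeric(g_max), is.numeric(E_Na),
            length(g_max) == 1L, length(E_Na) == 1L)
  if (!is.finite(g_max) || g_max <= 0) stop("g_max must be finite and > 0")
  if (!is.finite(E_Na)) stop("E_Na must be finite")
  structure(list(g_max = g_max, E_Na = E_Na), class = "channel_params")
}

#' Channel state: activation, availability, and bound fraction
#'
#' Holds the three dynamic variables of the model: the activation gate `m`,
#' the inactivation gate `h` (fraction non-inactivated), and the drug-bound
#' fraction `b`.  All three are fractions in \[0, 1\].
#'
#' @param m,h,b gating/block fractions in \[0, 1\].
#' @param t optional time stamp (ms).
#' @return An object of class `channel_state`.
#' @export
channel_state <- function(m, h, b = 0, t = NA_real_) {
  stopifnot(is.numeric(m), is.numeric(h), is.numeric(b))
  v <- c(m = m, h = h, b = b)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("channel_state components m, h, b must lie in [0, 1]")
  structure(list(m = m, h = h, b = b, t = t), class = "channel_state")
}

#' @export
print.channel_state <- function(x, ...) {
  cat(sprintf("<channel_state> m = %.6g, h = %.6g, b = %.6g (f_open = %.6g)\n",
              x$m, x$h, x$b, f_open(x)))
  invisible(x)
}

#' Dissociation constant of the blocker
#'
#' `K_d = k_off / k_on`, in molar.  For the lidocaine defaults this is
#' 6.8 uM, the inactivated-state affinity of the neutral species.
#'
#' @param d a [drug_params()] object (`k_off = 0` is tolerated here and gives
#'   `K_d = 0`).
#' @return dissociation constant (M).
#' @export
dissociation_constant <- function(d) {
  stopifnot(inherits(d, "drug_params") || (is.list(d) && !is.null(d$k_on)))
  if (d$k_on <= 0) stop("k_on must be > 0")
  d$k_off / d$k_on
}

#' Charged (protonated) fraction of a weak base
#'
#' Henderson-Hasselbalch arithmetic: the fraction of a weak base that is
#' protonated (positively charged) at a given pH is `1 / (1 + 10^(pH - pKa))`.
#' For lidocaine (pKa 7.6) at physiological pH 7.4 about 60% is charged and
#' 40% neutral; only the neutral species participates in the inactivated-state
#' binding modeled here.
#'
#' @param pH solution pH (vectorized).
#' @param pKa acid dissociation constant of the conjugate acid; default 7.6.
#' @return charged fraction in \[0, 1\].
#' @export
charged_fraction <- function(pH, pKa = 7.6) {
  1 / (1 + 10^(pH - pKa))
}
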