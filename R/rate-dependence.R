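# Closed-form theory of rate-dependent block under square-wave pacing.
#
# The action potential is idealized as a square wave: V = V_AP for APD ms,
# then V = V_DI for DI ms, repeating with period BCL = APD + DI; h is pinned
# to h_inf of the phase voltage.  Within each phase the bound fraction obeys
# a constant-coefficient linear ODE and relaxes exponentially toward
# b_inf(V_phase) with time constant tau_b(V_phase).  Composing the two
# phases gives an affine one-cycle map for b at the upstroke whose fixed
# point b* has the closed form implemented in b_star().

#' Square-wave action-potential descriptor
#'
#' @param V_AP plateau potential (mV); default 20.
#' @param V_DI diastolic potential (mV); default -85.
#' @param APD action-potential duration (ms), > 0.
#' @param DI diastolic interval (ms), > 0.
#' @return An object of class `square_wave_ap` with derived `BCL`.
#' @export
square_wave_ap <- function(APD, DI, V_AP = 20, V_DI = -85) {
  stopifnot(is.numeric(APD), is.numeric(DI), APD > 0, DI > 0)
  if (V_AP <= V_DI) stop("require V_AP > V_DI")
  structure(list(V_AP = V_AP, V_DI = V_DI, APD = APD, DI = DI,
                 BCL = APD + DI),
            class = "square_wave_ap")
}

#' @export
print.square_wave_ap <- function(x, ...) {
  cat(sprintf(
    "<square_wave_ap> V_AP = %g mV (%g ms), V_DI = %g mV (%g ms), BCL = %g ms\n",
    x$V_AP, x$APD, x$V_DI, x$DI, x$BCL))
  invisible(x)
}

#' Binding environment of a square-wave AP
#'
#' Precomputes the per-phase binding time constants and asymptotes and the
#' cycle weight factors `A = exp(-APD / tau_b(V_AP))`,
#' `D = exp(-DI / tau_b(V_DI))`.
#'
#' @param sq a [square_wave_ap()].
#' @param p a [gating_params()] object.
#' @param d a [drug_params()] object.
#' @return list with `tau_AP`, `tau_DI`, `binf_AP`, `binf_DI`, `A`, `D`.
#' @export
binding_env <- function(sq, p, d) {
  stopifnot(inherits(sq, "square_wave_ap"))
  list(tau_AP = tau_b(sq$V_AP, p, d), tau_DI = tau_b(sq$V_DI, p, d),
       binf_AP = b_inf(sq$V_AP, p, d), binf_DI = b_inf(sq$V_DI, p, d),
       A = exp(-sq$APD / tau_b(sq$V_AP, p, d)),
       D = exp(-sq$DI / tau_b(sq$V_DI, p, d)))
}

#' Piecewise-exponential binding transient within one pacing cycle
#'
#' The closed-form solution of the binding ODE with `h` pinned to the phase
#' value: `b(t) = b_inf - (b_inf - b0) * exp(-t / tau_b)` with the phase's
#' `b_inf` and `tau_b`.  `t` is measured from the phase start; the solution
#' is continuous across phase boundaries by construction.
#'
#' @param t time since phase start (ms), `0 <= t <=` phase duration
#'   (vectorized; `t` beyond the phase duration is allowed for limit
#'   checks).
#' @param phase `"ap"` or `"di"`.
#' @param b0 bound fraction at phase start.
#' @param env a [binding_env()].
#' @return bound fraction at `t`.
#' @export
b_transient <- function(t, phase = c("ap", "di"), b0, env) {
  phase <- match.arg(phase)
  stopifnot(all(t >= 0), b0 >= 0, b0 <= 1)
  if (phase == "ap")
    env$binf_AP - (env$binf_AP - b0) * exp(-t / env$tau_AP)
  else
    env$binf_DI - (env$binf_DI - b0) * exp(-t / env$tau_DI)
}

#' Fixed-point bound fraction at the upstroke, b*
#'
#' Under periodic square-wave pacing the bound fraction at the upstroke
#' settles to
#' `b* = [(1 - D)/(1 - A D)] b_inf(V_DI) + [(1 - A) D/(1 - A D)] b_inf(V_AP)`
#' -- a convex combination of the two phase asymptotes (the two bracketed
#' weights sum to 1).
#'
#' @param sq a [square_wave_ap()], or `NULL` when `BCL` and a restitution
#'   curve are given.
#' @param p a [gating_params()] object.
#' @param d a [drug_params()] object.
#' @param restitution optional [restitution_curve()]; when supplied together
#'   with `BCL`, the square wave is built with `APD = f(BCL)` and
#'   `DI = BCL - APD`.
#' @param BCL cycle length (ms) used with `restitution`.
#' @param V_AP,V_DI square-wave levels used with `restitution`.
#' @return fixed-point bound fraction in \[0, 1\].
#' @export
b_star <- function(sq = NULL, p, d, restitution = NULL, BCL = NULL,
                   V_AP = 20, V_DI = -85) {
  if (is.null(sq)) {
    stopifnot(!is.null(restitution), !is.null(BCL))
    APD <- apd_at(restitution, BCL)
    DI <- BCL - APD
    if (any(DI <= 0)) stop("degenerate cycle: DI <= 0 at requested BCL")
    if (length(BCL) > 1)
      return(vapply(seq_along(BCL), function(i)
        b_star(square_wave_ap(APD[i], DI[i], V_AP, V_DI), p, d),
        numeric(1)))
    sq <- square_wave_ap(APD, DI, V_AP, V_DI)
  }
  e <- binding_env(sq, p, d)
  ((1 - e$D) * e$binf_DI + (1 - e$A) * e$D * e$binf_AP) / (1 - e$A * e$D)
}

#' Iterate the one-cycle pacing map for b at the upstroke
#'
#' Composes the AP-phase and DI-phase exponential relaxations cycle by
#' cycle, starting from `b0`.  The map is affine with contraction factor
#' `A * D`, so the sequence converges geometrically to [b_star()].
#'
#' @inheritParams binding_env
#' @param b0 initial bound fraction at the first upstroke.
#' @param n_cycles number of cycles to iterate.
#' @return numeric vector of `b(t_k)`, `k = 0 .. n_cycles` (length
#'   `n_cycles + 1`, starting with `b0`).
#' @export
iterate_pacing_map <- function(sq, p, d, b0 = 0, n_cycles = 100) {
  stopifnot(b0 >= 0, b0 <= 1, n_cycles >= 1)
  e <- binding_env(sq, p, d)
  b <- numeric(n_cycles + 1)
  b[1] <- b0
  for (k in seq_len(n_cycles)) {
    b_ap <- b_transient(sq$APD, "ap", b[k], e)
    b[k + 1] <- b_transient(sq$DI, "di", b_ap, e)
  }
  b
}

#' Sensitivity of b* to cycle length
#'
#' Analytic derivative of [b_star()] with respect to BCL along a restitution
#' curve (`APD = f(BCL)`, `DI = BCL - APD`):
#' `db*/dBCL = (b_inf(V_AP) - b_inf(V_DI)) / (1 - A D)^2 *
#'   ( (1-D) A D / tau_b(V_AP) * f' - (1-A) D / tau_b(V_DI) * (1 - f') )`.
#' With a flat restitution curve the derivative is strictly negative
#' whenever `b_inf(V_AP) > b_inf(V_DI)`: block grows as pacing quickens.
#'
#' @param BCL cycle length (ms), inside the restitution domain (vectorized).
#' @param restitution a [restitution_curve()].
#' @param p,d model and drug parameters.
#' @param V_AP,V_DI square-wave levels (mV).
#' @return derivative in 1/ms.
#' @export
db_star_dBCL <- function(BCL, restitution, p, d, V_AP = 20, V_DI = -85) {
  APD <- apd_at(restitution, BCL)
  DI <- BCL - APD
  if (any(DI <= 0)) stop("degenerate cycle: DI <= 0 at requested BCL")
  s <- apd_slope(restitution, BCL)
  if (any(s < 0)) stop("restitution slope must be >= 0")
  tAP <- tau_b(V_AP, p, d); tDI <- tau_b(V_DI, p, d)
  bAP <- b_inf(V_AP, p, d); bDI <- b_inf(V_DI, p, d)
  A <- exp(-APD / tAP); D <- exp(-DI / tDI)
  (bAP - bDI) / (1 - A * D)^2 *
    ((1 - D) * A * D / tAP * s - (1 - A) * D / tDI * (1 - s))
}

#' Critical restitution slope for reverse rate dependence
#'
#' The value of `df/dBCL` at which `db*/dBCL` changes sign, obtained by
#' setting the bracketed factor of the BCL-derivative to zero (the common
#' factor `D` cancels):
#' `slope_c = 1 / (1 + (tau_b(V_DI)/tau_b(V_AP)) * (1 - D) A / (1 - A))`.
#' Above this slope, block *decreases* at faster pacing (reverse rate
#' dependence).  The value lies in (0, 1); substituting it back into the
#' bracket gives zero identically.
#'
#' @inheritParams db_star_dBCL
#' @return critical slope (dimensionless), in (0, 1).
#' @export
critical_slope <- function(BCL, restitution, p, d, V_AP = 20, V_DI = -85) {
  APD <- apd_at(restitution, BCL)
  DI <- BCL - APD
  if (any(DI <= 0)) stop("degenerate cycle: DI <= 0 at requested BCL")
  tAP <- tau_b(V_AP, p, d); tDI <- tau_b(V_DI, p, d)
  A <- exp(-APD / tAP); D <- exp(-DI / tDI)
  critical_slope_from_env(A, D, tAP, tDI)
}

# root of the BCL-sensitivity bracket in terms of (A, D, tau_AP, tau_DI)
critical_slope_from_env <- function(A, D, tau_AP, tau_DI) {
  1 / (1 + (tau_DI / tau_AP) * (1 - D) * A / (1 - A))
}

#' Scan b* over a BCL grid
#'
#' @inheritParams db_star_dBCL
#' @param BCL grid of cycle lengths (ms).
#' @return data frame with columns `BCL`, `APD`, `DI`, `b_star`,
#'   `db_star_dBCL`, `critical_slope`, `slope`; rows whose BCL is outside
#'   the restitution domain (or degenerate) carry `NA` and are collected in
#'   `attr(, "errors")` rather than raising.
#' @export
scan_b_star <- function(BCL, restitution, p, d, V_AP = 20, V_DI = -85) {
  n <- length(BCL)
  out <- data.frame(BCL = BCL, APD = NA_real_, DI = NA_real_,
                    b_star = NA_real_, db_star_dBCL = NA_real_,
                    critical_slope = NA_real_, slope = NA_real_)
  errs <- character(0)
  for (i in seq_len(n)) {
    ok <- tryCatch({
      out$APD[i] <- apd_at(restitution, BCL[i])
      out$DI[i] <- BCL[i] - out$APD[i]
      out$b_star[i] <- b_star(p = p, d = d, restitution = restitution,
                              BCL = BCL[i], V_AP = V_AP, V_DI = V_DI)
      out$db_star_dBCL[i] <- db_star_dBCL(BCL[i], restitution, p, d,
                                          V_AP, V_DI)
      out$critical_slope[i] <- critical_slope(BCL[i], restitution, p, d,
                                              V_AP, V_DI)
      out$slope[i] <- apd_slope(restitution, BCL[i])
      TRUE
    }, error = function(e) {
      errs <<- c(errs, sprintf("BCL %g: %s", BCL[i], conditionMessage(e)))
      FALSE
    })
  }
  attr(out, "errors") <- errs
  out
}

#' Equivalence of binding-rate scaling and time rescaling
#'
#' Scaling both binding rates by `sigma` is algebraically equivalent to
#' scaling APD and DI by `sigma` at the original rates (equivalently, to
#' rescaling BCL with the adjusted restitution curve
#' `APD = f(sigma * BCL) / sigma`): `A`, `D` and the phase asymptotes are
#' invariant, hence so is b*.  Returns both sides for verification.
#'
#' @inheritParams binding_env
#' @param sigma positive scale factor.
#' @return list with `b_scaled_rates` (rates scaled by `sigma`, original
#'   APD/DI) and `b_scaled_time` (original rates, APD/DI scaled by
#'   `sigma`).
#' @export
rate_scaling_check <- function(sigma, sq, p, d) {
  stopifnot(sigma > 0)
  d_s <- drug_params(d$k_on * sigma, d$k_off * sigma, d$conc)
  sq_s <- square_wave_ap(sq$APD * sigma, sq$DI * sigma, sq$V_AP, sq$V_DI)
  list(b_scaled_rates = b_star(sq, p, d_s),
       b_scaled_time = b_star(sq_s, p, d))
}

#' Sensitivity of b* to the square-wave voltage levels
#'
#' Central finite differences (default step 0.5 mV) of [b_star()] with
#' respect to `V_AP` or `V_DI` at fixed APD/DI.
#'
#' @inheritParams db_star_dBCL
#' @param which `"V_AP"` or `"V_DI"`.
#' @param step finite-difference step (mV).
#' @return derivative in 1/mV.
#' @export
db_star_dV <- function(BCL, restitution, p, d, which = c("V_AP", "V_DI"),
                       V_AP = 20, V_DI = -85, step = 0.5) {
  which <- match.arg(which)
  f <- function(vap, vdi)
    b_star(p = p, d = d, restitution = restitution, BCL = BCL,
           V_AP = vap, V_DI = vdi)
  if (which == "V_AP")
    (f(V_AP + step, V_DI) - f(V_AP - step, V_DI)) / (2 * step)
  else
    (f(V_AP, V_DI + step) - f(V_AP, V_DI - step)) / (2 * step)
}
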