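# Synthetic ground-truth fixtures.
#
# All test inputs are generated here with known truth.  The clamp fixtures
# emulate the qualitative shape of published sodium-channel voltage-clamp
# curves (half-points, slopes, time scales) but are NOT digitized
# experimental data; the package makes no claim of reproducing any published
# dataset numerically.

#' Reference ("truth") gating parameter preset
#'
#' A fixed coefficient set constructed so that the availability curve
#' `h_inf(V)` has its half-point near -71 mV with a ~6.5 mV slope factor
#' (steeply switching between -85 and -75 mV), `h_inf(-85)` rounds to 0.9
#' and `h_inf(+20)` rounds to 0.0, activation `m_inf(V)^3` saturates above
#' about -20 mV, and the gating time constants sit in the physiological
#' millisecond range (`tau_h(-85)` about 7 ms, `tau_m` sub-millisecond).
#' This preset is the generator truth for every synthetic fixture.
#'
#' @return a [gating_params()] object.
#' @export
default_truth <- function() {
  gating_params(c1_alpha_m = 40,      c2_alpha_m = 12,
                c1_beta_m  = 0.13,    c2_beta_m  = -16.8,
                c1_alpha_h = 2.6e-5,  c2_alpha_h = -10,
                c1_beta_h  = 1.39,    c2_beta_h  = 18.6)
}

#' Fixture generation specification
#'
#' @param protocols subset of `c("availability", "activation", "t_half",
#'   "tau_m")` to generate.
#' @param truth truth [gating_params()]; default [default_truth()].
#' @param noise_sd named noise standard deviations per protocol (additive
#'   Gaussian; fraction-valued outputs are clipped back to \[0, 1\], `t_half`
#'   noise is applied on the log scale so it fits the log-scale objective).
#'   Default 0 (noiseless).
#' @param seed RNG seed recorded in the provenance of every dataset.
#' @param grids named list of x-grids overriding the defaults.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(protocols = c("availability", "activation",
                                       "t_half", "tau_m"),
                         truth = default_truth(), noise_sd = 0,
                         seed = 20210629, grids = list()) {
  protocols <- match.arg(protocols, several.ok = TRUE)
  if (length(noise_sd) == 1 && is.null(names(noise_sd)))
    noise_sd <- stats::setNames(rep(noise_sd, length(protocols)), protocols)
  stopifnot(all(noise_sd >= 0))
  default_grids <- list(availability = seq(-120, -40, by = 5),
                        activation = seq(-60, 20, by = 5),
                        t_half = c(seq(-120, -90, by = 10),
                                   seq(-40, 30, by = 10)),
                        tau_m = seq(-60, 30, by = 10))
  for (nm in names(grids)) default_grids[[nm]] <- grids[[nm]]
  structure(list(protocols = protocols, truth = truth, noise_sd = noise_sd,
                 seed = as.integer(seed), grids = default_grids),
            class = "fixture_spec")
}

#' Generate synthetic clamp datasets with known truth
#'
#' Evaluates the drug-free model observables on the truth parameters at the
#' spec's x-grids and adds the spec's noise.  Reproducible bit-for-bit from
#' the seed; the seed and truth preset are recorded in each dataset's
#' provenance string.
#'
#' @param spec a [fixture_spec()].
#' @return named list of [clamp_dataset()] objects.
#' @export
gen_clamp_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  out <- list()
  for (tag in spec$protocols) {
    x <- spec$grids[[tag]]
    ds0 <- clamp_dataset(x, rep(0.5, length(x)), protocol = tag)
    y <- model_curve(spec$truth, ds0)
    sd <- spec$noise_sd[[tag]]
    if (is.null(sd) || is.na(sd)) sd <- 0
    if (sd > 0) {
      if (tag == "t_half") y <- exp(log(y) + stats::rnorm(length(y), 0, sd))
      else y <- pmin(pmax(y + stats::rnorm(length(y), 0, sd), 0), 1)
    }
    out[[tag]] <- clamp_dataset(
      x, y, protocol = tag,
      x_units = if (tag %in% c("availability", "activation", "tau_m"))
        "mV" else "mV",
      y_units = switch(tag, t_half = "ms", tau_m = "ms",
                       "normalized fraction"),
      provenance = sprintf("synthetic: truth=default_truth, sd=%g, seed=%d",
                           sd, spec$seed))
  }
  out
}

#' Restitution-curve presets
#'
#' `"default"` emulates a human-ventricular APD90 restitution curve
#' (exponential form, `APD_max` 320 ms, `tau_r` 200 ms on BCL 300-1000 ms);
#' `"steep"` is a steeper hypothetical curve (same `APD_max`, `a = 1.6`,
#' `tau_r` 320 ms) whose slope at 400 ms roughly doubles the default's;
#' `"flat"` has constant APD.  `"tabulated"` samples the default preset on a
#' coarse knot grid and interpolates it monotonically, exercising the
#' tabulated pathway.
#'
#' @param preset one of `"default"`, `"steep"`, `"flat"`, `"tabulated"`.
#' @return a [restitution_curve()].
#' @export
gen_restitution <- function(preset = c("default", "steep", "flat",
                                       "tabulated")) {
  preset <- match.arg(preset)
  switch(preset,
    default = restitution_curve("exponential", apd_max = 320, a = 1,
                                tau_r = 200, domain = c(300, 1000)),
    steep = restitution_curve("exponential", apd_max = 320, a = 1.6,
                              tau_r = 320, domain = c(300, 1000)),
    flat = restitution_curve("flat", apd = 250, domain = c(300, 1000)),
    tabulated = {
      knots <- seq(300, 1000, by = 50)
      restitution_curve("tabulated", bcl = knots,
                        apd_tab = 320 * (1 - exp(-knots / 200)),
                        domain = c(300, 1000))
    })
}

#' Action-potential clamp waveforms
#'
#' Builds a periodic AP-clamp drive: `"square"` alternates instantaneously
#' between `V_AP` and `V_DI`; `"trapezoid"` inserts linear ramps of
#' `ramp_ms` at the upstroke and repolarization (discretized to a fine
#' piecewise-constant staircase), for testing the insensitivity of pacing
#' results to the AP waveform shape.  Phase durations are defined so one
#' cycle is `APD + DI` with upstrokes at `t_k = k (APD + DI)`.
#'
#' @param kind `"square"` or `"trapezoid"`.
#' @param V_AP,V_DI plateau/diastolic potentials (mV).
#' @param APD,DI phase durations (ms).
#' @param ramp_ms ramp duration for the trapezoid (< APD/2).
#' @param n_cycles number of pacing cycles.
#' @param sample_dt output sampling (ms).
#' @param ramp_dt staircase step used to discretize ramps (ms).
#' @return a [step_waveform()].
#' @export
gen_ap_waveform <- function(kind = c("square", "trapezoid"), V_AP = 20,
                            V_DI = -85, APD, DI, ramp_ms = 2, n_cycles = 1,
                            sample_dt = 1, ramp_dt = 0.05) {
  kind <- match.arg(kind)
  stopifnot(APD > 0, DI > 0, n_cycles >= 1)
  if (kind == "square" || ramp_ms == 0)
    return(square_wave_clamp(V_AP, V_DI, APD, DI, n_cycles, sample_dt))
  if (ramp_ms >= APD / 2) stop("ramp_ms must be < APD/2")
  n_r <- max(2L, ceiling(ramp_ms / ramp_dt))
  # upstroke ramp occupies the start of the AP phase, repolarization ramp
  # the start of the DI phase, so BCL is preserved
  up_V <- V_DI + (seq_len(n_r) - 0.5) / n_r * (V_AP - V_DI)
  down_V <- rev(up_V)
  seg_V <- c(up_V, V_AP, down_V, V_DI)
  seg_d <- c(rep(ramp_ms / n_r, n_r), APD - ramp_ms,
             rep(ramp_ms / n_r, n_r), DI - ramp_ms)
  seg_l <- c(rep("ramp", n_r), "ap", rep("ramp", n_r), "di")
  step_waveform(rep(seg_V, n_cycles), rep(seg_d, n_cycles),
                sample_dt = sample_dt,
                label = rep(seg_l, n_cycles))
}

# session cache for the fitted default parameter set
.rdblock_cache <- new.env(parent = emptyenv())

#' Packaged default fitted parameter set
#'
#' The package's working parameter set is *derived*: it is the result of
#' [fit_drug_free()] on the packaged noiseless synthetic fixture
#' ([gen_clamp_fixture()] with defaults), not a published value.  The fit is
#' deterministic given the configuration and is cached for the session.
#'
#' @param config a [fit_config()]; default configuration.
#' @param refit force recomputation, ignoring the session cache.
#' @return a `fit_result` (see [fit_drug_free()]); the coefficient set is
#'   in `$params`.
#' @export
default_fitted_params <- function(config = fit_config(), refit = FALSE) {
  key <- sprintf("fit_%d_%d", config$n_starts, config$seed)
  if (!refit && !is.null(.rdblock_cache[[key]]))
    return(.rdblock_cache[[key]])
  fix <- gen_clamp_fixture(fixture_spec())
  fit <- fit_drug_free(fix, config)
  .rdblock_cache[[key]] <- fit
  fit
}
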