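---
title: "Modeling rate-dependent sodium-channel block with a three-variable model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling rate-dependent sodium-channel block with a three-variable model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdblock)
```

## The model

Class I antiarrhythmics such as lidocaine block the cardiac fast Na⁺
current in a use- and rate-dependent way: block accumulates at fast pacing
and washes out at slow pacing.  `rdblock` implements a deliberately minimal
model of this phenomenon.  The drug-free channel is a Hodgkin–Huxley
`m³h` conductance,

$$ I_{Na} = \bar g_{Na}\, m^3 h\, (1-b)\, (V - E_{Na}), $$

with first-order gates
$\mathrm{d}x/\mathrm{d}t = \alpha_x(V)(1-x) - \beta_x(V)x$ and rate
constants of the single-exponential form $c_1 e^{V/c_2}$ — eight free
coefficients in total.  The drug enters through one additional state
variable, the bound fraction $b$, built on three assumptions about neutral
lidocaine distilled from Markov-model analyses: only the neutral species
matters, it binds only to inactivated channels, and binding locks the
channel inactivated until the drug unbinds.  Hence

$$ \frac{\mathrm{d}b}{\mathrm{d}t} = k_{on}[D](1-h)(1-b) - k_{off}\,b, $$

with literature kinetics $k_{on} = 250\ \mathrm{M^{-1}ms^{-1}}$,
$k_{off} = 1.7\times10^{-3}\ \mathrm{ms^{-1}}$ (so
$K_d = 6.8\ \mu\mathrm{M}$).  Drug parameters are never fitted.
Internal units are fixed throughout: mV, ms, molar (file interfaces accept
micromolar and convert at the boundary).

At a fixed voltage with $h$ settled, $b$ relaxes as a scalar linear ODE
with

$$ \tau_b(V) = \frac{1}{(1-h_\infty(V))[D]k_{on} + k_{off}}, \qquad
   b_\infty(V) = (1-h_\infty(V))[D]k_{on}\,\tau_b(V). $$

Because $\tau_b$ is hundreds of milliseconds while $\tau_m$ is
sub-millisecond, the voltage dependence of $b_\infty$ — inherited entirely
from steady-state inactivation $1-h_\infty(V)$ — is what makes block
rate-dependent: the drug binds during the action potential (where
$h_\infty \approx 0$) and unbinds during diastole (where
$h_\infty \approx 0.9$).

## Square-wave pacing theory

Under periodic pacing, the membrane potential is idealized as a square wave:
$V_{AP}$ (default 20 mV) for a duration APD, then $V_{DI}$ (default
−85 mV) for a diastolic interval DI, with cycle length BCL = APD + DI, and
$h$ is idealized the same way ($h \equiv h_\infty$ of the phase voltage).
The binding ODE then has piecewise-constant coefficients; `b_transient()`
is its exact piecewise-exponential solution, and composing one AP phase and
one DI phase gives an affine map for $b$ at successive upstrokes with
contraction factor $AD$, where $A = e^{-APD/\tau_b(V_{AP})}$ and
$D = e^{-DI/\tau_b(V_{DI})}$.  Its fixed point is the closed form computed
by `b_star()`:

$$ b^* = \frac{1-D}{1-AD}\, b_\infty(V_{DI})
       + \frac{(1-A)D}{1-AD}\, b_\infty(V_{AP}), $$

a convex combination of the two phase asymptotes.  Along a restitution
curve APD = f(BCL) (DI = BCL − APD), the analytic sensitivity
`db_star_dBCL()` is

$$ \frac{\partial b^*}{\partial BCL} =
  \frac{b_\infty(V_{AP}) - b_\infty(V_{DI})}{(1-AD)^2}
  \left( \frac{(1-D)AD}{\tau_b(V_{AP})} f'
       - \frac{(1-A)D}{\tau_b(V_{DI})} (1 - f') \right), $$

whose bracket changes sign at the critical restitution slope

$$ f'_c = \left[ 1 + \frac{\tau_b(V_{DI})}{\tau_b(V_{AP})}
          \frac{(1-D)A}{1-A} \right]^{-1}. $$

Above that slope, block *decreases* at faster pacing (reverse rate
dependence).  The printed form of the sensitivity expression is ambiguous
in its source rendering, so the implementation *defines* the critical slope
as the root of the bracket and verifies algebraically (1000 random
$(A, D, \tau)$ tuples in the acceptance suite) that substituting it back
yields zero; the closed form above is the cancellation-simplified root (the
common factor $D$ drops).  Both the sensitivity formula and the root were
additionally cross-checked against numerical differentiation of $b^*$
before being frozen into code.

A useful exact symmetry, exposed as `rate_scaling_check()`: scaling both
binding rates by $\sigma$ equals scaling APD and DI by $\sigma$ ($A$, $D$,
and the asymptotes are invariant), i.e. rescaling BCL with the adjusted
restitution curve $f(\sigma\,\mathrm{BCL})/\sigma$.

### What "matches the ODE" means here

The closed form solves the binding ODE *with the square-wave* $h$.  The
oracle tests therefore integrate that same pinned-$h$ ODE with a forced
RK4 method (`simulate_gating(..., pin_h = TRUE, method = "rk4")`) — a
genuinely numerical, independent route — and demand agreement to 1e−6
(transient) and 1e−4 (fixed point).  With $h$ relaxing freely at its own
$\tau_h$, the model deviates from the square-wave idealization: extra
binding accrues while $h$ recovers at the start of diastole, roughly
$k_{on}[D](h_\infty^{DI}-h_\infty^{AP})(\tau_h^{DI}-\tau_h^{AP})$ per
cycle.  With the packaged parameters this puts the free-$h$ steady state
about 4×10⁻³ above $b^*$ (APD 300 ms, DI 450 ms, 20 µM) — small on the
scale of $b^* \approx 0.4$, which is why the square-wave theory is useful,
but two orders above the numerical tolerance, which is why the free-$h$
comparison is reported as a model-approximation gap (tested at 0.01,
alongside the trapezoid-waveform insensitivity check) and not as a solver
accuracy criterion.

## Numerical integration

There is no general-purpose stiff ODE solver among the package's
dependencies, and none is needed: every waveform is piecewise constant (or
is discretized to a fine staircase, as in the trapezoid AP clamp).  Within
a constant-voltage segment, $m$ and $h$ obey scalar linear ODEs and are
evaluated in closed form — the stiffness gap $\tau_m \ll \tau_b$ never
meets a finite-difference step.  The bound fraction is advanced by
classical RK4 sub-steps (`dt ≤ min(τ_h/4, τ_b/20)`) against the analytic
$h(t)$ while $h$ is still relaxing, and by the exact constant-coefficient
exponential update once $h$ has settled (after $12\,\tau_h$) or whenever
$h$ is pinned.  Integration restarts at segment boundaries, so voltage
discontinuities are handled exactly.  States are clipped to $[0,1]$ only
for excursions below 1e−8 (round-off); anything larger raises an error
rather than being silently repaired.  Peak detection in the protocol engine
samples test pulses at 0.01 ms and takes the grid maximum.

## Voltage-clamp protocols and the fit

The protocol engine reproduces the standard characterization suite:
steady-state availability and activation, the two-branch time to half
inactivation (conductance decay after an activation pulse at depolarized
potentials; half-recovery of $h$ at hyperpolarized potentials), activation
time constant $\tau_m = 1/(\alpha_m+\beta_m)$, tonic block, use-dependent
block with dose and frequency scans, and recovery from use-dependent block.
Peaks are measured on the conductance $\bar g m^3h(1-b)$ (driving force is
constant within a sweep; a `measure = "current"` toggle exists).  Because
$b$ equilibrates with a 10²–10³ ms time constant, sweeps start by default
from the *analytic* equilibrium of the conditioning potential — exact for
constant holds — instead of simulating multi-second holds; this is the
documented `analytic_init` option.  Protocol timings are conventional
defaults (availability prepulse 1000 ms; test pulses −20 mV × 20 ms; UDB
trains 25 × 25 ms from −100 mV; frequency scan 1–10 Hz), all overridable.
The model-vs-data summary is the mean of squared differences
($\tfrac1n\sum(y_i-x_i)^2$), kept under its conventional name `sse`.

Fitting (`fit_drug_free()`) estimates only the eight drug-free gating
coefficients, by bounded least squares on the combined availability /
activation / $t_{1/2}$ / $\tau_m$ objective ($t_{1/2}$ entering on the log
scale, since those values span 0.1–10 ms against fraction-valued curves;
per-dataset weights default to 1).  The optimizer vector is
$(\log c_1, c_2)$ per rate with signs fixed by the physiological
convention ($m_\infty$ increasing, $h_\infty$ decreasing) and bounds
$c_1 \in [10^{-6}, 10^3]\ \mathrm{ms^{-1}}$, $|c_2| \in [3, 100]$ mV.
Three design choices matter for reliability and were settled during
development:

* **Smooth observables.** Peak conductance and half-decay times are
  computed from the closed-form pulse solution with `optimize()` /
  `uniroot()`, not from grid maxima; grid-max kinks otherwise stall
  gradient-based optimizers at ~10⁻⁴ objective values ("false
  convergence").
* **A data-driven start.** Pointwise, $x_\infty = \alpha/(\alpha+\beta)$
  and $\tau = 1/(\alpha+\beta)$ invert to $\alpha = x_\infty/\tau$,
  $\beta = (1-x_\infty)/\tau$; crude curve-level estimates of
  $(x_\infty, \tau)$ at several voltages give implied rates whose
  log-linear regression on $V$ recovers $(\log c_1, 1/c_2)$.  This
  deterministic start joins the random log-uniform/uniform multistarts and
  reliably sits in the global basin for clean data.
* **L-BFGS-B polish.** The best screened starts are polished with
  L-BFGS-B down to the finite-difference noise floor (~10⁻⁹ objective on
  noiseless fixtures); `nlminb` alone quits early in the long curved
  $(\log c_1, c_2)$ valley.

On the packaged noiseless fixture the fit recovers every coefficient to
within 0.1% (the acceptance criterion allows 5%); with 0.02 Gaussian noise
the recovered *curves* stay within ~0.02 of truth even where coefficients
trade off.  The fit is bit-reproducible given its seed.

## What the synthetic fixtures are — and are not

All test inputs carry known ground truth.  `default_truth()` is a fixed
coefficient set constructed once from qualitative constraints:
availability half-point near −71 mV with a ~6.5 mV logistic slope (so
$h_\infty$ switches steeply between −85 and −75 mV, $h_\infty(-85)$ rounds
to 0.9 and $h_\infty(20)$ to 0.0), activation saturating above about
−20 mV, $\tau_h(-85) \approx 7$ ms and sub-millisecond $\tau_m$.  Noise is
additive Gaussian, homoscedastic per protocol (no error model is available
for the emulated experiments), clipped to $[0,1]$ for fraction-valued
curves and applied on the log scale for $t_{1/2}$.  Restitution presets
use $f(BCL) = APD_{max}(1 - a\,e^{-BCL/\tau_r})$ with
$APD_{max} = 320$ ms, $\tau_r = 200$ ms (default, emulating a human
ventricular APD₉₀ curve on BCL 300–1000 ms) and a steeper hypothetical
variant ($a = 1.6$, $\tau_r = 320$ ms); tabulated curves are interpolated
with a monotone Fritsch–Carlson cubic, whose derivative feeds the
sensitivity formula.

These fixtures emulate the *shapes* of published sodium-channel
voltage-clamp data (half-points, slopes, time scales).  They are not
digitized experimental curves, so a green test establishes internal
consistency — generator → protocol engine → fitter → closed-form theory —
and the qualitative phenomenology (use dependence, dose and frequency
dependence, recovery tails with $\tau_b$, the directional sensitivities of
$b^*$), not agreement with any particular published measurement.  Known
model limitations carry over from the three founding assumptions: no slow
inactivation (recovery from inactivation is faster than experiment), no
charged-species binding (tonic block is underpredicted at concentrations
well above the clinical 5–20 µM range), and no conduction — the package
deliberately stops at the AP-clamp level, where the square-wave theory is
exact enough to be checked to machine precision.

## Degenerate inputs and edge policies

Rate exponents are capped at $|V/c_2| \le 50$ with a warning (optimizer
excursions otherwise overflow); protocol sweeps with no detectable peak are
flagged rather than dropped; half-decay searches report their span when no
crossing exists; `scan_b_star()` collects per-point domain errors
(BCL outside the restitution domain, DI ≤ 0) instead of failing the scan;
the pacing map iterates to $|\Delta b| < 10^{-12}$ or 10⁴ cycles.
Restitution curves must satisfy $0 < f(BCL) < BCL$ and be nondecreasing on
their stated domain; both are validated at construction on a 201-point
grid.
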