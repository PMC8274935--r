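Package: rdblock
Title: Low-Dimensional Modeling of State-Dependent Sodium-Channel Block
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of use- and rate-dependent block of
    cardiac fast sodium channels by inactivated-state blockers such as
    lidocaine.  Implements a three-variable model coupling Hodgkin-Huxley
    m^3*h gating to a drug-bound channel fraction b, a voltage-clamp
    protocol engine (steady-state availability and activation, time to
    half inactivation, tonic block, use-dependent block, recovery,
    frequency dependence), multistart least-squares fitting of the eight
    drug-free gating coefficients, and the closed-form theory of
    rate-dependent block under square-wave pacing: the piecewise
    exponential binding transient, the periodic-pacing fixed point b*,
    its sensitivity to basic cycle length, and the critical restitution
    slope for reverse rate dependence.  Includes generators for synthetic
    voltage-clamp fixtures with known ground truth, restitution curves,
    and action-potential clamp waveforms, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
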