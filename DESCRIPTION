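Package: glycoreg
Title: Hybrid LQ-Integral and Adaptive Sliding-Mode Control of Blood Glucose
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: In-silico closed-loop insulin delivery on Bergman-minimal-model
    virtual patients. Provides the nonlinear glucose-insulin plant and its
    linearized state-space form with published parameter presets, a
    linear-quadratic-integral regulator synthesized through the continuous
    algebraic Riccati equation, an integral-type sliding surface with
    sgn/tanh reaching laws and a hyperbolic-secant self-adaptive switching
    gain, a sampled-data closed-loop simulator (60-second controller period,
    continuous plant integration) with hyperglycemia, meal, stress and
    sensor-fault scenarios, controller performance metrics (settling and
    recovery times, RMS error, input energy), an offline greedy tuning loop,
    sensitivity sweeps, and the accompanying statistical analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
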