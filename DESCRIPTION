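Package: goldrush
Title: Dynamics of Spurious and Corrective Publication in Biomedical Science
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A compartmental 'gold rush' model of the scientific publishing
    ecosystem in which an initial spurious (false-positive) finding seeds
    follow-on spurious work while corrective null results accumulate after a
    delay and eventually nullify it.  Provides the closed-form trajectories of
    the coupled linear system, the correction time, research-waste and
    corrective-effort integrals, classification of self-correcting versus
    non-correcting parameter regimes, scenario tables and two-parameter sweep
    grids, an independent fixed-step Runge-Kutta and quadrature oracle for
    cross-validation of every closed form, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
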