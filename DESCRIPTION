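Package: dpitrack
Title: Lagrangian Particle Tracking and Aerodynamic Performance Metrics for
    Capsule Dry Powder Inhalers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of powder transport and particle-wall
    interaction inside a capsule-based dry powder inhaler. Tracks particles
    through a pluggable steady velocity field with a capture-velocity sticking
    model and rolling/sliding detachment criteria, samples particle sizes from
    fitted Rosin-Rammler distributions, and computes the aerodynamic
    performance metrics used in inhaled-product development (emitted fraction,
    fine particle dose and fraction, mass median aerodynamic diameter and
    geometric standard deviation from cascade-impactor log-probability
    analysis) together with cross-method agreement statistics (R squared,
    RMSE, NRMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
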