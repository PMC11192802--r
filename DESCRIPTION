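Package: satloss
Title: Pulse-Oximetry Signal Loss During Prolonged Hypoxemic Episodes
    Under Automated Oxygen Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterization of prolonged hypoxemic episodes
    (SpO2 < 80% for at least 30 s within a desaturation below 90%), pulse-oximetry
    signal-loss periods, and post-recovery hyperoxemic overshoots in neonatal
    SpO2/FiO2 recordings. Includes a simulator of the signal-loss behaviors of an
    automated closed-loop oxygen controller (back-up FiO2 fallback, periodic
    baseline-FiO2 update toward a trailing mean, FiO2 cap), a ground-truthed
    synthetic cohort generator for preterm-infant recordings, and nonparametric
    cohort summaries comparing episodes with and without signal loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
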