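Package: gltr
Title: Gas-Liquid Transport Analysis of Airway Mucus Clearance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for cilia-independent gas-liquid
    transport (GLT) of airway mucus during tidal breathing. Provides a
    per-generation airflow model of the symmetric dichotomous (Weibel)
    human airway tree with inhalation/exhalation diameter hysteresis and
    Reynolds-number laminarity checks; drift-corrected kinematic analysis
    of mucus-embedded bead trajectories recorded during breath-mimicking
    airflow pulses (pulse displacement, elastic recoil, percent recovery,
    net displacement); radiotracer clearance-curve analysis (fiducial
    coregistration, percent-cleared curves, windowed initial rates,
    biphasic exponential fits, clearance-versus-breathing-frequency
    regression); and seeded synthetic-data generators with recorded ground
    truth so every analysis stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
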