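Package: pedibca
Title: Pediatric Body-Composition Analysis from Portable Sensor Readings
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational pipeline of a portable bioelectrical-impedance
    and near-infrared body-composition analyzer for children. Provides
    deterministic forward models for the raw sensors (strain-gauge load
    cell read through a 24-bit ADC, 970-nm photosensor, swept-frequency
    impedance converter), the estimation chain from those signals to six
    body-composition parameters (BMI, body-fat percentage, fat-free mass,
    total body water, muscle mass, bone mass), published cross-parameter
    linear prediction models with refitting and stepwise selection,
    method-agreement statistics (accuracy, Bland-Altman limits of
    agreement, intraclass correlation, standard error of measurement),
    and a seeded synthetic-cohort generator that inverts the estimation
    chain back to raw sensor frames so that every pipeline stage can be
    exercised end-to-end without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
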