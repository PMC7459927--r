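Package: waistload
Title: Static Biomechanical Model of Waist Loading During Manual Lifting
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Static sagittal-plane torque-balance model of the lumbosacral
    (L5-S1) joint during stooped manual material lifting, built on Chinese
    male body-segment inertial parameters. Computes the erector spinae
    pulling force as a function of object weight and lifting height, a
    China-adapted NIOSH recommended weight limit (20 kg load constant,
    72 cm vertical reference), a waist comfort score C = 1 - F/F(RWL), the
    lifting index with its load-risk classification, and the L5-S1
    compression/shear decomposition checked against the 3400 N NIOSH
    compression criterion. Provides grid sweeps over lifting heights, batch
    assessment of worker-task tables, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
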