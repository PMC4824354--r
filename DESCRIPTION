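Package: spindisc
Title: Modelling Centrifugal Lab-on-a-Disc Density-Gradient Blood Fractionation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Physical modelling toolkit for centrifugal microfluidic
    ("lab-on-a-disc") blood fractionation devices. Computes capillary
    burst-valve pressure thresholds and burst speeds from Young-Laplace
    pinning, Stokes sedimentation times of blood cells through discrete
    density-gradient sections under ramped spin protocols, predicted
    end-of-run partitions for a panel of cell species, and separation
    performance metrics (retention, exclusion, enrichment) from fraction
    count tables. Includes an independent numerical trajectory integrator
    used to validate the closed-form timing model, a seeded synthetic
    count-table generator, and YAML/CSV device-configuration round-tripping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
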