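Package: tropism
Title: Photo-Gravi-Proprioceptive Models of Plant Shoot Tropism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of plant shoot tropic movement under
    combined graviception, photoception and proprioception. Implements the
    four linear angle-curvature model variants for the dynamics of a growing
    organ's median line (local or apical light sensing, with or without
    gravisensing), their closed-form transients, steady states and limit
    cases, a method-of-lines integrator with a matrix-exponential reference
    stepper and a finite signal-propagation-time variant, and inference of
    the dimensionless control numbers B, D and M and of the intensity-response
    law M(I) (Stevens power law versus Weber-Fechner logarithmic law) from
    photogravitropic-equilibrium tip-angle data by orthogonal (total least
    squares) regression. Includes a synthetic-data generator emulating
    classical tilted-coleoptile equilibrium protocols with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
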