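Package: schoolkin
Title: Kinematic Analysis of Social Swimming and Active-Brownian Fish Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to quantify social swimming in groups of fish filmed in a
    circular tank: central-difference kinematics with tracking-error and
    activity filtering, wall-relative density and nematic alignment profiles,
    pair distance-angle correlation maps with wall-following reference
    curves, speed and turning-speed distributions with group-size trends,
    and a statistical comparison battery over per-trial metrics. Includes a
    data-driven two-dimensional active-Brownian-particle swimmer model with
    soft wall repulsion, wall-alignment torque and short-range avoidance
    torque, integrated with an Euler-Maruyama scheme, plus deterministic and
    stochastic trajectory generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
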