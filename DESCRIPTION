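Package: pendupush
Title: Rigid-Body Pendulum Model of Plyometric Push-Up Flight Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the flight phase of a plyometric (ballistic) push-up as a
    planar rigid-body pendulum pivoting about the ankle axis. Derives the
    pendulum geometry (initial angle, hand arc radius, torque-equivalent
    length) from four field-obtainable anthropometric measurements, computes
    flight time by singularity-regularized Gauss-Kronrod quadrature of the
    pendulum period integral with an independent ODE event-detection
    cross-check, inverts measured flight times to pendulum-consistent
    take-off velocities by bracketed root-finding, and evaluates hand- and
    center-of-mass-referenced performance indices (angular amplitude, arc
    displacement, maximum height, quarter-period push-off time, mean
    mechanical power). Parameter-sweep engines quantify the systematic
    divergence between the pendulum model and the conventional free-fall
    point-mass model over the anthropometrically admissible space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
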