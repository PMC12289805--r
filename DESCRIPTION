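Package: pclattice
Title: Predictive-Coding Lattice Dynamics: Bistable Fronts, Pinning and
    Propagation Thresholds
Version: 0.1.0
Authors@R:
    person("Pierre", "Cassou", email = "pierre.cassou@example.org",
           role = c("aut", "cre"))
Description: Continuous-time nonlinear dynamics of hierarchical cortical
    networks coupled by predictive-coding feedback, reduced to a scalar
    bistable lattice differential equation. Computes the stationary
    homogeneous branches (down, middle, up states), fold points and the
    linear stability spectrum; simulates truncated bi-infinite and
    semi-infinite lattices with an adaptive Runge-Kutta integrator;
    estimates bistable traveling-front speeds and detects propagation
    failure (pinning); and locates input-driven propagation thresholds
    (minimal constant amplitude, minimal flash duration) and pinning
    boundaries in both bottom-up and top-down orientations, together with
    sign maps and regime maps over parameter grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
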