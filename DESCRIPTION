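Package: vesiclegrowth
Title: Nonequilibrium Monte Carlo Simulation and Stochastic Thermodynamics of Growing Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grand-canonical Metropolis Monte Carlo simulation of dynamically
    triangulated, quasispherical vesicles that exchange surface particles,
    enclosed volume and heat with external reservoirs, together with the
    downstream analyses used to characterise driven membrane growth:
    spherical-harmonic shape-fluctuation spectroscopy with pressurized
    elastic-shell fits (renormalized tension, Young's modulus and bending
    rigidity), zero- and finite-temperature buckling thresholds with an
    elastothermal-number scaling function, and a stochastic-thermodynamics
    layer providing flux statistics, thermodynamic-uncertainty-relation
    entropy bounds, driving-force inference and a low-dimensional growth law.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    minpack.lm,
    pracma,
    jsonlite,
    tools,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
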