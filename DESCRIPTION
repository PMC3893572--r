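Package: lfpsim
Title: Forward Modeling of Extracellular Potentials from Multicompartment
    Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-step biophysical forward modeling of extracellular potentials
    around morphologically detailed neurons. A passive multicompartment cable
    solver yields per-compartment transmembrane currents, and a volume-conductor
    forward model maps those currents to extracellular potentials at arbitrary
    electrode geometries using the point-source, line-source and
    soma-as-sphere approximations, with finite-size contact averaging, a
    precomputed coefficient-matrix runtime scheme, and population summation
    with controlled input correlation from a shared Poisson spike-train pool.
    Includes SWC morphology reading, d_lambda compartmentalization, an
    independent analytic oracle for the sinusoidally driven passive stick, and
    a YAML-driven command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
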