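Package: lemsim
Title: Interpreter and Simulator for LEMS Declarative Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reads, validates and simulates models written in LEMS (Low
    Entropy Model Specification), a declarative XML language for hybrid
    dynamical systems used in computational neuroscience. Provides
    dimensional analysis with automatic unit conversion to SI, a C-like
    expression grammar with dimension inference, component-type
    inheritance and hierarchical containment with scoped value access,
    discrete events with delays and weights, multi-regime dynamics and
    kinetic schemes, and fixed-step simulation by forward Euler on the
    instance tree or 4th-order Runge-Kutta on a flattened system.
    Ships a library of runnable example models (passive and
    Hodgkin-Huxley channels, adaptive exponential integrate-and-fire
    cells, a blocking plastic synapse, kinetic gates and small spiking
    networks) and a command-line tool for validation and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
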