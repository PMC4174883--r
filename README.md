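# lemsim

An R interpreter and simulator for **LEMS** (Low Entropy Model
Specification), the declarative XML language used in computational
neuroscience to describe hybrid dynamical models — ion channels,
synapses, spiking neurons and the networks they form — in a fully
machine-readable way.

LEMS models separate *form* from *values*: a `ComponentType` declares a
parameterized family (dimensional parameters, exposed and required
quantities, containment slots, event ports, and dynamics as first-order
ODEs plus discrete events, regimes and kinetic schemes), while a
`Component` instantiates one member by supplying each parameter as a
number with a unit. Physical dimensions are primitives of the language:
every dimension is a 7-tuple of integer exponents over the SI base
dimensions (M, L, T, I, Θ, N, J), every unit maps a symbol to a
dimension with a power of ten (plus optional scale/offset), and every
equation is checked for dimensional consistency before anything runs.
For a membrane obeying

    C dv/dt = Σᵢ iᵢ + i_inj,        i_channel = g·(E − v),

the checker verifies, e.g., that `g·(E − v)` carries the dimension of
current and that each `d/dt` expression carries `dim(state)/time`,
using exact integer exponent arithmetic.

For whom: modelers who want to validate, run and probe LEMS/NeuroML-style
model documents from R or a shell, and tool authors who need a reference
implementation with a transparent, testable semantics.

What the package provides:

* **units** — dimensions, units, SI quantities (`parse_quantity("‑65 mV")`),
  dimension algebra;
* **expressions** — the C-like grammar with Fortran relationals
  (`v .gt. theta .and. t .geq. tNext`), evaluation, and dimension
  inference;
* **documents** — reading/writing LEMS XML with `<Include>` resolution
  (`parse_lems()`, `serialize_lems()`, `document_report()`);
* **semantics** — component-type inheritance resolution, component
  validation, full dimension checking (`resolve_type()`,
  `check_component()`, `check_dynamics()`, `validate_lems()`);
* **runtime & engine** — instance trees with population instantiation,
  hierarchical scoping, event connections with delays/weights and
  per-connection synapse attachment; simulation by forward Euler on the
  tree or 4th-order Runge–Kutta on a flattened, code-generated system
  (`build_instance_tree()`, `flatten()`, `simulate_lems()`,
  `write_traces()`);
* **component library** — seven runnable example models
  (`fixture_catalog()`) and a seeded random-network generator
  (`generate_random_network()`);
* **CLI** — `exec/lemsr` with `validate`, `run` and `info` commands.

## Worked example

Simulate the bundled Hodgkin–Huxley cell (classic squid-axon Na/K/leak
conductances, 10 µA step current from 50 ms):

```r
library(lemsim)

doc <- parse_fixture("hh_cell")
validate_lems(doc)          # character(0)  — dimensionally clean

tr <- simulate_lems(doc)    # RK4 on the flattened system
tr
#> <lems_traces> 6001 samples (dt = 2e-05 s), 5 records, 4 events

spikes <- subset(tr$events, port == "spike")
sprintf("%d spikes; first at %.2f ms", nrow(spikes), 1000 * spikes$time[1])
#> "4 spikes; first at 51.92 ms"

range(tr$records$v) * 1000  # mV: rest near -65, spikes overshoot +40
#> -75.18  40.26
```

The cell is silent until the stimulus arrives, then fires repetitively;
gating variables `m`, `h`, `n` are recorded alongside `v` and stay in
[0, 1]. The same document runs from the shell:

```sh
exec/lemsr run --fixture hh_cell -o out/    # traces + events + metadata
exec/lemsr validate --fixture adex_cell    # "0 issues", exit 0
exec/lemsr info --fixture hh_cell          # counts and type lineages
```

Quantities and checking are first-class:

```r
parse_quantity("-65 mV", doc$units)
#> <quantity> -0.065 [voltage] (SI)
infer_dimension(parse_expression("g * (v - E)"),
                list(g = doc$dimensions$conductance,
                     v = doc$dimensions$voltage,
                     E = doc$dimensions$voltage))
#> <dimension> i: i     (current)
```

See `vignettes/lemsim-methods.Rmd` for the full account of the
semantics, the numerical scheme and the rationale behind the bundled
model parameterizations.

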