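---
title: "Model semantics and numerical methods in lemsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model semantics and numerical methods in lemsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lemsim)
```

## The modeling language

lemsim interprets LEMS (Low Entropy Model Specification) documents:
declarative XML descriptions of hybrid dynamical systems built from two
separated layers. A *ComponentType* declares the form of a family of
models — parameters with physical dimensions, quantities it exposes or
requires from its surroundings, the child components it may contain,
event ports, and a *Dynamics* block with state variables, first-order
time derivatives, derived variables, discrete event handlers, regimes
and kinetic schemes. A *Component* picks one member of the family by
binding every parameter to a number-plus-unit pair and nesting concrete
children. The executable model is a tree of component instances; a
population directive can stamp out many instances sharing one component
definition, each with independent state.

Dimensional bookkeeping is the load-bearing feature. A dimension is a
tuple of integer exponents over the seven SI base dimensions in the
fixed order (mass, length, time, current, temperature, amount, luminous
intensity); equality is exponent-wise and ignores names. A unit binds a
symbol to a dimension with a power of ten plus optional scale and
offset; parsing `"-65 mV"` yields the SI magnitude `-0.065` tagged
`voltage`. All runtime arithmetic is in SI; units exist only at the
document boundary.

### Expression grammar

Expressions follow C arithmetic with Fortran-spelled relationals
(`.lt.`, `.gt.`, `.leq.`, `.geq.`, `.eq.`, `.neq.`; the `.le.`, `.ge.`,
`.ne.` aliases are accepted on input and canonicalized on output).
Precedence, loosest to tightest: `.or.`, `.and.`, relationals, `+ -`,
`* /`, unary minus, `^` (right-associative). Built-ins: `exp`, `log`,
`ln` (both natural), `sqrt`, trigonometric and hyperbolic functions,
`abs`, `ceil`, `floor`, `random`, and a Heaviside `H` with `H(0) = 0.5`.
Boolean values never escape conditions: a relational result inside
arithmetic is a parse-time error, which keeps the dimension algebra
total.

Three choices here were genuinely open and are worth recording:

* **The literal `0` is dimension-polymorphic.** Every other literal is
  dimensionless, so `v / vScale` must cancel before entering `exp`. But
  state resets such as `tsince = 0` or comparisons against zero would
  otherwise require a dedicated zero constant per dimension. A bare `0`
  therefore unifies with any dimension during checking.
* **The exponential-linear rate form is guarded.** The classic gating
  form `x / (1 - exp(-x))` has a removable singularity at `x = 0`. The
  parser recognizes the pattern structurally (either `exp(-x)` or
  `exp(0 - x)` spelling, matched against a structurally identical
  numerator) and evaluates the two-term Taylor expansion `1 + x/2` for
  `|x| < 1e-7`. The guarded form is continuous and monotone across the
  grid the tests sweep.
* **`random(x)` draws uniformly from `[0, x)`** using R's seeded
  generator; the seed is a run parameter recorded in the output
  metadata, so stochastic models are exactly reproducible.

### Dimension checking

`infer_dimension()` propagates exponent tuples through an expression:
`+`/`-` and relationals demand equal operand dimensions, `*`/`/` add or
subtract exponents, `^` demands an integer literal exponent when the
base is dimensional, and transcendental functions demand dimensionless
arguments. `check_dynamics()` applies this to a resolved type: the
expression for d`X`/d`t` must carry `dim(X)/time`, derived variables and
assignment right-hand sides must match their declarations, and
conditions must compare like dimensions. All violations are collected
rather than stopping at the first; any violation blocks simulation. The
test suite cross-checks inference against a numeric homogeneity oracle:
scaling every symbol by base-dimension factors must scale the value by
the factors implied by the inferred exponents.

### Inheritance and containment

Types form an inheritance hierarchy: an extending type inherits every
member of its base and may add members or override an inherited derived
variable, time derivative or regime of the same name; parameters and
exposures may not change dimension. A component satisfies a child-slot
declaration if its type extends the slot's declared type, which is what
lets one gate type accept any of the three standard rate forms as its
forward or reverse transition rate. One nuance: exposures name
*published* quantities and live in their own namespace — the idiomatic
`StateVariable name="v" exposure="v"` pairing is legal, while parameter,
state, derived, requirement and text names share a single value
namespace in which collisions after the inheritance merge are errors.

Containment drives scoping. A requirement is satisfied by the nearest
ancestor exposing a quantity of that name (a local symbol shadows any
ancestor exposure by construction), so a rate inside a gate inside a
channel on a cell reads that cell's membrane potential and cannot reach
any other cell's. Requirements are matched by exposure name; if several
same-named candidates existed at different depths, nearest wins.

## Building and running models

`build_instance_tree()` instantiates the target depth-first, then
executes `Structure` directives: `MultiInstantiate` creates
`size` sibling instances named `componentId[k]`, and `EventConnection`
wires an out-port to an in-port with optional delay and weight,
instantiating a receiver synapse into the target's attachment slot
(named `slot[k]` in creation order) when one is declared. State starts
at zero; `OnStart` assignments run parent-first in document order (so a
gate's steady-state initialization sees the cell's already-assigned
potential); kinetic-scheme occupancies default to the first declared
state when nothing else sets them; finally the initial regime — exactly
one regime must carry the `initial` flag — is entered and its `OnEntry`
applied.

Two evaluation routes exist and are held equivalent by tests:

* the **tree walk**, which evaluates expressions by traversing the
  instance hierarchy and re-resolving requirements on every read, and
  integrates with forward Euler;
* the **flattened system**, in which every scoped quantity is renamed
  with its instance path, requirements are bound to their resolved
  ancestor slots once, derived variables are topologically ordered
  (cycles rejected with the cycle listed), and the whole derivative
  computation is generated as a single R function over a flat state
  vector. The flattened route integrates with forward Euler or
  4th-order Runge-Kutta and is the default (`method = "rk4"`).

### The hybrid step

Each fixed step of size `dt` proceeds in this order: (1) ODE update of
the states governed by the currently active regime (RK4 evaluates
derived variables and requirements at each internal stage; events and
conditions are handled only at step boundaries); (2) delivery of all
events due at or before the new boundary, drained to a fixpoint so that
zero-delay relays — for example a synapse forwarding a spike to its
plasticity child — are handled within the same step, with the
connection's weight bound to the reserved symbol `weight` inside the
handler; (3) `OnCondition` tests, edge-triggered on a false-to-true
transition relative to the previous step (a condition already true at
initialization fires once at `t = 0`; entering a regime re-arms its
conditions), with handlers run in document order; (4) a second event
drain for emissions from condition handlers; (5) recomputation of
derived variables and recording. Assignments within one handler apply
sequentially, each seeing its predecessors.

Kinetic schemes contribute mean-field occupancy ODEs
(d occupancy/dt = inflows − outflows over the scheme's edges, with each
edge's forward and reverse rates read from its exposures). After every
step occupancies are clipped to `[0, 1]` and renormalized to sum to 1,
guarding fixed-step drift; conservation holds to 1e-9 over entire runs
in the tests. Stochastic trajectory sampling of schemes is out of
scope.

Events are delivered at the first step boundary at or after their due
time (sub-step event localization is out of scope); delays default to
0 and weights to 1. A non-finite state after an update aborts the run
naming the offending variable path.

## The bundled models

The catalog is chosen so that every language feature above is exercised
by at least one runnable document; all documents enter parameters in
mV/ms-friendly units to exercise conversion while traces are SI.

* `passive_channel` — an ohmic channel (`I = g (v − E)`) on a passive
  compartment; relaxation matches the closed-form exponential with
  time constant `C/g = 20 ms`.
* `hh_cell` — the classic squid-axon Na/K/leak conductances with the
  three standard rate forms; parameters follow the standard modern
  −65 mV convention at nominal 1 cm² (C = 1 µF, ḡNa = 120 mS,
  ḡK = 36 mS, ḡleak = 0.3 mS, ENa = 50 mV, EK = −77 mV,
  Eleak = −54.387 mV). A 10 µA step at 50 ms elicits repetitive
  spiking; with no input the cell settles to rest.
* `adex_cell` — an adaptive exponential integrate-and-fire cell in the
  standard reference parameterization (C = 281 pF, gL = 30 nS,
  EL = −70.6 mV, VT = −50.4 mV, ΔT = 2 mV, τw = 144 ms, a = 4 nS,
  b = 80.5 pA), two regimes (integrating, refractory) with the reset
  and adaptation increment in the refractory `OnEntry`. The spike
  cutoff is −40.4 mV — crossing detection is what matters, and a low
  cutoff keeps the exponential term benign at any fixed step — and the
  refractory period is 5 ms, so inter-spike intervals are bounded below
  by it exactly.
* `blocking_plastic_synapse` — a conductance synapse with a
  voltage/concentration-dependent block factor
  `1 / (1 + ([B]/Ks) e^(−v/Vs))` (Ks = 1.9 mM, Vs = 16.13 mV) and a
  two-variable depression/facilitation mechanism. On each spike the
  facilitation variable updates first (`U += U0 (1 − U)`), then
  depression (`R *= 1 − U`); the parent synapse reads the efficacy
  `R·U` for the current spike *before* relaying it to the child, i.e.
  use-then-update. Several update conventions circulate for this model
  family; this one is fixed here and asserted by tests.
* `two_state_kinetic_gate` — closed ⇌ open with constant rates
  α = 100/s, β = 400/s; the simulated steady state equals α/(α+β).
* `small_network` — a three-cell mutually inhibitory ring (a pacemaker
  population and two followers) built from the AdEx cell and the
  blocking/plastic synapse, with fast (1 ms, weight 1) and slow (2 ms,
  weight 0.5) inhibitory connections. Its checks are property-based:
  it must validate, run, conserve invariants and route events;
  sustained alternating activity is not asserted, since the cell and
  synapse models are deliberately simpler than a full conductance-based
  pacemaker network.
* `exp_decay` — `dx/dt = −x/τ`, the linear system used for integrator
  convergence measurements.

`generate_random_network(n, p, ...)` emits one population of `n` AdEx
cells with Bernoulli(p) directed connections (no self-connections),
delays and weights drawn uniformly from the given ranges under a local
seed that leaves the caller's RNG untouched. It emulates the scale and
wiring style of event-driven network models; it does not emulate
spatial structure, conduction-distance-dependent delays, cell-intrinsic
heterogeneity or graded transmission, so passing tests say nothing
about those features of real networks.

## Numerical choices and problem sizes

Convergence order is measured on `exp_decay` over `t ∈ [0, 1] s` at
`dt ∈ {0.1, 0.05, 0.025, 0.0125} s` as the slope of log2(global error)
against log2(dt): ≈ 4 for RK4, ≈ 1 for Euler, with the finest grid still
far above double-precision noise. Flattened-versus-tree equivalence is
asserted at 1e-9 relative on short runs of every fixture (8–80 ms at
the fixture's natural step); default fixture runs use steps between
0.01 and 0.05 ms, sizes chosen as the coarsest grids that keep the
stiffest fixture (the spiking Hodgkin–Huxley cell) well resolved under
RK4. The Hodgkin–Huxley resting check settles for 500 ms and requires
|dv/dt| < 1e-6 V/s at the end.

## Known limitations

Variable-step and implicit solvers, sub-step event localization,
stochastic kinetic schemes, spatially extended (multi-compartment)
cells, graded synapses and export to other simulator formats are out of
scope. XML Schema validation is not performed — documents are checked
semantically, not against a schema — and element order is
unconstrained beyond containment. Offset (affine) units are accepted
only for direct parameter assignment, never inside compound unit
definitions or expressions.
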