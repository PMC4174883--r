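test_that("inheritance resolution merges members along the lineage", {
  doc <- fixture_doc("hh_cell")
  rt <- resolve_type("ionChannelHH", doc)
  expect_identical(rt$lineage, c("ionChannelHH", "baseIonChannel"))
  # requirement v and exposure g inherited from the base channel type
  expect_true("v" %in% names(rt$requirements))
  expect_true("g" %in% names(rt$exposures))

  # the three rate forms are usable wherever the base rate is declared
  gate <- resolve_type("gateHHrates", doc)
  expect_identical(gate$children_slots$forwardRate$type,
                   "baseVoltageDepRate")
  for (tn in c("expRate", "sigmoidRate", "expLinearRate")) {
    expect_true(lemsim:::is_subtype(tn, "baseVoltageDepRate", doc))
  }
  expect_false(lemsim:::is_subtype("baseVoltageDepRate", "expRate", doc))

  # resolution is idempotent and independent of declaration order
  rt2 <- resolve_type("ionChannelHH", doc)
  expect_identical(rt, rt2)
  doc_rev <- doc
  doc_rev$types <- rev(doc_rev$types)
  rt3 <- resolve_type("ionChannelHH", doc_rev)
  expect_identical(rt$parameters, rt3$parameters)
  expect_identical(rt$lineage, rt3$lineage)
})

test_that("extension cycles and conflicting redeclarations are errors", {
  doc <- parse_lems('<Lems>
    <ComponentType name="selfish" extends="selfish"/>
    <ComponentType name="a" extends="b"/>
    <ComponentType name="b" extends="a"/>
    <Dimension name="voltage" m="1" l="2" t="-3" i="-1"/>
    <Dimension name="time" t="1"/>
    <ComponentType name="base"><Parameter name="p" dimension="voltage"/></ComponentType>
    <ComponentType name="bad" extends="base"><Parameter name="p" dimension="time"/></ComponentType>
    <ComponentType name="ok" extends="base"><Parameter name="p" dimension="voltage"/></ComponentType>
  </Lems>')
  expect_error(resolve_type("selfish", doc), "cyclic extension")
  expect_error(resolve_type("a", doc), "cyclic extension")
  expect_error(resolve_type("bad", doc), "conflicting dimension")
  expect_silent(resolve_type("ok", doc))
})

test_that("component checking converts parameters to SI and enforces dims",
{
  doc <- fixture_doc("passive_channel")
  cell <- check_component(doc$components$pasCell, doc)
  expect_equal(cell$params$C, 1e-9)
  chan <- cell$children$channels[[1]]
  expect_equal(chan$params$g, 5e-8)     # 50 nS
  expect_equal(chan$params$E, -0.065)   # -65 mV

  bad <- set_component_attr(doc, "leak", "E", "-65 ms")
  expect_error(check_component(bad$components$pasCell, bad),
               "parameter 'E' has dimension 'time' but 'voltage'")

  missing <- doc
  missing$components$pasCell$attrs <-
    missing$components$pasCell$attrs[
      names(missing$components$pasCell$attrs) != "v0"]
  expect_error(check_component(missing$components$pasCell, missing),
               "missing parameter.*'v0'")

  unknown <- set_component_attr(doc, "pasCell", "bogus", "1")
  expect_error(check_component(unknown$components$pasCell, unknown),
               "unknown attribute 'bogus'")
})

test_that("child slots enforce arity and type compatibility", {
  doc <- fixture_doc("hh_cell")
  # removing the forwardRate child of the m gate breaks the one-and-only-
  # one contract
  raw <- doc$components$hhcell
  drop_fwd <- function(comp) {
    comp$children <- lapply(comp$children, drop_fwd)
    comp$children <- Filter(function(ch) {
      !(ch$tag == "forwardRate" && grepl("^m", ch$id))
    }, comp$children)
    comp
  }
  mutated <- drop_fwd(raw)
  expect_error(check_component(mutated, doc),
               "requires exactly one")
  # a channel is not a valid gate child
  doc2 <- parse_lems(get_fixture("hh_cell"),
                     include_dirs = dirname(fixture_path("hh_cell")))
  expect_silent(check_component(doc2$components$hhcell, doc2))
})

test_that("dynamics dimension checking accepts V/s balances and flags others",
{
  hdr <- '<Dimension name="voltage" m="1" l="2" t="-3" i="-1"/>
    <Dimension name="current" i="1"/>
    <Dimension name="capacitance" m="-1" l="-2" t="4" i="2"/>
    <Dimension name="conductance" m="-1" l="-2" t="3" i="2"/>'
  ok <- parse_lems(paste0('<Lems>', hdr, '
    <ComponentType name="cell">
      <Parameter name="C" dimension="capacitance"/>
      <Parameter name="I" dimension="current"/>
      <Dynamics>
        <StateVariable name="v" dimension="voltage"/>
        <TimeDerivative variable="v" value="I / C"/>
      </Dynamics>
    </ComponentType></Lems>'))
  expect_length(check_dynamics(resolve_type("cell", ok), ok), 0L)

  bad <- parse_lems(paste0('<Lems>', hdr, '
    <ComponentType name="cell">
      <Parameter name="g" dimension="conductance"/>
      <Dynamics>
        <StateVariable name="v" dimension="voltage"/>
        <TimeDerivative variable="v" value="g * v"/>
      </Dynamics>
    </ComponentType></Lems>'))
  report <- check_dynamics(resolve_type("cell", bad), bad)
  expect_length(report, 1L)
  expect_match(report, "dv/dt")

  none <- parse_lems('<Lems><ComponentType name="still"/></Lems>')
  expect_length(check_dynamics(resolve_type("still", none), none), 0L)
})

test_that("every fixture type checks dimensionally clean", {
  for (nm in fixture_catalog()) {
    doc <- fixture_doc(nm)
    for (tn in names(doc$types)) {
      expect_length(check_dynamics(resolve_type(tn, doc), doc), 0L)
    }
    expect_length(validate_lems(doc), 0L)
  }
})

test_that("regime declarations require exactly one initial regime", {
  doc <- parse_lems('<Lems>
    <Dimension name="time" t="1"/>
    <ComponentType name="flip">
      <Parameter name="tau" dimension="time"/>
      <Dynamics>
        <StateVariable name="x" dimension="none"/>
        <Regime name="up"><TimeDerivative variable="x" value="1/tau"/></Regime>
        <Regime name="down"><TimeDerivative variable="x" value="-1/tau"/></Regime>
      </Dynamics>
    </ComponentType></Lems>')
  expect_error(resolve_type("flip", doc), "exactly one regime")
})
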