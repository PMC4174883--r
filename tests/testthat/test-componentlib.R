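test_that("every catalog entry parses, validates and simulates", {
  expect_setequal(fixture_catalog(),
                  c("passive_channel", "hh_cell", "adex_cell",
                    "blocking_plastic_synapse", "two_state_kinetic_gate",
                    "small_network", "exp_decay"))
  for (nm in fixture_catalog()) {
    xml <- get_fixture(nm)
    expect_match(xml, "<Lems>", fixed = TRUE)
    expect_match(xml, "<Simulation", fixed = TRUE)
    doc <- fixture_doc(nm)
    expect_length(validate_lems(doc), 0L)
    tr <- simulate_lems(doc, length = "2 ms", validate = FALSE)
    expect_true(all(is.finite(unlist(tr$records))))
  }
  expect_error(get_fixture("nope"), "unknown fixture.*passive_channel")
})

test_that("hh gating uses the three standard rate forms", {
  doc <- fixture_doc("hh_cell")
  hh <- doc$components$hhcell
  rate_types <- unlist(lapply(hh$children, function(chan) {
    lapply(chan$children, function(gate) {
      vapply(gate$children, function(r) r$attrs[["type"]], character(1))
    })
  }))
  expect_setequal(unique(rate_types),
                  c("expLinearRate", "expRate", "sigmoidRate"))
})

test_that("the hh cell rests without input and spikes only after the step current", {
  doc <- fixture_doc("hh_cell")
  silent <- set_component_attr(doc, "stim", "amplitude", "0 uA")
  tr <- simulate_lems(silent, dt = "0.05 ms", length = "500 ms")
  n <- length(tr$time)
  dvdt <- abs(tr$records$v[n] - tr$records$v[n - 1]) / tr$meta$dt
  expect_lt(dvdt, 1e-6)                     # V/s at the end of the settle
  expect_equal(sum(tr$events$port == "spike"), 0L)

  driven <- simulate_lems(doc)              # 10 uA step at 50 ms
  spikes <- driven$events$time[driven$events$port == "spike"]
  expect_gt(length(spikes), 0L)
  expect_true(all(spikes > 0.05))
})

test_that("the synaptic block factor is monotone in potential and concentration", {
  base <- get_fixture("blocking_plastic_synapse")
  block_at <- function(v_mV, conc_mM) {
    doc <- parse_lems(base, include_dirs = dirname(fixture_path("hh_cell")))
    doc <- set_component_attr(doc, "post", "vHold", paste(v_mV, "mV"))
    doc <- set_component_attr(doc, "nmdaSyn_blockMechanism_0",
                              "blockConcentration", paste(conc_mM, "mM"))
    tr <- simulate_lems(doc, length = 0, validate = FALSE,
                        records = "post/synapses[0]/blockMechanism/blockFactor")
    tr$records[[1]][1]
  }
  vs <- seq(-80, 40, by = 20)
  for (conc in c(0.5, 2)) {
    curve <- vapply(vs, block_at, numeric(1), conc_mM = conc)
    expect_true(all(diff(curve) > 0),
                label = paste("monotone in v at", conc, "mM"))
    expect_true(all(curve > 0 & curve < 1))
  }
  for (v in c(-60, 0)) {
    curve <- vapply(c(0.5, 1, 2, 4), function(c0) block_at(v, c0),
                    numeric(1))
    expect_true(all(diff(curve) < 0),
                label = paste("decreasing in concentration at", v, "mV"))
  }
})

test_that("short-term plasticity depresses and facilitates across a train", {
  doc <- fixture_doc("blocking_plastic_synapse")
  tr <- simulate_lems(doc)
  R <- tr$records$R
  U <- tr$records$U
  expect_lt(R[length(R)], 1)       # depression accumulated
  expect_gt(max(U), 0.5)           # facilitation above baseline
  expect_true(all(R >= 0 & R <= 1))
  expect_true(all(U >= 0 & U <= 1))
})

test_that("random networks are seeded, bounded and honor p", {
  count_conns <- function(xml) {
    doc <- parse_lems(xml, include_dirs = dirname(fixture_path("hh_cell")))
    sum(vapply(doc$components$net$children,
               function(c) c$type == "explicitConnection", logical(1)))
  }
  expect_equal(count_conns(generate_random_network(10, 0, seed = 1)), 0L)
  expect_equal(count_conns(generate_random_network(10, 1, seed = 1)), 90L)
  x1 <- generate_random_network(50, 0.2, seed = 7)
  x2 <- generate_random_network(50, 0.2, seed = 7)
  expect_identical(x1, x2)
  x3 <- generate_random_network(50, 0.2, seed = 8)
  expect_false(identical(x1, x3))
  expect_error(generate_random_network(10, 1.2), "probability")
  expect_error(generate_random_network(0, 0.5), "positive integer")
  # generation does not disturb the caller's RNG stream
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(generate_random_network(5, 0.5, seed = 99))
  expect_identical(stats::runif(1), before)
})

test_that("small network routes inhibition between populations", {
  doc <- fixture_doc("small_network")
  tr <- simulate_lems(doc, length = "150 ms")
  spikes <- tr$events[tr$events$port == "spike", ]
  expect_gt(nrow(spikes), 0L)
  expect_true("ring/abpd/pacemaker[0]" %in% spikes$path)
  # inhibitory synapses must actually carry charge: followers fire less
  # than they would without inhibition
  per_cell <- table(spikes$path)
  expect_gte(per_cell[["ring/abpd/pacemaker[0]"]],
             max(per_cell) - per_cell[["ring/abpd/pacemaker[0]"]])
})
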