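decay_doc <- function() fixture_doc("exp_decay")

convergence_order <- function(method, dts = c(0.1, 0.05, 0.025, 0.0125)) {
  doc <- decay_doc()
  errs <- vapply(dts, function(dt) {
    tr <- simulate_lems(doc, method = method, dt = dt, length = 1)
    abs(tr$records$x[length(tr$records$x)] - exp(-1))
  }, numeric(1))
  stats::coef(stats::lm(log2(errs) ~ log2(dts)))[[2]]
}

test_that("a single Euler step matches the scheme definition", {
  doc <- decay_doc()
  dt <- 0.01
  tr <- simulate_lems(doc, method = "euler", dt = dt, length = dt)
  # dv/dt = -v/tau, one step: v' = v (1 - dt/tau), tau = 1 s, v0 = 1
  expect_equal(tr$records$x[2], 1 * (1 - dt / 1), tolerance = 1e-14)
})

test_that("empirical convergence orders are 1 (Euler) and 4 (RK4)", {
  expect_equal(convergence_order("euler"), 1, tolerance = 0.2)
  expect_equal(convergence_order("rk4"), 4, tolerance = 0.05)
})

test_that("flattening reproduces tree-walk trajectories on the fixtures", {
  runs <- list(
    passive_channel = list(length = "10 ms", dt = "0.02 ms"),
    exp_decay = list(length = "1 s", dt = "0.01 s"),
    two_state_kinetic_gate = list(length = "20 ms", dt = "0.02 ms"),
    adex_cell = list(length = "80 ms", dt = "0.05 ms"),
    blocking_plastic_synapse = list(length = "50 ms", dt = "0.05 ms"),
    hh_cell = list(length = "8 ms", dt = "0.02 ms")
  )
  for (nm in names(runs)) {
    doc <- fixture_doc(nm)
    a <- simulate_lems(doc, method = "euler", dt = runs[[nm]]$dt,
                       length = runs[[nm]]$length)
    b <- simulate_lems(doc, method = "euler-tree", dt = runs[[nm]]$dt,
                       length = runs[[nm]]$length)
    for (rec in names(a$records)) {
      denom <- pmax(abs(a$records[[rec]]), 1e-12)
      expect_lt(max(abs(a$records[[rec]] - b$records[[rec]]) / denom),
                1e-9, label = paste(nm, rec, "flat vs tree"))
    }
    expect_identical(a$events, b$events)
  }
})

test_that("the passive membrane relaxes with the analytic exponential", {
  doc <- fixture_doc("passive_channel")
  # tau = C/g = 20 ms; run one time constant at dt = tau/1000
  tau <- 0.02
  tr <- simulate_lems(doc, method = "euler", dt = tau / 1000, length = tau)
  vT <- tr$records$v[length(tr$records$v)]
  expected <- -0.065 + 0.01 * exp(-1)
  expect_lt(abs(vT - expected) / abs(expected - -0.065), 1e-3)
})

test_that("kinetic occupancies hit the analytic fixed point and stay conserved", {
  doc <- fixture_doc("two_state_kinetic_gate")
  tr <- simulate_lems(doc)
  open <- tr$records$open
  closed <- tr$records$closed
  # alpha/(alpha+beta) = 100/500
  expect_lt(abs(open[length(open)] - 0.2), 1e-6)
  expect_lt(max(abs(open + closed - 1)), 1e-9)
  expect_true(all(open >= 0 & open <= 1))
})

test_that("regime dynamics: refractory hold, reset, and exact ISI floor", {
  doc <- fixture_doc("adex_cell")
  tr <- simulate_lems(doc)
  spikes <- tr$events$time[tr$events$port == "spike"]
  expect_gt(length(spikes), 2L)
  expect_true(all(spikes > 0.05))         # before the stimulus: silence
  refract <- 0.005
  expect_true(all(diff(spikes) >= refract))
  # membrane potential is clamped at the reset value through the
  # refractory window following each spike
  for (ts in spikes[1:2]) {
    idx <- which(tr$time > ts & tr$time < ts + refract - 1e-9)
    expect_true(all(abs(tr$records$v[idx] - -0.0706) < 1e-12))
  }
  # no threshold crossings are emitted during refractory windows
  for (k in seq_along(spikes)[-1]) {
    expect_gte(spikes[k] - spikes[k - 1], refract)
  }
})

test_that("deterministic reruns produce byte-identical trace files", {
  doc <- parse_random_network(4, 0.5, seed = 9, length_ms = 40)
  with_tmpdir(function(dir) {
    d1 <- file.path(dir, "r1")
    d2 <- file.path(dir, "r2")
    f1 <- write_traces(simulate_lems(doc, seed = 3), d1)
    f2 <- write_traces(simulate_lems(doc, seed = 3), d2)
    for (k in seq_along(f1)) {
      expect_identical(readBin(f1[k], "raw", file.size(f1[k])),
                       readBin(f2[k], "raw", file.size(f2[k])),
                       label = paste("bytes of", basename(f1[k])))
    }
  })
})

test_that("trace files have the declared shape, including zero-length runs", {
  doc <- fixture_doc("exp_decay")
  with_tmpdir(function(dir) {
    tr <- simulate_lems(doc, dt = 0.001, length = 1)
    files <- write_traces(tr, dir)
    dat <- read.delim(files[1])
    expect_equal(nrow(dat), 1001L)
    expect_equal(ncol(dat), 2L)
    expect_identical(names(dat)[1], "time")

    tr0 <- simulate_lems(doc, dt = 0.001, length = 0)
    f0 <- write_traces(tr0, file.path(dir, "zero"))
    dat0 <- read.delim(f0[1])
    expect_equal(nrow(dat0), 1L)
    expect_equal(dat0$time, 0)
  })
})

test_that("a diverging state aborts with the offending variable path", {
  doc <- parse_lems('<Lems>
    <Dimension name="time" t="1"/>
    <Unit symbol="s" dimension="time" power="0"/>
    <Target component="boom1"/>
    <ComponentType name="boom">
      <Parameter name="tau" dimension="time"/>
      <Dynamics>
        <StateVariable name="x" dimension="none"/>
        <TimeDerivative variable="x" value="x * x / tau"/>
        <OnStart><StateAssignment variable="x" value="1e154"/></OnStart>
      </Dynamics>
    </ComponentType>
    <boom id="boom1" tau="1 s"/>
  </Lems>')
  expect_error(simulate_lems(doc, dt = 1, length = 5, records = "x"),
               "non-finite state.*boom1/x")
})

test_that("derived-variable cycles are rejected at flatten time", {
  doc <- parse_lems('<Lems>
    <Target component="loop1"/>
    <ComponentType name="loopy">
      <Dynamics>
        <StateVariable name="x" dimension="none"/>
        <DerivedVariable name="a" dimension="none" value="b + x"/>
        <DerivedVariable name="b" dimension="none" value="a + 1"/>
      </Dynamics>
    </ComponentType>
    <loopy id="loop1"/>
  </Lems>')
  root <- build_instance_tree(doc)
  expect_error(flatten(root, doc), "cycle among derived variables")
})
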