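# Bundled example models and a seeded synthetic-network generator.

FIXTURE_NAMES <- c("passive_channel", "hh_cell", "adex_cell",
                   "blocking_plastic_synapse", "two_state_kinetic_gate",
                   "small_network", "exp_decay")

fixture_dir <- function() {
  system.file("extdata", "fixtures", package = "lemsim", mustWork = TRUE)
}

#' Names of the bundled example models
#' @return Character vector of fixture names usable with [get_fixture()]
#'   and the CLI's `--fixture` flag.
#' @export
fixture_catalog <- function() FIXTURE_NAMES

#' Path to a bundled example model
#' @param name One of [fixture_catalog()].
#' @return Path to the fixture's XML file.
#' @export
fixture_path <- function(name) {
  if (!name %in% FIXTURE_NAMES) {
    stop("unknown fixture '", name, "'; available: ",
         paste(FIXTURE_NAMES, collapse = ", "), call. = FALSE)
  }
  file.path(fixture_dir(), paste0(name, ".xml"))
}

#' Full XML text of a bundled example model
#'
#' Each fixture is a complete, runnable LEMS document including a
#' Simulation element. The catalog collectively exercises parameters,
#' derived parameters and variables, requirements, child/children slots,
#' component references, attachments, event ports, regimes, kinetic
#' schemes, population instantiation and event connections with delays
#' and weights.
#'
#' @param name One of [fixture_catalog()].
#' @return A single string of LEMS XML.
#' @export
get_fixture <- function(name) {
  paste(readLines(fixture_path(name), warn = FALSE), collapse = "\n")
}

#' Parse a bundled example model
#' @param name One of [fixture_catalog()].
#' @return A `lems_document`.
#' @export
parse_fixture <- function(name) {
  parse_lems(fixture_path(name))
}

#' Override an attribute on a component of a parsed document
#'
#' Convenience for programmatic experiments on the bundled models (e.g.
#' setting a stimulus amplitude to zero). The component is located by id
#' anywhere in the top-level component trees.
#'
#' @param doc A `lems_document`.
#' @param id Component id.
#' @param attr Attribute name.
#' @param value New attribute value (a string, e.g. `"0 nA"`).
#' @return The modified document.
#' @export
set_component_attr <- function(doc, id, attr, value) {
  found <- FALSE
  patch <- function(comp) {
    if (identical(comp$id, id)) {
      comp$attrs[[attr]] <- value
      found <<- TRUE
    }
    comp$children <- lapply(comp$children, patch)
    comp
  }
  doc$components <- lapply(doc$components, patch)
  if (!found) stop("no component with id '", id, "' in document",
                   call. = FALSE)
  doc
}

#' Generate a random spiking network as a LEMS document (seeded)
#'
#' Builds one population of `n_cells` adaptive exponential
#' integrate-and-fire cells with Bernoulli(p) directed connections (no
#' self-connections), each realized as an event connection attaching a
#' fixed synapse component with delay and weight drawn uniformly from the
#' given ranges. Identical arguments (including the seed) give
#' byte-identical documents.
#'
#' @param n_cells Positive integer number of cells.
#' @param p Connection probability in \[0, 1\].
#' @param delay_range Length-2 numeric, delay range in milliseconds.
#' @param weight_range Length-2 numeric, dimensionless weight range.
#' @param seed Integer seed.
#' @param length_ms,step_ms Simulation length and step, milliseconds.
#' @return A single string of LEMS XML (parse with [parse_lems()]).
#' @export
generate_random_network <- function(n_cells, p, delay_range = c(1, 5),
                                    weight_range = c(0.5, 1.5), seed = 1,
                                    length_ms = 100, step_ms = 0.05) {
  if (n_cells < 1 || n_cells != round(n_cells)) {
    stop("n_cells must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("connection probability must lie in [0, 1]", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fmt <- function(x) sprintf("%.6f", x)
  conns <- character()
  k <- 0L
  for (src in seq_len(n_cells) - 1L) {
    for (dst in seq_len(n_cells) - 1L) {
      if (src == dst) next
      if (stats::runif(1) >= p) next
      delay <- stats::runif(1, delay_range[1], delay_range[2])
      weight <- stats::runif(1, weight_range[1], weight_range[2])
      conns <- c(conns, paste0(
        '    <explicitConnection id="c', k,
        '" from="pop/netCell[', src, ']" to="pop/netCell[', dst,
        ']" synapse="netSyn" delay="', fmt(delay), ' ms" weight="',
        fmt(weight), '"/>'))
      k <- k + 1L
    }
  }
  paste0(
    '<Lems>\n',
    '  <!-- synthetic random network: n=', n_cells, ', p=', p,
    ', seed=', seed, ' -->\n',
    '  <Include file="lems_core_types.xml"/>\n',
    '  <Target component="sim1"/>\n\n',
    '  <adExIaFCell id="netCell" C="281 pF" gL="30 nS" EL="-70.6 mV"\n',
    '               VT="-50.4 mV" delT="2 mV" Vr="-70.6 mV"\n',
    '               vPeak="-40.4 mV" a="4 nS" b="80.5 pA" tauw="144 ms"\n',
    '               refract="5 ms">\n',
    '    <pulseGenerator id="drive" delay="5 ms" duration="',
    fmt(max(length_ms - 10, 10)), ' ms" amplitude="0.7 nA"/>\n',
    '  </adExIaFCell>\n\n',
    '  <blockingPlasticSynapse id="netSyn" gbase="3 nS" erev="-80 mV"\n',
    '                          tauDecay="10 ms">\n',
    '    <blockMechanism type="voltageConcDepBlockMechanism"\n',
    '                    blockConcentration="0 mM" scalingConc="1.9 mM"\n',
    '                    scalingVolt="16.13 mV"/>\n',
    '    <plasticityMechanism type="tsodyksMarkramDepFacMechanism"\n',
    '                         initReleaseProb="0.5" tauRec="120 ms"\n',
    '                         tauFac="10 ms"/>\n',
    '  </blockingPlasticSynapse>\n\n',
    '  <network id="net">\n',
    '    <population id="pop" size="', n_cells, '" component="netCell"/>\n',
    if (length(conns)) paste0(paste(conns, collapse = "\n"), "\n") else "",
    '  </network>\n\n',
    '  <Simulation id="sim1" length="', fmt(length_ms), ' ms" step="',
    fmt(step_ms), ' ms" target="net">\n',
    '    <OutputFile id="of1" fileName="random_network.dat">\n',
    '      <OutputColumn id="v0" quantity="pop/netCell[0]/v"/>\n',
    '    </OutputFile>\n',
    '    <EventOutputFile id="ev1" fileName="random_network.events"/>\n',
    '  </Simulation>\n',
    '</Lems>\n')
}

#' Parse a random network generated by [generate_random_network()]
#' @param ... Passed to [generate_random_network()].
#' @return A `lems_document`.
#' @export
parse_random_network <- function(...) {
  parse_lems(generate_random_network(...), include_dirs = fixture_dir())
}
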