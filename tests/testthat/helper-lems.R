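# Shared helpers: an inline unit registry, dimension-consistent random
# expression generation, and a numeric homogeneity oracle for the
# dimension checker.

mini_units_xml <- '<Lems>
  <Dimension name="voltage" m="1" l="2" t="-3" i="-1"/>
  <Dimension name="time" t="1"/>
  <Dimension name="length" l="1"/>
  <Dimension name="area" l="2"/>
  <Dimension name="temperature" k="1"/>
  <Dimension name="conductance" m="-1" l="-2" t="3" i="2"/>
  <Dimension name="current" i="1"/>
  <Unit symbol="mV" dimension="voltage" power="-3"/>
  <Unit symbol="V" dimension="voltage" power="0"/>
  <Unit symbol="ms" dimension="time" power="-3"/>
  <Unit symbol="s" dimension="time" power="0"/>
  <Unit symbol="mS" dimension="conductance" power="-3"/>
  <Unit symbol="nS" dimension="conductance" power="-9"/>
  <Unit symbol="A" dimension="current" power="0"/>
  <Unit symbol="degF" dimension="temperature" power="0"
        scale="0.5555555555555556" offset="255.37222222222223"/>
</Lems>'

mini_doc <- function() parse_lems(mini_units_xml)
mini_units <- function() mini_doc()$units

dim_voltage <- function() lems_dimension("voltage", 1, 2, -3, -1)
dim_conductance <- function() lems_dimension("conductance", -1, -2, 3, 2)
dim_current <- function() lems_dimension("current", i = 1)
dim_time <- function() lems_dimension("time", t = 1)
dim_capacitance <- function() lems_dimension("capacitance", -1, -2, 4, 2)

random_dimension <- function() {
  do.call(lems_dimension,
          c(list(name = "rand"),
            as.list(sample(-2:2, 7, replace = TRUE))))
}

# Generate a dimension-consistent random expression over fresh symbols.
# Returns list(text, dims = named list of lems_dimension, dim = result).
random_homogeneous_expr <- function(depth = 3) {
  counter <- 0L
  dims <- list()
  gen <- function(dim, d) {
    if (d <= 0 || stats::runif(1) < 0.25) {
      if (all(dim$exponents == 0L) && stats::runif(1) < 0.3) {
        return(format(stats::runif(1, 0.5, 2)))
      }
      counter <<- counter + 1L
      nm <- paste0("s", counter)
      dims[[nm]] <<- dim
      return(nm)
    }
    op <- sample(c("add", "sub", "mul", "div", "neg"), 1)
    if (op %in% c("add", "sub")) {
      paste0("(", gen(dim, d - 1L), if (op == "add") " + " else " - ",
             gen(dim, d - 1L), ")")
    } else if (op == "neg") {
      paste0("(-", gen(dim, d - 1L), ")")
    } else {
      other <- random_dimension()
      if (op == "mul") {
        paste0("(", gen(other, d - 1L), " * ",
               gen(dim_combine(dim, other, "divide"), d - 1L), ")")
      } else {
        paste0("(", gen(dim_combine(dim, other, "multiply"), d - 1L),
               " / ", gen(other, d - 1L), ")")
      }
    }
  }
  out_dim <- random_dimension()
  text <- gen(out_dim, depth)
  list(text = text, dims = dims, dim = out_dim)
}

# Numeric homogeneity oracle: scale each symbol by the base-dimension
# factors raised to its exponents; a dimensionally homogeneous expression
# of inferred dimension D must scale by the same rule.
homogeneity_check <- function(text, dims, inferred) {
  ast <- parse_expression(text)
  base_vals <- stats::setNames(stats::runif(length(dims), 0.5, 2),
                               names(dims))
  factors <- stats::runif(7, 0.5, 2)
  scale_for <- function(exponents) prod(factors^exponents)
  scaled_vals <- vapply(names(dims), function(nm) {
    base_vals[[nm]] * scale_for(dims[[nm]]$exponents)
  }, numeric(1))
  v1 <- eval_expression(ast, base_vals)
  v2 <- eval_expression(ast, scaled_vals)
  expected <- v1 * scale_for(inferred$exponents)
  abs(v2 - expected) <= 1e-8 * max(abs(v2), abs(expected), 1)
}

with_tmpdir <- function(fn) {
  dir <- tempfile("lemsim")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  fn(dir)
}

fixture_doc <- function(name) parse_fixture(name)
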