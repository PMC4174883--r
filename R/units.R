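# Dimensional quantities: 7-exponent SI dimensions, units with power-of-ten
# (plus optional scale/offset) conversion, and quantity parsing/formatting.

#' Names of the seven SI base dimensions, in canonical order
#'
#' The canonical order is (mass, length, time, current, temperature,
#' amount, luminous intensity), abbreviated `m, l, t, i, k, n, j` as in
#' LEMS `Dimension` attributes. All dimension arithmetic and equality in
#' the package is exponent-tuple based in this fixed order.
#'
#' @return Character vector of length 7.
#' @export
lems_base_dimensions <- function() {
  c("m", "l", "t", "i", "k", "n", "j")
}

#' Create a dimension
#'
#' A dimension associates a name with integer powers of the seven SI base
#' dimensions. Two dimensions are equal iff all seven exponents are equal;
#' the name plays no role in equality.
#'
#' @param name Identifier for the dimension.
#' @param m,l,t,i,k,n,j Integer exponents of mass, length, time, current,
#'   temperature, amount and luminous intensity.
#' @return An object of class `lems_dimension`.
#' @examples
#' voltage <- lems_dimension("voltage", m = 1, l = 2, t = -3, i = -1)
#' @export
lems_dimension <- function(name, m = 0, l = 0, t = 0, i = 0, k = 0, n = 0,
                           j = 0) {
  exps <- c(m = m, l = l, t = t, i = i, k = k, n = n, j = j)
  if (any(exps != round(exps))) {
    stop("dimension '", name, "': exponents must be integers", call. = FALSE)
  }
  exps <- as.integer(round(exps))
  names(exps) <- lems_base_dimensions()
  structure(list(name = as.character(name), exponents = exps),
            class = "lems_dimension")
}

#' The dimensionless dimension (all exponents zero)
#' @return A `lems_dimension` with every exponent zero.
#' @export
dimensionless <- function() lems_dimension("none")

#' @export
print.lems_dimension <- function(x, ...) {
  e <- x$exponents
  parts <- paste0(names(e)[e != 0], ifelse(e[e != 0] == 1, "",
                                           paste0("^", e[e != 0])))
  cat("<dimension> ", x$name, ": ",
      if (length(parts)) paste(parts, collapse = " ") else "1", "\n", sep = "")
  invisible(x)
}

#' Test dimension equality by exponents
#'
#' @param a,b `lems_dimension` objects.
#' @return Logical scalar.
#' @export
dim_equal <- function(a, b) {
  all(a$exponents == b$exponents)
}

is_dimensionless <- function(a) all(a$exponents == 0L)

synth_dim_name <- function(exps) {
  nz <- exps[exps != 0L]
  if (!length(nz)) return("none")
  paste0(names(nz), ifelse(nz == 1L, "", nz), collapse = "_")
}

#' Combine two dimensions by multiplication or division
#'
#' Exponent-wise sum (multiply) or difference (divide). The name of the
#' result is synthesized from the exponents; equality is by exponents only.
#'
#' @param a,b `lems_dimension` objects.
#' @param op `"multiply"` or `"divide"`.
#' @return A `lems_dimension`.
#' @examples
#' S <- lems_dimension("conductance", m = -1, l = -2, t = 3, i = 2)
#' V <- lems_dimension("voltage", m = 1, l = 2, t = -3, i = -1)
#' dim_combine(S, V, "multiply") # current
#' @export
dim_combine <- function(a, b, op = c("multiply", "divide")) {
  op <- match.arg(op)
  exps <- if (op == "multiply") a$exponents + b$exponents else
    a$exponents - b$exponents
  structure(list(name = synth_dim_name(exps), exponents = exps),
            class = "lems_dimension")
}

#' Raise a dimension to an integer power
#'
#' @param a A `lems_dimension`.
#' @param k Integer exponent (non-integers are rejected).
#' @return A `lems_dimension` with every exponent multiplied by `k`.
#' @export
dim_power <- function(a, k) {
  if (length(k) != 1L || !is.numeric(k) || is.na(k) || k != round(k)) {
    stop("dim_power: exponent must be a single integer, got ",
         deparse(k), call. = FALSE)
  }
  exps <- a$exponents * as.integer(round(k))
  structure(list(name = synth_dim_name(exps), exponents = exps),
            class = "lems_dimension")
}

#' Create a unit
#'
#' A unit binds a symbol to a dimension together with a power of ten and an
#' optional scale and offset. Conversion to SI is
#' `si = value * scale * 10^power10 + offset`. Units with a non-zero offset
#' (affine units such as Fahrenheit) may only be used for direct parameter
#' assignment, never inside compound unit definitions or expressions.
#'
#' @param symbol Unit symbol; case-sensitive (`"mV"` differs from `"MV"`).
#' @param dimension A `lems_dimension`.
#' @param power10 Integer power of ten.
#' @param scale Multiplicative scale (default 1).
#' @param offset Additive offset in SI units (default 0).
#' @return An object of class `lems_unit`.
#' @export
lems_unit <- function(symbol, dimension, power10 = 0, scale = 1, offset = 0) {
  stopifnot(inherits(dimension, "lems_dimension"))
  if (power10 != round(power10)) {
    stop("unit '", symbol, "': power10 must be an integer", call. = FALSE)
  }
  structure(list(symbol = as.character(symbol), dimension = dimension,
                 power10 = as.integer(round(power10)),
                 scale = as.numeric(scale), offset = as.numeric(offset)),
            class = "lems_unit")
}

#' @export
print.lems_unit <- function(x, ...) {
  cat("<unit> ", x$symbol, " = 10^", x$power10,
      if (x$scale != 1) paste0(" * ", x$scale) else "",
      if (x$offset != 0) paste0(" + ", x$offset) else "",
      " [", x$dimension$name, "]\n", sep = "")
  invisible(x)
}

#' Create a quantity (magnitude stored in SI)
#'
#' @param magnitude Numeric magnitude in SI units.
#' @param dimension A `lems_dimension`.
#' @return An object of class `lems_quantity`.
#' @export
lems_quantity <- function(magnitude, dimension) {
  if (!is.finite(magnitude)) {
    stop("quantity magnitude must be finite", call. = FALSE)
  }
  structure(list(magnitude = as.numeric(magnitude), dimension = dimension),
            class = "lems_quantity")
}

#' @export
print.lems_quantity <- function(x, ...) {
  cat("<quantity> ", format(x$magnitude), " [", x$dimension$name, "] (SI)\n",
      sep = "")
  invisible(x)
}

to_si <- function(value, unit) {
  value * unit$scale * 10^unit$power10 + unit$offset
}

from_si <- function(si, unit) {
  (si - unit$offset) / (unit$scale * 10^unit$power10)
}

quantity_num_re <- "[+-]?(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?"

#' Parse a quantity string such as "-65 mV" into an SI quantity
#'
#' The text must be `<number><optional whitespace><unit symbol>` or a bare
#' number (bare numbers are dimensionless). Conversion applies the unit's
#' scale, power of ten and offset.
#'
#' @param text Quantity string.
#' @param units Named list of `lems_unit` objects keyed by symbol (a unit
#'   registry, e.g. `doc$units` from [parse_lems()]).
#' @return A `lems_quantity` with magnitude in SI.
#' @examples
#' mV <- lems_unit("mV", lems_dimension("voltage", 1, 2, -3, -1), -3)
#' parse_quantity("-65 mV", list(mV = mV))$magnitude # -0.065
#' @export
parse_quantity <- function(text, units = list()) {
  txt <- trimws(text)
  m <- regmatches(txt, regexec(
    paste0("^(", quantity_num_re, ")\\s*([A-Za-z_][A-Za-z0-9_]*)?$"),
    txt))[[1]]
  if (!length(m)) {
    stop("malformed quantity: '", text, "'", call. = FALSE)
  }
  num <- suppressWarnings(as.numeric(m[2]))
  if (is.na(num)) stop("malformed number in quantity: '", text, "'",
                       call. = FALSE)
  sym <- m[3]
  if (is.na(sym) || sym == "") {
    return(lems_quantity(num, dimensionless()))
  }
  unit <- units[[sym]]
  if (is.null(unit)) {
    stop("unknown unit symbol '", sym, "' in quantity '", text, "'",
         call. = FALSE)
  }
  lems_quantity(to_si(num, unit), unit$dimension)
}

#' Format a quantity in a given unit
#'
#' Inverse of [parse_quantity()]: the round trip
#' `parse_quantity(format_quantity(q, u))` recovers the SI magnitude
#' (to floating-point tolerance for offset-free units).
#'
#' @param q A `lems_quantity`.
#' @param unit A `lems_unit` whose dimension equals `q`'s, or `NULL` for a
#'   dimensionless quantity.
#' @return A string such as `"1 mS"`.
#' @export
format_quantity <- function(q, unit = NULL) {
  if (is.null(unit)) {
    if (!is_dimensionless(q$dimension)) {
      stop("format_quantity: a unit is required for dimensional quantities",
           call. = FALSE)
    }
    return(format_num(q$magnitude))
  }
  if (!dim_equal(q$dimension, unit$dimension)) {
    stop("format_quantity: dimension mismatch (", q$dimension$name, " vs ",
         unit$dimension$name, ")", call. = FALSE)
  }
  paste0(format_num(from_si(q$magnitude, unit)), " ", unit$symbol)
}

format_num <- function(x) {
  s <- sprintf("%.17g", x)
  # prefer the shortest representation that round-trips
  for (digits in 1:16) {
    cand <- sprintf("%.*g", digits, x)
    if (as.numeric(cand) == x) return(cand)
  }
  s
}
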