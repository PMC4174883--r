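# The C-like expression grammar used inside Dynamics elements: parsing,
# evaluation, dimension inference and serialization. Relational operators
# use Fortran-style spellings (.lt., .gt., ...) to stay XML-friendly.

LEMS_FUNCTIONS <- c("exp", "log", "ln", "sqrt", "sin", "cos", "tan",
                    "sinh", "cosh", "tanh", "abs", "ceil", "floor",
                    "random", "H")

REL_OPS <- c(".lt.", ".gt.", ".leq.", ".geq.", ".eq.", ".neq.")
REL_ALIASES <- c(".le." = ".leq.", ".ge." = ".geq.", ".ne." = ".neq.")

# ---- tokenizer ----------------------------------------------------------

tokenize_expr <- function(text) {
  tokens <- list()
  i <- 1L
  nch <- nchar(text)
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           pos = pos)
  }
  while (i <= nch) {
    rest <- substr(text, i, nch)
    if (grepl("^\\s", rest)) {
      i <- i + attr(regexpr("^\\s+", rest), "match.length")
      next
    }
    m <- regexpr("^\\.(lt|gt|leq|geq|eq|neq|le|ge|ne|and|or)\\.", rest)
    if (m == 1L) {
      op <- substr(rest, 1L, attr(m, "match.length"))
      if (op %in% names(REL_ALIASES)) op <- REL_ALIASES[[op]]
      push(if (op %in% c(".and.", ".or.")) "logic" else "rel", op, i)
      i <- i + attr(m, "match.length")
      next
    }
    m <- regexpr("^(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?", rest)
    if (m == 1L) {
      num <- substr(rest, 1L, attr(m, "match.length"))
      push("num", as.numeric(num), i)
      i <- i + attr(m, "match.length")
      next
    }
    m <- regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest)
    if (m == 1L) {
      push("name", substr(rest, 1L, attr(m, "match.length")), i)
      i <- i + attr(m, "match.length")
      next
    }
    ch <- substr(rest, 1L, 1L)
    if (ch %in% c("+", "-", "*", "/", "^", "(", ")", ",")) {
      push(ch, ch, i)
      i <- i + 1L
      next
    }
    stop("expression syntax error at position ", i, ": unexpected '", ch,
         "' in \"", text, "\"", call. = FALSE)
  }
  tokens
}

# ---- parser -------------------------------------------------------------
# Precedence (loosest to tightest):
#   .or. < .and. < relational < + - < * / < unary minus < ^ (right-assoc)

ast_num <- function(value) list(kind = "num", value = value)
ast_sym <- function(name) list(kind = "sym", name = name)
ast_neg <- function(arg) list(kind = "neg", arg = arg)
ast_bin <- function(op, lhs, rhs) list(kind = "bin", op = op, lhs = lhs,
                                       rhs = rhs)
ast_rel <- function(op, lhs, rhs) list(kind = "rel", op = op, lhs = lhs,
                                       rhs = rhs)
ast_logic <- function(op, lhs, rhs) list(kind = "logic", op = op, lhs = lhs,
                                         rhs = rhs)
ast_call <- function(fn, args) list(kind = "call", fn = fn, args = args)

is_boolean_ast <- function(ast) ast$kind %in% c("rel", "logic")

require_numeric_ast <- function(ast, where) {
  if (is_boolean_ast(ast)) {
    stop("expression syntax error: boolean sub-expression used inside ",
         where, " (relational results may only appear in conditions)",
         call. = FALSE)
  }
  ast
}

#' Parse a LEMS mathematical expression
#'
#' The grammar follows C conventions for arithmetic with Fortran-style
#' relational spellings: `^` (right-associative) binds tighter than unary
#' minus, then `*` `/`, then `+` `-`, then the relationals `.lt. .gt. .leq.
#' .geq. .eq. .neq.` (aliases `.le.`/`.ge.`/`.ne.` are accepted on input),
#' then `.and.`, then `.or.`. Known functions: exp, log, ln, sqrt, sin,
#' cos, tan, sinh, cosh, tanh, abs, ceil, floor, random, H.
#'
#' Boolean-valued sub-expressions are only legal where a condition is
#' expected; using one inside arithmetic is a parse-time error. The
#' removable singularity of the exponential-linear form
#' `x / (1 - exp(0 - x))` is recognised structurally and evaluated by its
#' two-term Taylor expansion `1 + x/2` for `|x| < 1e-7`.
#'
#' @param text Expression string.
#' @return An expression AST (nested lists; see details in the package
#'   vignette).
#' @examples
#' ast <- parse_expression("g * (v - E)")
#' expr_symbols(ast)
#' @export
parse_expression <- function(text) {
  if (!nzchar(trimws(text))) stop("empty expression", call. = FALSE)
  tokens <- tokenize_expr(text)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() {
    tk <- peek()
    pos <<- pos + 1L
    tk
  }
  expect <- function(type) {
    tk <- peek()
    if (is.null(tk) || tk$type != type) {
      stop("expression syntax error at ",
           if (is.null(tk)) "end of input" else paste0("position ", tk$pos),
           ": expected '", type, "' in \"", text, "\"", call. = FALSE)
    }
    advance()
  }

  parse_or <- function() {
    lhs <- parse_and()
    while (!is.null(peek()) && peek()$type == "logic" &&
           peek()$value == ".or.") {
      advance()
      lhs <- ast_logic(".or.", lhs, parse_and())
    }
    lhs
  }
  parse_and <- function() {
    lhs <- parse_rel()
    while (!is.null(peek()) && peek()$type == "logic" &&
           peek()$value == ".and.") {
      advance()
      lhs <- ast_logic(".and.", lhs, parse_rel())
    }
    lhs
  }
  parse_rel <- function() {
    lhs <- parse_sum()
    if (!is.null(peek()) && peek()$type == "rel") {
      op <- advance()$value
      rhs <- parse_sum()
      return(ast_rel(op, require_numeric_ast(lhs, "a relational operand"),
                     require_numeric_ast(rhs, "a relational operand")))
    }
    lhs
  }
  parse_sum <- function() {
    lhs <- parse_term()
    while (!is.null(peek()) && peek()$type %in% c("+", "-")) {
      op <- advance()$type
      rhs <- parse_term()
      lhs <- ast_bin(op, require_numeric_ast(lhs, "arithmetic"),
                     require_numeric_ast(rhs, "arithmetic"))
    }
    lhs
  }
  parse_term <- function() {
    lhs <- parse_unary()
    while (!is.null(peek()) && peek()$type %in% c("*", "/")) {
      op <- advance()$type
      rhs <- parse_unary()
      lhs <- ast_bin(op, require_numeric_ast(lhs, "arithmetic"),
                     require_numeric_ast(rhs, "arithmetic"))
    }
    lhs
  }
  parse_unary <- function() {
    tk <- peek()
    if (!is.null(tk) && tk$type == "-") {
      advance()
      return(ast_neg(require_numeric_ast(parse_unary(), "unary minus")))
    }
    if (!is.null(tk) && tk$type == "+") {
      advance()
      return(parse_unary())
    }
    parse_power()
  }
  parse_power <- function() {
    base <- parse_atom()
    if (!is.null(peek()) && peek()$type == "^") {
      advance()
      # right-associative; exponent may itself be signed
      expo <- parse_unary()
      return(ast_bin("^", require_numeric_ast(base, "arithmetic"),
                     require_numeric_ast(expo, "arithmetic")))
    }
    base
  }
  parse_atom <- function() {
    tk <- peek()
    if (is.null(tk)) {
      stop("expression syntax error: unexpected end of \"", text, "\"",
           call. = FALSE)
    }
    if (tk$type == "num") {
      advance()
      return(ast_num(tk$value))
    }
    if (tk$type == "name") {
      advance()
      if (!is.null(peek()) && peek()$type == "(") {
        if (!(tk$value %in% LEMS_FUNCTIONS)) {
          stop("unknown function '", tk$value, "' at position ", tk$pos,
               " in \"", text, "\"", call. = FALSE)
        }
        advance()
        args <- list()
        if (!is.null(peek()) && peek()$type != ")") {
          repeat {
            args[[length(args) + 1L]] <-
              require_numeric_ast(parse_or(), "a function argument")
            if (!is.null(peek()) && peek()$type == ",") advance() else break
          }
        }
        expect(")")
        return(ast_call(tk$value, args))
      }
      return(ast_sym(tk$value))
    }
    if (tk$type == "(") {
      advance()
      inner <- parse_or()
      expect(")")
      return(inner)
    }
    stop("expression syntax error at position ", tk$pos, ": unexpected '",
         tk$value, "' in \"", text, "\"", call. = FALSE)
  }

  ast <- parse_or()
  if (!is.null(peek())) {
    tk <- peek()
    stop("expression syntax error at position ", tk$pos,
         ": trailing input '", tk$value, "' in \"", text, "\"",
         call. = FALSE)
  }
  normalize_ast(ast)
}

# Structural equality of ASTs (used for the singularity guard).
ast_equal <- function(a, b) {
  if (a$kind != b$kind) return(FALSE)
  switch(a$kind,
    num = isTRUE(a$value == b$value),
    sym = a$name == b$name,
    neg = ast_equal(a$arg, b$arg),
    bin = a$op == b$op && ast_equal(a$lhs, b$lhs) && ast_equal(a$rhs, b$rhs),
    rel = a$op == b$op && ast_equal(a$lhs, b$lhs) && ast_equal(a$rhs, b$rhs),
    logic = a$op == b$op && ast_equal(a$lhs, b$lhs) &&
      ast_equal(a$rhs, b$rhs),
    call = a$fn == b$fn && length(a$args) == length(b$args) &&
      all(vapply(seq_along(a$args),
                 function(i) ast_equal(a$args[[i]], b$args[[i]]), logical(1))),
    linoid = ast_equal(a$arg, b$arg),
    FALSE)
}

# Is `ast` the negation of `x`, either as unary minus or as (0 - x)?
is_negation_of <- function(ast, x) {
  if (ast$kind == "neg") return(ast_equal(ast$arg, x))
  if (ast$kind == "bin" && ast$op == "-" && ast$lhs$kind == "num" &&
      ast$lhs$value == 0) {
    return(ast_equal(ast$rhs, x))
  }
  FALSE
}

# Recognise x / (1 - exp(-x)) and tag it as a guarded "linoid" node so the
# removable singularity at x = 0 is handled explicitly.
normalize_ast <- function(ast) {
  recurse <- function(a) {
    out <- switch(a$kind,
      num = a,
      sym = a,
      neg = { a$arg <- recurse(a$arg); a },
      bin = { a$lhs <- recurse(a$lhs); a$rhs <- recurse(a$rhs); a },
      rel = { a$lhs <- recurse(a$lhs); a$rhs <- recurse(a$rhs); a },
      logic = { a$lhs <- recurse(a$lhs); a$rhs <- recurse(a$rhs); a },
      call = { a$args <- lapply(a$args, recurse); a },
      linoid = a,
      a)
    if (out$kind == "bin" && out$op == "/" &&
        out$rhs$kind == "bin" && out$rhs$op == "-" &&
        out$rhs$lhs$kind == "num" && out$rhs$lhs$value == 1 &&
        out$rhs$rhs$kind == "call" && out$rhs$rhs$fn == "exp" &&
        length(out$rhs$rhs$args) == 1L &&
        is_negation_of(out$rhs$rhs$args[[1]], out$lhs)) {
      return(list(kind = "linoid", arg = out$lhs))
    }
    out
  }
  recurse(ast)
}

#' Free symbols of an expression AST
#' @param ast An AST from [parse_expression()].
#' @return Character vector of symbol names (sorted, unique).
#' @export
expr_symbols <- function(ast) {
  syms <- character()
  walk <- function(a) {
    switch(a$kind,
      sym = syms[[length(syms) + 1L]] <<- a$name,
      neg = walk(a$arg),
      bin = { walk(a$lhs); walk(a$rhs) },
      rel = { walk(a$lhs); walk(a$rhs) },
      logic = { walk(a$lhs); walk(a$rhs) },
      call = lapply(a$args, walk),
      linoid = walk(a$arg),
      NULL)
    invisible(NULL)
  }
  walk(ast)
  sort(unique(syms))
}

linoid_val <- function(x) {
  # x / (1 - exp(-x)) with its removable singularity guarded by the
  # two-term Taylor expansion 1 + x/2 near 0
  if (abs(x) < 1e-7) 1 + x / 2 else x / (1 - exp(-x))
}

apply_lems_fn <- function(fn, args, where) {
  x <- args[[1]]
  switch(fn,
    exp = exp(x),
    log = { if (x <= 0) stop("domain error: log of non-positive value in ",
                             where, call. = FALSE); log(x) },
    ln = { if (x <= 0) stop("domain error: ln of non-positive value in ",
                            where, call. = FALSE); log(x) },
    sqrt = { if (x < 0) stop("domain error: sqrt of negative value in ",
                             where, call. = FALSE); sqrt(x) },
    sin = sin(x), cos = cos(x), tan = tan(x),
    sinh = sinh(x), cosh = cosh(x), tanh = tanh(x),
    abs = abs(x), ceil = ceiling(x), floor = floor(x),
    H = if (x > 0) 1 else if (x < 0) 0 else 0.5,
    random = stats::runif(1) * x,
    stop("unknown function '", fn, "'", call. = FALSE))
}

#' Evaluate an expression AST
#'
#' Arithmetic nodes yield numerics; relational/logical nodes yield
#' logicals. `random(x)` draws uniformly from `[0, x)` using R's global
#' random stream (seed it with `set.seed()` for reproducibility).
#'
#' @param ast AST from [parse_expression()].
#' @param bindings Named numeric vector or list binding every free symbol
#'   (values in SI).
#' @return Numeric or logical scalar.
#' @examples
#' eval_expression(parse_expression("1/(1 + exp(0 - x))"), c(x = 0)) # 0.5
#' @export
eval_expression <- function(ast, bindings = numeric()) {
  bindings <- as.list(bindings)
  ev <- function(a) {
    switch(a$kind,
      num = a$value,
      sym = {
        v <- bindings[[a$name]]
        if (is.null(v) || length(v) != 1L || is.na(v)) {
          stop("unbound symbol '", a$name, "' in expression", call. = FALSE)
        }
        v
      },
      neg = -ev(a$arg),
      bin = {
        l <- ev(a$lhs)
        r <- ev(a$rhs)
        switch(a$op,
          "+" = l + r, "-" = l - r, "*" = l * r,
          "/" = {
            if (r == 0) stop("domain error: division by zero in '",
                             ast_to_text(a), "'", call. = FALSE)
            l / r
          },
          "^" = l^r)
      },
      rel = {
        l <- ev(a$lhs)
        r <- ev(a$rhs)
        switch(a$op,
          ".lt." = l < r, ".gt." = l > r, ".leq." = l <= r,
          ".geq." = l >= r, ".eq." = l == r, ".neq." = l != r)
      },
      logic = {
        l <- ev(a$lhs)
        r <- ev(a$rhs)
        if (a$op == ".and.") l && r else l || r
      },
      call = apply_lems_fn(a$fn, lapply(a$args, ev),
                           paste0("'", ast_to_text(a), "'")),
      linoid = linoid_val(ev(a$arg)),
      stop("unknown AST node kind '", a$kind, "'", call. = FALSE))
  }
  ev(ast)
}

#' Serialize an AST back to expression text
#'
#' Produces a fully parenthesized form that re-parses to an equivalent AST
#' (round-trip property). Canonical relational spellings are emitted
#' (`.leq.`/`.geq.`, never the `.le.`/`.ge.` aliases).
#'
#' @param ast An expression AST.
#' @return A string.
#' @export
ast_to_text <- function(ast) {
  switch(ast$kind,
    num = format_num(ast$value),
    sym = ast$name,
    neg = paste0("(-", ast_to_text(ast$arg), ")"),
    bin = paste0("(", ast_to_text(ast$lhs), " ", ast$op, " ",
                 ast_to_text(ast$rhs), ")"),
    rel = paste0("(", ast_to_text(ast$lhs), " ", ast$op, " ",
                 ast_to_text(ast$rhs), ")"),
    logic = paste0("(", ast_to_text(ast$lhs), " ", ast$op, " ",
                   ast_to_text(ast$rhs), ")"),
    call = paste0(ast$fn, "(",
                  paste(vapply(ast$args, ast_to_text, character(1)),
                        collapse = ", "), ")"),
    linoid = paste0("(", ast_to_text(ast$arg), " / (1 - exp(0 - ",
                    ast_to_text(ast$arg), ")))"),
    stop("unknown AST node kind '", ast$kind, "'", call. = FALSE))
}

# ---- dimension inference ------------------------------------------------

# The literal 0 is dimension-polymorphic: it unifies with any dimension.
# Represent that internally as NULL; every other literal is dimensionless.

unify_dims <- function(a, b, what, node) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (!dim_equal(a, b)) {
    stop("dimension mismatch in '", ast_to_text(node), "': ", what,
         " requires equal dimensions but got '", a$name, "' vs '",
         b$name, "'", call. = FALSE)
  }
  a
}

#' Infer the dimension of an expression
#'
#' `+` and `-` require equal operand dimensions; `*` and `/` combine
#' exponents; `^` requires an integer literal exponent when the base is
#' dimensional; transcendental functions require and return dimensionless
#' arguments; relational operators require equal operand dimensions and
#' yield a boolean marker. The literal `0` unifies with any dimension.
#'
#' @param ast An expression AST.
#' @param dims Named list mapping every free symbol to a `lems_dimension`.
#' @return A `lems_dimension`, or the string `"boolean"` for
#'   relational/logical expressions.
#' @export
infer_dimension <- function(ast, dims = list()) {
  out <- infer_dimension_raw(ast, dims)
  if (is.null(out)) dimensionless() else out
}

# As infer_dimension, but returns NULL for the dimension-polymorphic
# literal 0 so callers can unify it with any expected dimension.
infer_dimension_raw <- function(ast, dims = list()) {
  inf <- function(a) {
    switch(a$kind,
      num = if (a$value == 0) NULL else dimensionless(),
      sym = {
        d <- dims[[a$name]]
        if (is.null(d)) {
          stop("no declared dimension for symbol '", a$name, "'",
               call. = FALSE)
        }
        d
      },
      neg = inf(a$arg),
      bin = {
        l <- inf(a$lhs)
        r <- inf(a$rhs)
        switch(a$op,
          "+" = unify_dims(l, r, "'+'", a),
          "-" = unify_dims(l, r, "'-'", a),
          "*" = if (is.null(l) || is.null(r)) NULL else
            dim_combine(l, r, "multiply"),
          "/" = if (is.null(l)) NULL else
            dim_combine(l, if (is.null(r)) dimensionless() else r, "divide"),
          "^" = {
            base <- if (is.null(l)) dimensionless() else l
            if (is_dimensionless(base)) {
              rd <- if (is.null(r)) dimensionless() else r
              if (!is_dimensionless(rd)) {
                stop("dimension mismatch in '", ast_to_text(a),
                     "': exponent must be dimensionless, got '", rd$name,
                     "'", call. = FALSE)
              }
              dimensionless()
            } else {
              if (a$rhs$kind != "num" || a$rhs$value != round(a$rhs$value)) {
                stop("dimension error in '", ast_to_text(a),
                     "': a dimensional base requires an integer literal ",
                     "exponent", call. = FALSE)
              }
              dim_power(base, a$rhs$value)
            }
          })
      },
      rel = {
        unify_dims(inf(a$lhs), inf(a$rhs),
                   paste0("'", a$op, "'"), a)
        "boolean"
      },
      logic = {
        for (side in list(a$lhs, a$rhs)) {
          if (!identical(inf(side), "boolean")) {
            stop("'", a$op, "' requires boolean operands in '",
                 ast_to_text(a), "'", call. = FALSE)
          }
        }
        "boolean"
      },
      call = {
        for (arg in a$args) {
          d <- inf(arg)
          if (identical(d, "boolean")) {
            stop("boolean argument to function '", a$fn, "'", call. = FALSE)
          }
          if (!is.null(d) && !is_dimensionless(d)) {
            stop("dimension mismatch in '", ast_to_text(a), "': function '",
                 a$fn, "' requires a dimensionless argument, got '",
                 d$name, "'", call. = FALSE)
          }
        }
        dimensionless()
      },
      linoid = {
        d <- inf(a$arg)
        if (!is.null(d) && !is_dimensionless(d)) {
          stop("dimension mismatch in '", ast_to_text(a),
               "': the exponential-linear form requires a dimensionless ",
               "argument, got '", d$name, "'", call. = FALSE)
        }
        dimensionless()
      },
      stop("unknown AST node kind '", a$kind, "'", call. = FALSE))
  }
  inf(ast)
}

# ---- compilation to R source (used by the flattened engine) -------------

# Render an AST as R source. `symmap` maps symbol names to R source
# fragments (e.g. a state slot "y[3L]" or a precomputed local).
ast_to_rcode <- function(ast, symmap) {
  rc <- function(a) {
    switch(a$kind,
      num = format_num(a$value),
      sym = {
        frag <- symmap[[a$name]]
        if (is.null(frag)) {
          stop("internal: no compilation target for symbol '", a$name, "'",
               call. = FALSE)
        }
        frag
      },
      neg = paste0("(-", rc(a$arg), ")"),
      bin = paste0("(", rc(a$lhs), " ",
                   if (a$op == "^") "^" else a$op, " ", rc(a$rhs), ")"),
      rel = paste0("(", rc(a$lhs), " ",
                   switch(a$op, ".lt." = "<", ".gt." = ">", ".leq." = "<=",
                          ".geq." = ">=", ".eq." = "==", ".neq." = "!="),
                   " ", rc(a$rhs), ")"),
      logic = paste0("(", rc(a$lhs), " ",
                     if (a$op == ".and.") "&&" else "||", " ", rc(a$rhs),
                     ")"),
      call = {
        args <- vapply(a$args, rc, character(1))
        switch(a$fn,
          ln = paste0("log(", args[1], ")"),
          ceil = paste0("ceiling(", args[1], ")"),
          random = paste0("(stats::runif(1) * ", args[1], ")"),
          H = paste0(".lems_H(", args[1], ")"),
          paste0(a$fn, "(", paste(args, collapse = ", "), ")"))
      },
      linoid = paste0(".lems_linoid(", rc(a$arg), ")"),
      stop("unknown AST node kind '", a$kind, "'", call. = FALSE))
  }
  rc(ast)
}

# helpers referenced by generated code
.lems_H <- function(x) if (x > 0) 1 else if (x < 0) 0 else 0.5
.lems_linoid <- function(x) if (abs(x) < 1e-7) 1 + x / 2 else
  x / (1 - exp(-x))
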