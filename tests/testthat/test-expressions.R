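test_that("the grammar honors precedence and Fortran relational forms", {
  ast <- parse_expression("g * (v - E)")
  expect_identical(ast$kind, "bin")
  expect_identical(ast$op, "*")
  expect_identical(expr_symbols(ast), c("E", "g", "v"))

  cond <- parse_expression("v .gt. theta .and. t .geq. tNext")
  expect_identical(cond$kind, "logic")
  expect_identical(cond$op, ".and.")
  expect_identical(cond$lhs$op, ".gt.")
  expect_identical(cond$rhs$op, ".geq.")

  neg <- parse_expression("-x")
  expect_identical(neg$kind, "neg")
  expect_identical(neg$arg$name, "x")

  # ^ right-associative and tighter than unary minus, * over +
  ast2 <- parse_expression("a + b * c ^ d ^ e")
  expect_identical(ast2$op, "+")
  expect_identical(ast2$rhs$op, "*")
  expect_identical(ast2$rhs$rhs$op, "^")
  expect_identical(ast2$rhs$rhs$rhs$op, "^")
  expect_equal(eval_expression(parse_expression("-2^2"), NULL), -4)

  # aliases accepted on input, canonical on output
  ali <- parse_expression("a .le. b .and. c .ge. d")
  expect_identical(ali$lhs$op, ".leq.")
  expect_identical(ali$rhs$op, ".geq.")
  expect_match(ast_to_text(ali), ".leq.", fixed = TRUE)

  expect_error(parse_expression("foo(x)"), "unknown function 'foo'")
  expect_error(parse_expression("a + + "), "syntax error")
  expect_error(parse_expression("(a .gt. b) + 1"), "boolean")
  expect_error(parse_expression("exp(a .and. b)"), "boolean|syntax")
  expect_error(parse_expression(""), "empty")
})

test_that("evaluation covers arithmetic, functions and reported errors", {
  expect_equal(eval_expression(parse_expression("1/(1 + exp(0 - x))"),
                               c(x = 0)), 0.5)
  expect_equal(eval_expression(parse_expression("exp(x)"), c(x = 0)), 1)
  expect_equal(eval_expression(parse_expression("sqrt(abs(x))"),
                               c(x = -9)), 3)
  expect_equal(eval_expression(parse_expression("ceil(x) + floor(x)"),
                               c(x = 1.5)), 3)
  expect_error(eval_expression(parse_expression("log(x)"), c(x = -1)),
               "domain error")
  expect_error(eval_expression(parse_expression("1 / x"), c(x = 0)),
               "division by zero")
  expect_error(eval_expression(parse_expression("a + b"), c(a = 1)),
               "unbound symbol 'b'")
})

test_that("the exponential-linear form is guarded across its singularity", {
  ast <- parse_expression("x / (1 - exp(0 - x))")
  expect_identical(ast$kind, "linoid")
  expect_equal(eval_expression(ast, c(x = 1e-9)), 1, tolerance = 1e-6)
  expect_equal(eval_expression(ast, c(x = 0)), 1)
  # also recognised with unary-minus spelling
  expect_identical(parse_expression("x / (1 - exp(-x))")$kind, "linoid")
  # monotone increasing and continuous over [-10, 10]
  grid <- seq(-10, 10, by = 0.01)
  vals <- vapply(grid, function(x) eval_expression(ast, c(x = x)),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_lt(max(abs(diff(vals))), 0.011)
})

test_that("random(x) draws uniformly from [0, x) with a seedable stream", {
  ast <- parse_expression("random(x)")
  set.seed(5)
  draws <- replicate(200, eval_expression(ast, c(x = 3)))
  expect_true(all(draws >= 0 & draws < 3))
  set.seed(5)
  again <- replicate(200, eval_expression(ast, c(x = 3)))
  expect_identical(draws, again)
})

test_that("serialize -> reparse preserves evaluation (round trip)", {
  exprs <- c("g * (v - E)", "-x^2 + 3*(y - 1)", "x / (1 - exp(0 - x))",
             "exp(a / b) * sinh(c) - tanh(a)", "abs(a - b) / (a + b)",
             "H(a - b) + H(b - a)")
  set.seed(3)
  for (text in exprs) {
    ast <- parse_expression(text)
    bind <- stats::setNames(stats::runif(length(expr_symbols(ast)),
                                         0.5, 2),
                            expr_symbols(ast))
    v1 <- eval_expression(ast, bind)
    v2 <- eval_expression(parse_expression(ast_to_text(ast)), bind)
    expect_equal(v1, v2, tolerance = 1e-15)
  }
})

test_that("dimension inference matches the declared examples", {
  dims <- list(g = dim_conductance(), v = dim_voltage(),
               E = dim_voltage(), vScale = dim_voltage())
  got <- infer_dimension(parse_expression("g * (v - E)"), dims)
  expect_true(dim_equal(got, dim_current()))
  expect_error(infer_dimension(parse_expression("v + g"), dims),
               "dimension mismatch.*voltage.*conductance")
  expect_true(dim_equal(
    infer_dimension(parse_expression("exp(v / vScale)"), dims),
    dimensionless()))
  expect_error(
    infer_dimension(parse_expression("exp(v)"), dims), "dimensionless")
  expect_error(
    infer_dimension(parse_expression("v .gt. g"), dims),
    "dimension mismatch")
  expect_identical(
    infer_dimension(parse_expression("v .gt. E"), dims), "boolean")
  # ^ needs an integer literal exponent for dimensional bases
  expect_true(dim_equal(
    infer_dimension(parse_expression("v^2"), dims),
    dim_power(dim_voltage(), 2)))
  expect_error(infer_dimension(parse_expression("v^x"),
                               c(dims, list(x = dimensionless()))),
               "integer literal")
  # the literal 0 is dimension-polymorphic
  expect_true(dim_equal(infer_dimension(parse_expression("v - 0"), dims),
                        dim_voltage()))
})

test_that("inference agrees with a numeric homogeneity oracle", {
  set.seed(17)
  for (k in 1:40) {
    e <- random_homogeneous_expr(depth = 3)
    if (!length(e$dims)) next
    inferred <- infer_dimension(parse_expression(e$text), e$dims)
    expect_identical(inferred$exponents, e$dim$exponents,
                     label = paste("inferred dim of", e$text))
    expect_true(homogeneity_check(e$text, e$dims, inferred),
                label = paste("homogeneity of", e$text))
  }
})
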