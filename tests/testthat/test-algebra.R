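poly_str <- function(p) format(p)

test_that("the Boolean-polynomial dictionary holds on the base cases", {
  expect_identical(poly_str(expr_to_polynomial("!x")), "x + 1")
  # x | y  <->  x + y + x*y (terms printed leading-first)
  expect_setequal(vapply(expr_to_polynomial("x | y")$monomials,
                         paste, character(1), collapse = "*"),
                  c("x", "y", "x*y"))
  # x & !y = x(y+1) = x*y + x
  p <- expr_to_polynomial("x & !y")
  expect_setequal(vapply(p$monomials, paste, character(1), collapse = "*"),
                  c("x*y", "x"))
  expect_identical(poly_str(expr_to_polynomial("x ^ y")), "x + y")
  expect_identical(poly_str(expr_to_polynomial(b_const(0L), "x")), "0")
})

test_that("polynomials evaluate like the Boolean expressions they encode", {
  eval_poly <- function(p, assign) {
    total <- 0L
    for (m in p$monomials) {
      total <- bitwXor(total, as.integer(all(assign[m] == 1L)))
    }
    total
  }
  set.seed(707)
  vars <- paste0("v", 1:6)
  for (i in 1:150) {
    e <- random_expression(vars, 4L)
    p <- expr_to_polynomial(e, vars)
    net <- boolean_network(vars, c(list(e), lapply(vars[-1L], b_var))
                           |> stats::setNames(vars))
    states <- bnsteady:::all_states_matrix(length(vars))
    want <- as.integer(bnsteady:::eval_states(net, states)[, 1L])
    got <- vapply(seq_len(nrow(states)), function(r) {
      eval_poly(p, stats::setNames(as.integer(states[r, ]), vars))
    }, integer(1))
    expect_identical(got, want)
  }
})

test_that("the fixed-point system encodes h_i + x_i = 0", {
  # negation self-loop: (x+1) + x = 1, an inconsistent equation
  h1 <- andnot_network("x1", list(x1 = list(reg = "x1", sign = -1L)))
  sys1 <- steady_state_system(h1)
  expect_identical(poly_str(sys1$polys[[1L]]), "1")
  expect_identical(length(enumerate_solutions(sys1)), 0L)

  # identity node: x + x = 0
  h2 <- andnot_network("x1", list(x1 = list(reg = "x1", sign = 1L)))
  expect_identical(poly_str(steady_state_system(h2)$polys[[1L]]), "0")

  # two-node negative loop: both equations are x1 + x2 + 1
  h3 <- andnot_network(c("x1", "x2"),
    list(x1 = list(reg = "x2", sign = -1L), x2 = list(reg = "x1", sign = -1L)))
  sys3 <- steady_state_system(h3)
  for (p in sys3$polys) {
    expect_setequal(vapply(p$monomials, paste, character(1), collapse = "*"),
                    c("x1", "x2", ""))
  }
  sol <- enumerate_solutions(sys3)
  expect_true(same_steady_states(sol,
    steady_state_set(rbind(c(0L, 1L), c(1L, 0L)), c("x1", "x2"))))
  expect_true(same_steady_states(sol, enumerate_exhaustive(h3)))
})

test_that("reduced lexicographic bases come out triangular and canonical", {
  sys <- structure(list(
    variables = c("x1", "x2"),
    polys = list(expr_to_polynomial("x1 ^ x2", c("x1", "x2")),
                 expr_to_polynomial("!x2", c("x1", "x2")))),
    class = "gf2_system")
  gb <- groebner_basis(sys, order = c("x1", "x2"))
  expect_setequal(vapply(gb, format, character(1)), c("x1 + 1", "x2 + 1"))

  # inconsistent input stays {1}
  one <- structure(list(variables = "x1",
                        polys = list(expr_to_polynomial(b_const(1L), "x1"))),
                   class = "gf2_system")
  expect_identical(vapply(groebner_basis(one), format, character(1)), "1")

  # a single irreducible linear equation is already a basis
  lin <- structure(list(
    variables = c("x1", "x2"),
    polys = list(expr_to_polynomial("!(x1 ^ x2)", c("x1", "x2")),
                 expr_to_polynomial("!(x1 ^ x2)", c("x1", "x2")))),
    class = "gf2_system")
  gb2 <- groebner_basis(lin, order = c("x1", "x2"))
  expect_identical(vapply(gb2, format, character(1)), "x1 + x2 + 1")
})

test_that("an empty equation set leaves every assignment as a solution", {
  h <- andnot_network(c("a", "b", "c"),
    list(a = list(reg = "a", sign = 1L),
         b = list(reg = "b", sign = 1L),
         c = list(reg = "c", sign = 1L)))
  sol <- enumerate_solutions(steady_state_system(h))
  expect_identical(length(sol), 8L)
})

test_that("the algebra solver matches the exhaustive scan on random AND-NOT networks", {
  set.seed(808)
  for (i in 1:400) {
    h <- random_andnot_network(sample(3:13, 1L))
    sol <- enumerate_solutions(steady_state_system(h))
    expect_true(same_steady_states(sol, enumerate_exhaustive(h)))
  }
})

test_that("the solution set does not depend on the variable ordering", {
  set.seed(909)
  for (i in 1:60) {
    h <- random_andnot_network(sample(3:12, 1L))
    sys <- steady_state_system(h)
    a <- enumerate_solutions(sys, order = sys$variables)
    b <- enumerate_solutions(sys, order = rev(sys$variables))
    expect_true(same_steady_states(a, b))
    # {1} in the reduced basis exactly when there is no solution
    gb <- groebner_basis(sys)
    is_one_basis <- length(gb) == 1L && identical(format(gb[[1L]]), "1")
    expect_identical(is_one_basis, length(a) == 0L)
  }
})

test_that("the solution cap raises a distinct error", {
  h <- andnot_network(paste0("x", 1:12),
    stats::setNames(lapply(paste0("x", 1:12), function(v)
      list(reg = v, sign = 1L)), paste0("x", 1:12)))
  expect_error(enumerate_solutions(steady_state_system(h), max_solutions = 100),
               class = "bnsteady_cap_error")
})
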