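test_that("synchronous evaluation matches hand computation", {
  id3 <- boolean_network(c("a", "b", "c"),
                         list(a = b_var("a"), b = b_var("b"), c = b_var("c")))
  for (x in list(c(0, 0, 0), c(1, 0, 1), c(1, 1, 1))) {
    expect_identical(evaluate_network(id3, x), as.integer(x))
    expect_true(is_steady_state(id3, x))
  }

  neg <- boolean_network("x", list(x = b_not(b_var("x"))))
  expect_identical(evaluate_network(neg, 0), 1L)
  expect_identical(evaluate_network(neg, 1), 0L)
  expect_false(is_steady_state(neg, 0))
  expect_false(is_steady_state(neg, 1))

  f <- boolean_network(c("x1", "x2", "x3"),
    list(x1 = b_and(b_var("x2"), b_var("x3")),
         x2 = b_var("x1"),
         x3 = b_not(b_var("x1"))))
  expect_identical(evaluate_network(f, c(0, 0, 1)), c(0L, 0L, 1L))
  expect_true(is_steady_state(f, c(0, 0, 1)))
  # brute-force over all 8 states: (0,0,1) is the unique fixed point
  ss <- enumerate_exhaustive(f)
  expect_identical(unname(ss$states), matrix(c(0L, 0L, 1L), nrow = 1L))
})

test_that("evaluation validates its inputs", {
  f <- boolean_network("x", list(x = b_var("x")))
  expect_error(evaluate_network(f, c(0, 1)), "does not match")
  expect_error(evaluate_network(f, 2), "0 or 1")
  expect_error(boolean_network("x", list(x = b_var("y"))), "undeclared")
  expect_error(boolean_network(c("x", "y"), list(x = b_var("x"))), "one update")
})

test_that("wiring diagram reads off signed regulators", {
  h <- andnot_network(c("x1", "x2"),
    list(x1 = list(reg = "x2", sign = -1L), x2 = list(reg = "x1", sign = -1L)))
  wd <- wiring_diagram(h)
  expect_identical(wd$edges$from, c("x1", "x2"))
  expect_identical(wd$edges$to, c("x2", "x1"))
  expect_identical(wd$edges$sign, c("-", "-"))

  # fragment x1 = !x2 & !x5, x5 = !x3 & !x4 (others inputs)
  a <- andnot_network(c("x1", "x2", "x3", "x4", "x5"),
    list(x1 = list(reg = c("x2", "x5"), sign = c(-1L, -1L)),
         x2 = list(reg = "x2", sign = 1L),
         x3 = list(reg = "x3", sign = 1L),
         x4 = list(reg = "x4", sign = 1L),
         x5 = list(reg = c("x3", "x4"), sign = c(-1L, -1L))))
  wd <- wiring_diagram(a)
  neg <- wd$edges[wd$edges$sign == "-", ]
  expect_identical(nrow(neg), 4L)
  expect_setequal(paste(neg$from, neg$to), c("x2 x1", "x5 x1", "x3 x5", "x4 x5"))

  const <- andnot_network("x1", list(x1 = list(const = 1L)))
  expect_identical(nrow(wiring_diagram(const)$edges), 0L)
})

test_that("a contradictory conjunction normalizes to constant 0", {
  a <- andnot_network(c("x", "y"),
    list(x = list(reg = c("y", "y"), sign = c(1L, -1L)),
         y = list(reg = "y", sign = 1L)))
  expect_identical(a$funcs$x$const, 0L)
  # duplicate literals merge
  b <- andnot_network(c("x", "y"),
    list(x = list(reg = c("y", "y"), sign = c(1L, 1L)),
         y = list(reg = "y", sign = 1L)))
  expect_identical(b$funcs$x$reg, "y")
})

test_that("edge count equals signed-regulator count on random AND-NOT networks", {
  set.seed(101)
  for (i in 1:50) {
    a <- random_andnot_network(sample(2:10, 1L))
    nreg <- sum(vapply(a$funcs, function(fn)
      if (is.null(fn$const)) length(fn$reg) else 0L, integer(1)))
    expect_identical(nrow(wiring_diagram(a)$edges), nreg)
  }
})

test_that("expression-tree and AND-NOT representations agree on steady states", {
  # the same update rules written as expression trees and as signed
  # conjunctions must give identical fixed-point sets (exhaustive scan)
  set.seed(202)
  for (i in 1:200) {
    m <- sample(2:9, 1L)
    a <- random_andnot_network(m)
    exprs <- lapply(a$funcs, function(fn) {
      if (!is.null(fn$const)) return(b_const(fn$const))
      lits <- lapply(seq_along(fn$reg), function(k) {
        v <- b_var(fn$reg[[k]])
        if (fn$sign[[k]] > 0L) v else b_not(v)
      })
      .b_nary <- bnsteady:::.b_nary
      .b_nary("AND", lits)
    })
    f <- boolean_network(a$variables, exprs)
    expect_true(same_steady_states(enumerate_exhaustive(f), enumerate_exhaustive(a)))
  }
})

test_that("steady-state sets deduplicate and sort deterministically", {
  s <- steady_state_set(rbind(c(1L, 1L), c(0L, 0L), c(1L, 1L)), c("a", "b"))
  expect_identical(nrow(s$states), 2L)
  expect_identical(unname(s$states[1L, ]), c(0L, 0L))
  expect_identical(length(s), 2L)
  empty <- steady_state_set(NULL, c("a", "b"))
  expect_identical(length(empty), 0L)
})
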