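test_that("negation normal form applies De Morgan and removes double negation", {
  e <- to_nnf(b_not(b_and(b_var("x"), b_var("y"))))
  expect_identical(deparse_expression(e), "!x | !y")
  expect_identical(deparse_expression(to_nnf(b_not(b_not(b_var("x"))))), "x")
  e2 <- to_nnf(b_not(b_or(b_var("x2"), b_not(b_var("x3")))))
  expect_identical(deparse_expression(e2), "!x2 & x3")
  # truth-table preservation on random expressions, XOR included
  set.seed(404)
  vars <- paste0("v", 1:5)
  net_of <- function(e) {
    exprs <- c(list(e), lapply(vars[-1L], b_var))
    names(exprs) <- vars
    boolean_network(vars, exprs)
  }
  for (i in 1:100) {
    e <- random_expression(vars, 4L)
    expect_true(same_truth_tables(net_of(e), net_of(to_nnf(e))))
  }
})

test_that("the OR rewrite introduces one auxiliary via De Morgan", {
  # f1 = !x2 & (x3 | x4)  ==>  f1 = !x2 & !a, a = !x3 & !x4
  f <- parse_rules("x1 = !x2 & (x3 | x4)\nx2 = x1\nx3 = x3\nx4 = x4")
  tr <- boolean_to_andnot(f)
  expect_identical(length(tr$map$aux), 1L)
  aux <- tr$map$aux[[1L]]
  g1 <- tr$network$funcs$x1
  expect_setequal(g1$reg, c("x2", aux))
  expect_true(all(g1$sign == -1L))
  ga <- tr$network$funcs[[aux]]
  expect_setequal(ga$reg, c("x3", "x4"))
  expect_true(all(ga$sign == -1L))

  # x2 | x3 with self-looped inputs: one auxiliary, g1 = !a, a = !x2 & !x3
  f2 <- parse_rules("x1 = x2 | x3\nx2 = x2\nx3 = x3")
  tr2 <- boolean_to_andnot(f2)
  expect_identical(length(tr2$map$aux), 1L)
  expect_identical(tr2$network$funcs$x1$sign, -1L)
  expect_identical(tr2$network$funcs$x1$reg, tr2$map$aux[[1L]])
})

test_that("a network already in AND-NOT form gains no auxiliaries", {
  f <- parse_rules("x1 = !x2 & x3\nx2 = x1\nx3 = !x1")
  tr <- boolean_to_andnot(f)
  expect_identical(length(tr$map$aux), 0L)
  expect_identical(length(tr$network$variables), 3L)
})

test_that("constant folding prevents spurious auxiliaries", {
  f <- parse_rules("x1 = x2 & 0\nx2 = x1 | 1\nx3 = x3 & (x1 | 0)")
  tr <- boolean_to_andnot(f)
  expect_identical(length(tr$map$aux), 0L)
  expect_identical(tr$network$funcs$x1$const, 0L)
  expect_identical(tr$network$funcs$x2$const, 1L)
})

test_that("projection truncates to the original coordinates and is injective", {
  f <- parse_rules("x1 = x2 | x3\nx2 = x1\nx3 = x1")
  tr <- boolean_to_andnot(f)
  sg <- enumerate_exhaustive(tr$network)
  proj <- project_steady_states(sg, tr$map)
  expect_true(same_steady_states(proj,
    steady_state_set(rbind(c(0L, 0L, 0L), c(1L, 1L, 1L)), f$variables)))
  # empty set maps to empty set
  none <- steady_state_set(NULL, tr$network$variables)
  expect_identical(length(project_steady_states(none, tr$map)), 0L)
})

test_that("transform preserves the steady-state set bijectively on random networks", {
  set.seed(505)
  tried <- 0L
  for (i in 1:400) {
    f <- random_boolean_network(sample(3:9, 1L))
    tr <- boolean_to_andnot(f)
    if (length(tr$network$variables) > 16L) next  # keep the scan of g tractable
    tried <- tried + 1L
    ss_f <- enumerate_exhaustive(f)
    ss_g <- enumerate_exhaustive(tr$network)
    expect_identical(length(ss_g), length(ss_f))
    expect_true(same_steady_states(project_steady_states(ss_g, tr$map), ss_f))
  }
  expect_gt(tried, 250L)
})
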