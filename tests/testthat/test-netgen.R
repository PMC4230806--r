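test_that("Kauffman networks have exactly K drawn regulators per node", {
  f <- generate_kauffman(n = 5, K = 2, seed = 0)
  regs <- attr(f, "regulators")
  expect_true(all(lengths(regs) == 2L))
  expect_true(all(vapply(regs, anyDuplicated, integer(1)) == 0L))
  # the rule text references a subset of the drawn regulators (a sampled
  # table may turn out independent of an input, or constant)
  for (v in f$variables) {
    expect_true(all(expression_vars(f$exprs[[v]]) %in% regs[[v]]))
  }
  single <- generate_kauffman(n = 1, K = 1, seed = 0)
  expect_identical(attr(single, "regulators")$x1, "x1")
  noself <- generate_kauffman(n = 6, K = 2, seed = 1, allow_self = FALSE)
  for (v in noself$variables) {
    expect_false(v %in% attr(noself, "regulators")[[v]])
  }
  expect_error(generate_kauffman(n = 3, K = 4, seed = 1), "exceeds")
})

test_that("generated truth tables are uniform over the 16 arity-2 functions", {
  # chi-square against the uniform null at alpha = 0.01
  set.seed(0)
  table_id <- function(e, inputs) {
    net <- boolean_network(inputs, stats::setNames(list(e, b_var(inputs[[2L]])), inputs))
    states <- bnsteady:::all_states_matrix(2L)
    bits <- as.integer(bnsteady:::eval_states(net, states)[, 1L])
    sum(bits * 2L^(3:0))
  }
  counts <- integer(16)
  for (i in 1:1000) {
    f <- generate_kauffman(n = 3, K = 2, seed = i, allow_self = FALSE)
    e <- f$exprs$x1
    regs <- attr(f, "regulators")$x1
    id <- table_id(e, regs)
    counts[[id + 1L]] <- counts[[id + 1L]] + 1L
  }
  p <- stats::chisq.test(counts, p = rep(1 / 16, 16))$p.value
  expect_gt(p, 0.01)
})

test_that("identical seeds give byte-identical rule files", {
  a <- write_rules(generate_kauffman(30, 2, seed = 123))
  b <- write_rules(generate_kauffman(30, 2, seed = 123))
  expect_identical(a, b)
  c1 <- write_rules(generate_powerlaw(50, 2, seed = 9))
  c2 <- write_rules(generate_powerlaw(50, 2, seed = 9))
  expect_identical(c1, c2)
  d <- write_rules(generate_kauffman(30, 2, seed = 124))
  expect_false(identical(a, d))
})

test_that("power-law networks hit the target mean in-degree", {
  f <- generate_powerlaw(n = 1000, avg_k = 2, gamma = 2.5, seed = 1)
  deg <- lengths(attr(f, "regulators"))
  expect_gte(mean(deg), 1.9)
  expect_lte(mean(deg), 2.1)
  # heavy upper tail relative to the constant-K model
  expect_gt(max(deg), 5L)

  # mean target 1 with lower cutoff 1 forces in-degree exactly 1
  g <- generate_powerlaw(n = 10, avg_k = 1, gamma = 2.5, seed = 3)
  expect_true(all(lengths(attr(g, "regulators")) == 1L))

  expect_error(generate_powerlaw(n = 5, avg_k = 5, seed = 1), "avg_k")
})

test_that("nested canalyzing functions are canalyzing in some input order", {
  set.seed(333)
  for (i in 1:40) {
    inputs <- paste0("v", 1:3)
    e <- bnsteady:::random_ncf_expression(inputs)
    net <- boolean_network(inputs,
      stats::setNames(list(e, b_var("v2"), b_var("v3")), inputs))
    states <- bnsteady:::all_states_matrix(3L)
    out <- bnsteady:::eval_states(net, states)[, 1L]
    expect_false(all(out) || !any(out))  # never degenerate to a constant
    # some input with some value pins the output
    canal <- FALSE
    for (j in 1:3) for (val in c(FALSE, TRUE)) {
      rows <- states[, j] == val
      if (length(unique(out[rows])) == 1L) canal <- TRUE
    }
    expect_true(canal)
  }
})

test_that("generated networks are closed under the full pipeline", {
  set.seed(444)
  for (i in 1:25) {
    f <- random_benchmark_network(i, n_range = 3:10)
    g <- parse_rules(write_rules(f))
    expect_true(same_truth_tables(f, g))
    expect_s3_class(solve_network(g, method = "pipeline")$steady_states,
                    "steady_state_set")
  }
})
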