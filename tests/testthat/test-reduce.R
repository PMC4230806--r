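test_that("unit-input elimination records an alias and preserves steady states", {
  g <- andnot_network(c("x1", "x2", "x3"),
    list(x1 = list(reg = "x2", sign = -1L),
         x2 = list(reg = "x3", sign = 1L),
         x3 = list(reg = "x3", sign = 1L)))
  red <- reduce_andnot(g)
  kinds <- vapply(red$trace$records, `[[`, character(1), "var")
  rec_x2 <- red$trace$records[[match("x2", kinds)]]
  expect_identical(rec_x2$kind, "alias")
  expect_identical(rec_x2$source, "x3")
  expect_identical(rec_x2$sign, 1L)
  # the input loop x3 = x3 survives
  expect_true("x3" %in% red$network$variables)
  ss_h <- enumerate_exhaustive(red$network)
  lifted <- backtrack_states(red$trace, ss_h, g)
  expect_true(same_steady_states(lifted, enumerate_exhaustive(g)))
  expect_true(same_steady_states(lifted,
    steady_state_set(rbind(c(1L, 0L, 0L), c(0L, 1L, 1L)), g$variables)))
})

test_that("constant contradiction propagates through targets", {
  # x1's function is normalized to 0 at construction; R1 then substitutes
  g <- andnot_network(c("x1", "x2", "x3"),
    list(x1 = list(reg = c("x2", "x2", "x3"), sign = c(1L, -1L, 1L)),
         x2 = list(reg = "x1", sign = 1L),
         x3 = list(reg = c("x1", "x3"), sign = c(-1L, 1L))))
  expect_identical(g$funcs$x1$const, 0L)
  red <- reduce_andnot(g)
  expect_gt(red$trace$counts[["R1"]], 0L)
  lifted <- backtrack_states(red$trace,
    if (is.null(red$network)) NULL else enumerate_exhaustive(red$network), g)
  expect_true(same_steady_states(lifted, enumerate_exhaustive(g)))
})

test_that("an irreducible motif is a fixpoint of the rules", {
  # mutual inhibition with self-activation: no constants, no unit inputs,
  # no sinks, no feed-forward triangle
  g <- andnot_network(c("x1", "x2"),
    list(x1 = list(reg = c("x1", "x2"), sign = c(1L, -1L)),
         x2 = list(reg = c("x2", "x1"), sign = c(1L, -1L))))
  red <- reduce_andnot(g)
  expect_identical(length(red$trace$records), 0L)
  expect_identical(red$network$variables, g$variables)

  # the negative two-node loop is aliased down to a single free node, and
  # backtracking still restores exactly its two antiphase fixed points
  neg <- andnot_network(c("x1", "x2"),
    list(x1 = list(reg = "x2", sign = -1L), x2 = list(reg = "x1", sign = -1L)))
  red2 <- reduce_andnot(neg)
  lifted <- backtrack_states(red2$trace,
    if (is.null(red2$network)) NULL else enumerate_exhaustive(red2$network), neg)
  expect_true(same_steady_states(lifted,
    steady_state_set(rbind(c(0L, 1L), c(1L, 0L)), c("x1", "x2"))))
})

test_that("feed-forward redundancy deletes the direct edge", {
  # x -> y (+), y -> z (+), x -> z (+): the direct x edge in z is absorbed
  g <- andnot_network(c("x", "y", "z"),
    list(x = list(reg = "x", sign = 1L),
         y = list(reg = "x", sign = 1L),
         z = list(reg = c("x", "y"), sign = c(1L, 1L))))
  red <- reduce_andnot(g)
  expect_gt(red$trace$counts[["R4"]] + red$trace$counts[["R2"]], 0L)
  lifted <- backtrack_states(red$trace,
    if (is.null(red$network)) NULL else enumerate_exhaustive(red$network), g)
  expect_true(same_steady_states(lifted, enumerate_exhaustive(g)))
})

test_that("sink elimination reconstructs the removed node from its conjunction", {
  g <- andnot_network(c("s", "a", "b"),
    list(s = list(reg = c("a", "b"), sign = c(1L, -1L)),
         a = list(reg = "a", sign = 1L),
         b = list(reg = "b", sign = 1L)))
  red <- reduce_andnot(g)
  kinds <- vapply(red$trace$records, `[[`, character(1), "kind")
  expect_true("sink" %in% kinds)
  lifted <- backtrack_states(red$trace,
    if (is.null(red$network)) NULL else enumerate_exhaustive(red$network), g)
  expect_true(same_steady_states(lifted, enumerate_exhaustive(g)))
})

test_that("backtracking handles constants and empty traces", {
  g <- andnot_network(c("x", "y"),
    list(x = list(const = 1L), y = list(reg = c("x", "y"), sign = c(1L, 1L))))
  red <- reduce_andnot(g)
  lifted <- backtrack_states(red$trace,
    if (is.null(red$network)) NULL else enumerate_exhaustive(red$network), g)
  expect_true(same_steady_states(lifted, enumerate_exhaustive(g)))
  expect_true(all(lifted$states[, "x"] == 1L))

  irr <- andnot_network(c("x1", "x2"),
    list(x1 = list(reg = "x2", sign = -1L), x2 = list(reg = "x1", sign = -1L)))
  red2 <- reduce_andnot(irr)
  ss <- enumerate_exhaustive(irr)
  expect_true(same_steady_states(backtrack_states(red2$trace, ss, irr), ss))
})

test_that("reduction is monotone, input loops survive, and backtracking is exact", {
  set.seed(606)
  for (i in 1:400) {
    m <- sample(3:12, 1L)
    g <- random_andnot_network(m)
    red <- reduce_andnot(g)
    l <- if (is.null(red$network)) 0L else length(red$network$variables)
    expect_lte(l, m)
    ss_h <- if (is.null(red$network)) NULL else enumerate_exhaustive(red$network)
    lifted <- backtrack_states(red$trace, ss_h, g)
    expect_true(same_steady_states(lifted, enumerate_exhaustive(g)))
    # nodes with a self-loop are only ever removed once constant
    if (!is.null(red$network)) {
      for (rec in red$trace$records) {
        if (rec$kind %in% c("alias", "sink")) {
          fn <- g$funcs[[rec$var]]
          expect_false(is.null(fn$const) && rec$var %in% fn$reg)
        }
      }
    }
  }
})
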