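test_that("exhaustive enumeration handles the closed-form cases", {
  id3 <- parse_rules("a = a\nb = b\nc = c")
  expect_identical(length(enumerate_exhaustive(id3)), 8L)
  neg <- parse_rules("x = !x")
  expect_identical(length(enumerate_exhaustive(neg)), 0L)
  f <- parse_rules("x1 = x2 & x3\nx2 = x1\nx3 = !x1")
  ss <- enumerate_exhaustive(f)
  expect_identical(unname(ss$states), matrix(c(0L, 0L, 1L), nrow = 1L))
  big <- parse_rules(paste(paste0("x", 1:30, " = x", 1:30), collapse = "\n"))
  expect_error(enumerate_exhaustive(big), "cap")
})

test_that("feedback vertex sets are valid and minimal on small graphs", {
  chain <- signed_digraph(c("x1", "x2", "x3"),
                          from = c("x1", "x2"), to = c("x2", "x3"),
                          sign = c("+", "+"))
  expect_identical(find_fvs(chain), character(0))

  loop2 <- signed_digraph(c("x1", "x2"),
                          from = c("x1", "x2"), to = c("x2", "x1"),
                          sign = c("+", "+"))
  expect_identical(length(find_fvs(loop2)), 1L)

  two_loops <- signed_digraph(c("a", "b", "c", "d"),
                              from = c("a", "b", "c", "d"),
                              to = c("b", "a", "d", "c"),
                              sign = rep("+", 4))
  expect_identical(length(find_fvs(two_loops)), 2L)

  # self-loops count as cycles
  selfy <- signed_digraph("x", from = "x", to = "x", sign = "+")
  expect_identical(find_fvs(selfy), "x")
})

test_that("exact FVS is never larger than the greedy heuristic", {
  set.seed(111)
  for (i in 1:40) {
    f <- generate_kauffman(sample(6:14, 1L), 2L, seed = i)
    gr <- dependency_graph(f)
    exact <- find_fvs(gr, exact_cap = 25L)
    greedy_only <- bnsteady:::.fvs_greedy(gr, f$variables)
    sub <- igraph::delete_vertices(gr, greedy_only)
    expect_true(bnsteady:::.is_acyclic(sub))
    expect_lte(length(exact), length(greedy_only))
  }
})

test_that("FVS candidate enumeration matches the hand-worked cases", {
  f <- parse_rules("x1 = x2\nx2 = x1")
  ss <- enumerate_via_fvs(f, S = "x1")
  expect_true(same_steady_states(ss,
    steady_state_set(rbind(c(0L, 0L), c(1L, 1L)), c("x1", "x2"))))

  # acyclic network: a single candidate, exactly one steady state
  acyc <- parse_rules("x1 = 1\nx2 = x1")
  ss2 <- enumerate_via_fvs(acyc, S = character(0))
  expect_identical(unname(ss2$states), matrix(c(1L, 1L), nrow = 1L))

  noss <- parse_rules("x1 = !x1")
  expect_identical(length(enumerate_via_fvs(noss, S = "x1")), 0L)

  expect_error(enumerate_via_fvs(f, S = character(0)), "not a valid feedback")
})

test_that("FVS enumeration equals the exhaustive scan on random networks", {
  set.seed(222)
  for (i in 1:200) {
    f <- random_benchmark_network(i, n_range = 3:12)
    S <- find_fvs(f)
    sub <- igraph::delete_vertices(dependency_graph(f), S)
    expect_true(bnsteady:::.is_acyclic(sub))
    expect_true(same_steady_states(enumerate_via_fvs(f, S),
                                   enumerate_exhaustive(f)))
  }
})

test_that("dependency graphs fold constants before reading off edges", {
  f <- parse_rules("x1 = x2 & 0\nx2 = x2")
  gr <- dependency_graph(f)
  expect_equal(igraph::ecount(gr), 1)  # only the x2 self-loop remains
})
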