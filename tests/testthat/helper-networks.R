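# Helpers: seeded random model builders used by the property tests.

# Random expression over a fixed variable set: a shallow random tree with
# AND/OR/NOT/XOR, per-node arity at most `max_arity` distinct variables.
random_expression <- function(vars, max_arity = 4L) {
  inputs <- sample(vars, min(length(vars), sample.int(max_arity, 1L)))
  leaf <- function(v) if (runif(1) < 0.4) b_not(b_var(v)) else b_var(v)
  if (length(inputs) == 1L) {
    if (runif(1) < 0.05) return(b_const(sample(0:1, 1L)))
    return(leaf(inputs[[1L]]))
  }
  op <- sample(c("and", "or", "xor"), 1L, prob = c(0.4, 0.4, 0.2))
  halves <- split(inputs, rep(1:2, length.out = length(inputs)))
  sub <- lapply(halves, function(h) {
    if (length(h) == 1L) return(leaf(h[[1L]]))
    inner <- sample(c("and", "or"), 1L)
    parts <- lapply(h, leaf)
    if (inner == "and") do.call(b_and, parts) else do.call(b_or, parts)
  })
  e <- switch(op,
    and = do.call(b_and, sub),
    or = do.call(b_or, sub),
    xor = do.call(b_xor, sub))
  if (runif(1) < 0.15) b_not(e) else e
}

# Random general Boolean network on n nodes.
random_boolean_network <- function(n, max_arity = 4L) {
  vars <- paste0("x", seq_len(n))
  exprs <- lapply(vars, function(v) random_expression(vars, max_arity))
  names(exprs) <- vars
  boolean_network(vars, exprs)
}

# Random AND-NOT network on m nodes: a few constants, the rest conjunctions
# of 1-3 signed literals.
random_andnot_network <- function(m, p_const = 0.08) {
  vars <- paste0("y", seq_len(m))
  funcs <- lapply(seq_len(m), function(i) {
    if (runif(1) < p_const) return(list(const = sample(0:1, 1L)))
    k <- sample.int(min(3L, m), 1L)
    reg <- sample(vars, k)
    list(reg = reg, sign = sample(c(-1L, 1L), k, replace = TRUE))
  })
  names(funcs) <- vars
  andnot_network(vars, funcs)
}

# Truth-table equality of two networks over the same variables.
same_truth_tables <- function(f, g) {
  stopifnot(identical(f$variables, g$variables))
  n <- length(f$variables)
  states <- bnsteady:::all_states_matrix(n)
  identical(bnsteady:::eval_states(f, states), bnsteady:::eval_states(g, states))
}

# A mixed corpus entry for cross-method checks (used in several suites).
random_benchmark_network <- function(i, n_range = 3:14) {
  n <- sample(n_range, 1L)
  cls <- sample(c("k1", "k2", "k3", "p2", "p3"), 1L)
  switch(cls,
    k1 = generate_kauffman(n, 1L, seed = i),
    k2 = generate_kauffman(n, min(2L, n), seed = i),
    k3 = generate_kauffman(n, min(3L, n), seed = i),
    p2 = generate_powerlaw(n, avg_k = min(2, n - 1), seed = i),
    p3 = generate_powerlaw(n, avg_k = min(3, n - 1), seed = i))
}
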