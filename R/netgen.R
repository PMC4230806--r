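# Seeded generators for benchmark network classes: Kauffman N-K networks and
# power-law in-degree networks, with uniformly random or nested-canalyzing
# update functions.

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Prime implicants of the on-set `ones` (0-based assignments) over k inputs,
# by Quine-McCluskey merging, followed by a greedy cover. Each implicant is
# returned as c(mask, value): `mask` marks the cared-about inputs (bit 2^(k-j)
# for input j), `value` their required values.
.prime_implicant_cover <- function(ones, k) {
  full <- bitwShiftL(1L, k) - 1L
  pow2 <- as.integer(2^(0:(k - 1)))
  cur_mask <- rep(full, length(ones))
  cur_val <- as.integer(ones)
  primes <- list()
  while (length(cur_mask) > 0L) {
    nr <- length(cur_mask)
    merged <- rep(FALSE, nr)
    nxt_mask <- integer(0)
    nxt_val <- integer(0)
    for (i in seq_len(nr)) {
      for (j in seq_len(nr)) {
        if (i >= j || cur_mask[[i]] != cur_mask[[j]]) next
        diffb <- bitwXor(cur_val[[i]], cur_val[[j]])
        if (sum(bitwAnd(diffb, pow2) > 0L) == 1L) {
          merged[[i]] <- merged[[j]] <- TRUE
          nxt_mask <- c(nxt_mask, bitwAnd(cur_mask[[i]], bitwNot(diffb)))
          nxt_val <- c(nxt_val, bitwAnd(cur_val[[i]], bitwNot(diffb)))
        }
      }
    }
    for (i in which(!merged)) {
      primes[[length(primes) + 1L]] <- c(cur_mask[[i]], cur_val[[i]])
    }
    if (length(nxt_mask) == 0L) break
    nxt_mask <- bitwAnd(nxt_mask, full)
    keep <- !duplicated(nxt_mask * (full + 1) + nxt_val)
    cur_mask <- nxt_mask[keep]
    cur_val <- nxt_val[keep]
  }
  # greedy cover of the on-set
  covers <- lapply(primes, function(p) {
    ones[bitwAnd(as.integer(ones), p[[1L]]) == p[[2L]]]
  })
  chosen <- list()
  uncovered <- ones
  while (length(uncovered) > 0L) {
    gain <- vapply(covers, function(cv) sum(uncovered %in% cv), integer(1))
    best <- which.max(gain)
    chosen[[length(chosen) + 1L]] <- primes[[best]]
    uncovered <- setdiff(uncovered, covers[[best]])
  }
  chosen
}

.implicant_term <- function(imp, inputs) {
  k <- length(inputs)
  lits <- list()
  for (j in seq_len(k)) {
    bit <- 2^(k - j)
    if (bitwAnd(imp[[1L]], bit) > 0) {
      v <- b_var(inputs[[j]])
      lits[[length(lits) + 1L]] <- if (bitwAnd(imp[[2L]], bit) > 0) v else b_not(v)
    }
  }
  .b_nary("AND", lits)
}

# Compact expression for a truth table over `inputs`. `bits` has length 2^K;
# entry i+1 is the output for assignment i, input 1 being the most
# significant bit. A minimal-cover disjunction of prime implicants is built
# for both the function and its complement, and the cheaper form (fewer
# AND-NOT auxiliaries after the transform, then fewer literals) is kept.
truth_table_to_expression <- function(inputs, bits) {
  k <- length(inputs)
  stopifnot(length(bits) == 2^k)
  ones <- which(bits == 1L) - 1L
  if (length(ones) == 0L) return(b_const(0L))
  if (length(ones) == 2^k) return(b_const(1L))
  build <- function(onset, negate) {
    terms <- lapply(.prime_implicant_cover(onset, k), .implicant_term, inputs = inputs)
    e <- .b_nary("OR", terms)
    if (negate) b_not(e) else e
  }
  direct <- build(ones, FALSE)
  complement <- build(setdiff(0:(2^k - 1L), ones), TRUE)
  # auxiliaries the AND-NOT transform will introduce: every OR needs one
  # De Morgan node, and every non-literal part of an AND or OR needs its own
  aux_cost <- function(e) {
    n <- to_nnf(e)
    as_part <- function(x) {
      switch(x$kind, VAR = , NOT = , CONST = 0L,
        1L + sum(vapply(x$args, as_part, integer(1))))
    }
    switch(n$kind,
      VAR = , NOT = , CONST = 0L,
      AND = sum(vapply(n$args, as_part, integer(1))),
      OR = 1L + sum(vapply(n$args, as_part, integer(1))))
  }
  size <- function(e) length(unlist(e, use.names = FALSE))
  ca <- aux_cost(direct); cb <- aux_cost(complement)
  if (cb < ca || (cb == ca && size(complement) < size(direct))) complement else direct
}

# A random nested canalyzing function on `inputs`: a random input order with
# per-input canalyzing value and output, last layer non-degenerate.
random_ncf_expression <- function(inputs) {
  k <- length(inputs)
  ord <- if (k == 1L) inputs else sample(inputs)
  a <- sample(c(0L, 1L), k, replace = TRUE)   # canalyzing input values
  b <- sample(c(0L, 1L), k, replace = TRUE)   # canalyzed outputs
  # innermost layer: if x_k = a_k the output is b_k, otherwise !b_k
  lit <- function(v, val) if (val == 1L) b_var(v) else b_not(b_var(v))
  e <- if (b[[k]] == 1L) lit(ord[[k]], a[[k]]) else b_not(lit(ord[[k]], a[[k]]))
  if (k >= 2L) {
    for (i in seq(k - 1L, 1L)) {
      e <- if (b[[i]] == 1L) {
        b_or(lit(ord[[i]], a[[i]]), e)                 # canalyzed to 1
      } else {
        b_and(b_not(lit(ord[[i]], a[[i]])), e)         # canalyzed to 0
      }
    }
  }
  e
}

# Above this arity a uniformly random truth table is impractical (2^k
# entries), so the generator falls back to a random nested canalyzing
# function, which has linear-size structure at any arity.
.uniform_table_max_arity <- 6L

.random_function <- function(inputs, family) {
  if (family == "nested-canalyzing" || length(inputs) > .uniform_table_max_arity) {
    random_ncf_expression(inputs)
  } else {
    bits <- sample(c(0L, 1L), 2^length(inputs), replace = TRUE)
    truth_table_to_expression(inputs, bits)
  }
}

.make_var_names <- function(n) paste0("x", seq_len(n))

#' Generate a random Kauffman N-K network
#'
#' Every node receives exactly `K` distinct regulators drawn uniformly
#' without replacement from all `n` nodes (optionally excluding itself), and
#' an update function drawn from the chosen family: a uniformly random truth
#' table on its 2^K input combinations, or a random nested canalyzing
#' function. Fully reproducible from `seed`.
#'
#' @param n Number of nodes.
#' @param K Exact in-degree, `1 <= K <= n` (`<= n - 1` with
#'   `allow_self = FALSE`).
#' @param seed Integer RNG seed.
#' @param family `"uniform"` (random truth table) or `"nested-canalyzing"`.
#' @param allow_self May a node select itself as a regulator?
#' @return A [boolean_network()], with the drawn regulator sets attached as
#'   `attr(net, "regulators")` (a named list). The minimized rule text may
#'   reference fewer variables than were drawn when a sampled truth table
#'   turns out not to depend on one of its inputs (e.g. a constant table);
#'   the attribute always records the draw itself.
#' @examples
#' f <- generate_kauffman(n = 8, K = 2, seed = 1)
#' @export
generate_kauffman <- function(n, K, seed, family = c("uniform", "nested-canalyzing"),
                              allow_self = TRUE) {
  family <- match.arg(family)
  stopifnot(n >= 1L, K >= 1L)
  pool_size <- if (allow_self) n else n - 1L
  if (K > pool_size) stop("K = ", K, " exceeds the available regulator pool (", pool_size, ")")
  vars <- .make_var_names(n)
  with_seed(seed, {
    exprs <- vector("list", n)
    regs <- vector("list", n)
    names(exprs) <- names(regs) <- vars
    for (i in seq_len(n)) {
      pool <- if (allow_self) vars else vars[-i]
      inputs <- if (length(pool) == 1L) pool else sample(pool, K)
      regs[[i]] <- inputs
      exprs[[i]] <- .random_function(inputs, family)
    }
    net <- boolean_network(vars, exprs)
    attr(net, "regulators") <- regs
    net
  })
}

# Sample one in-degree vector from a truncated discrete power law
# P(k) proportional to k^(-gamma) on 1..kmax.
.sample_powerlaw_degrees <- function(n, gamma, kmax) {
  k <- seq_len(kmax)
  w <- k^(-gamma)
  sample(k, n, replace = TRUE, prob = w / sum(w))
}

#' Generate a random power-law in-degree network
#'
#' In-degrees are sampled from a truncated discrete power law
#' P(k) proportional to k^(-gamma) on 1..min(n-1, 32) and then rescaled by
#' random unit increments/decrements until the total in-degree matches
#' `round(avg_k * n)`, so the realized mean in-degree equals the target to
#' within rounding (comfortably within a 5% tolerance). The upper truncation
#' reflects that regulatory in-degrees beyond a few dozen are not observed
#' in molecular networks; the rescaling step absorbs the truncated tail so
#' the mean is unaffected. Regulators are drawn uniformly without
#' replacement; update functions as in [generate_kauffman()]. Fully
#' reproducible from `seed`.
#'
#' @param n Number of nodes.
#' @param avg_k Target mean in-degree (must satisfy `1 <= avg_k < n`).
#' @param gamma Power-law exponent (default 2.5, in the 2-3 range reported
#'   for biological in-degree distributions).
#' @param seed Integer RNG seed.
#' @inheritParams generate_kauffman
#' @return A [boolean_network()] with the drawn regulator sets in
#'   `attr(net, "regulators")` (see [generate_kauffman()]).
#' @examples
#' f <- generate_powerlaw(n = 50, avg_k = 2, seed = 1)
#' @export
generate_powerlaw <- function(n, avg_k, gamma = 2.5, seed,
                              family = c("uniform", "nested-canalyzing"),
                              allow_self = TRUE) {
  family <- match.arg(family)
  stopifnot(n >= 2L, gamma > 1)
  if (avg_k < 1 || avg_k >= n) stop("avg_k must lie in [1, n)")
  kmax <- min(n - 1L, 32L)
  target_sum <- round(avg_k * n)
  if (target_sum > n * kmax) stop("avg_k is infeasible under the in-degree truncation")
  vars <- .make_var_names(n)
  with_seed(seed, {
    deg <- .sample_powerlaw_degrees(n, gamma, kmax)
    # rescale: unit adjustments on randomly chosen adjustable nodes
    while (sum(deg) != target_sum) {
      if (sum(deg) < target_sum) {
        cand <- which(deg < kmax)
        i <- if (length(cand) == 1L) cand else sample(cand, 1L)
        deg[[i]] <- deg[[i]] + 1L
      } else {
        cand <- which(deg > 1L)
        i <- if (length(cand) == 1L) cand else sample(cand, 1L)
        deg[[i]] <- deg[[i]] - 1L
      }
    }
    exprs <- vector("list", n)
    regs <- vector("list", n)
    names(exprs) <- names(regs) <- vars
    for (i in seq_len(n)) {
      pool <- if (allow_self) vars else vars[-i]
      ki <- min(deg[[i]], length(pool))
      inputs <- if (length(pool) == 1L) pool else sample(pool, ki)
      regs[[i]] <- inputs
      exprs[[i]] <- .random_function(inputs, family)
    }
    net <- boolean_network(vars, exprs)
    attr(net, "regulators") <- regs
    net
  })
}
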