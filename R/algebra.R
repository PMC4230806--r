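# Square-free polynomials over GF(2) and exact solving of the fixed-point
# system h_i + x_i = 0.
#
# Every Boolean function has a unique square-free polynomial form over GF(2)
# via the dictionary  x AND y <-> x*y,  x OR y <-> x + y + x*y,
# NOT x <-> x + 1.  All arithmetic here happens in the Boolean quotient ring
# (exponents truncated to 1 throughout, coefficients mod 2), so monomials are
# simply sets of variables and a polynomial is a set of monomials (symmetric
# difference as addition).
#
# Internal representation: within a solver call, variables are mapped to
# integer "ranks" 1..l along the chosen lexicographic elimination order
# (rank 1 = highest variable). A monomial is a strictly increasing integer
# vector of ranks (integer(0) is the constant 1); a polynomial is a list of
# monomials kept sorted in decreasing lexicographic order, with a parallel
# character key vector used for fast canonicalization. The zero polynomial
# is the empty list.

# Monomial key encoding: rank r becomes a zero-padded code of (10^5 - r), so
# plain string comparison of concatenated codes realizes the lexicographic
# monomial order (larger string = larger monomial).
.mono_keys <- function(monos) {
  vapply(monos, function(m) {
    if (length(m) == 0L) "" else paste(sprintf("%05d", 100000L - m), collapse = "")
  }, character(1))
}

# Canonical polynomial from an unordered bag of monomials: keep monomials of
# odd multiplicity, sort decreasing (leading monomial first).
.poly_canon <- function(monos) {
  if (length(monos) == 0L) return(list(monos = list(), keys = character(0)))
  keys <- .mono_keys(monos)
  if (anyDuplicated(keys)) {
    o <- order(keys, method = "radix")
    keys <- keys[o]
    monos <- monos[o]
    runs <- rle(keys)
    odd <- runs$lengths %% 2L == 1L
    if (!any(odd)) return(list(monos = list(), keys = character(0)))
    first_of_run <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
    keep <- first_of_run[odd]
    keys <- keys[keep]
    monos <- monos[keep]
  }
  o <- order(keys, decreasing = TRUE, method = "radix")
  list(monos = monos[o], keys = keys[o])
}

.cap_stop <- function(max_solutions) {
  stop(errorCondition(
    paste0("solution cap exceeded (", format(max_solutions, scientific = FALSE), ")"),
    class = "bnsteady_cap_error"))
}

.poly_zero <- list(monos = list(), keys = character(0))
.poly_one <- list(monos = list(integer(0)), keys = "")

.poly_is_zero <- function(p) length(p$monos) == 0L


# p + q over GF(2): symmetric difference of monomial sets. Both inputs are
# canonical, so equal monomials have equal keys.
.poly_add <- function(p, q) {
  if (.poly_is_zero(p)) return(q)
  if (.poly_is_zero(q)) return(p)
  shared_p <- p$keys %in% q$keys
  shared_q <- q$keys %in% p$keys
  monos <- c(p$monos[!shared_p], q$monos[!shared_q])
  keys <- c(p$keys[!shared_p], q$keys[!shared_q])
  o <- order(keys, decreasing = TRUE, method = "radix")
  list(monos = monos[o], keys = keys[o])
}

# General product (used only for the Boolean-to-polynomial dictionary).
.poly_mul <- function(p, q) {
  if (.poly_is_zero(p) || .poly_is_zero(q)) return(.poly_zero)
  out <- list()
  for (mp in p$monos) {
    for (mq in q$monos) out[[length(out) + 1L]] <- sort.int(unique(c(mp, mq)))
  }
  .poly_canon(out)
}

# The Buchberger engine and the branching back-substitution solver live in
# compiled code (src/boolean_gb.cpp); see .gb_cpp() and
# .solve_component_cpp(). Polynomials cross the boundary as plain lists of
# integer rank vectors.
.ranked_to_cpp <- function(p) p$monos
.cpp_to_ranked <- function(monos) {
  if (length(monos) == 0L) return(.poly_zero)
  list(monos = monos, keys = .mono_keys(monos))
}

# ---- public polynomial objects (variable-name space) -----------------------

.poly_object <- function(monomials, variables) {
  structure(list(monomials = monomials, variables = variables),
            class = "gf2_poly")
}

#' @export
print.gf2_poly <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.gf2_poly <- function(x, ...) {
  if (length(x$monomials) == 0L) return("0")
  terms <- vapply(x$monomials, function(m) {
    if (length(m) == 0L) "1" else paste(m, collapse = "*")
  }, character(1))
  paste(terms, collapse = " + ")
}

# Convert between name-space monomials and rank-space canonical polynomials.
# Monomials of a gf2_poly are already distinct, so remapping ranks needs a
# re-sort but no duplicate cancellation.
.poly_to_ranks <- function(p, rank_of) {
  monos <- lapply(p$monomials, function(m) sort.int(unname(rank_of[m])))
  keys <- .mono_keys(monos)
  o <- order(keys, decreasing = TRUE, method = "radix")
  list(monos = monos[o], keys = keys[o])
}
.poly_from_ranks <- function(p, order_vars) {
  monos <- lapply(p$monos, function(m) order_vars[m])
  .poly_object(monos, order_vars)
}

#' Square-free GF(2) polynomial of a Boolean expression
#'
#' Applies the Boolean-polynomial dictionary `x AND y <-> x*y`,
#' `x OR y <-> x + y + x*y`, `NOT x <-> x + 1` (and `XOR <-> +`), reducing
#' exponents to 1 and coefficients mod 2 throughout. The result evaluates
#' identically to the expression on every 0/1 assignment and is the unique
#' square-free polynomial form of the function.
#'
#' @param e An expression tree (see [b_var()]), or a character scalar parsed
#'   with [parse_expression()].
#' @param variables Character vector fixing the variable universe and order;
#'   defaults to the variables occurring in `e`.
#' @return A `gf2_poly`: a list of monomials (character vectors of variable
#'   names; the empty vector is the constant 1) summed over GF(2).
#' @examples
#' expr_to_polynomial("!x")        # x + 1
#' expr_to_polynomial("x | y")     # x + y + x*y
#' @export
expr_to_polynomial <- function(e, variables = NULL) {
  if (is.character(e)) e <- parse_expression(e)
  if (is.null(variables)) variables <- expression_vars(e)
  rank_of <- seq_along(variables)
  names(rank_of) <- variables
  conv <- function(x) {
    switch(x$kind,
      VAR = {
        r <- rank_of[[x$name]]
        list(monos = list(r), keys = .mono_keys(list(r)))
      },
      CONST = if (x$value == 1L) .poly_one else .poly_zero,
      NOT = .poly_add(conv(x$args[[1L]]), .poly_one),
      AND = Reduce(.poly_mul, lapply(x$args, conv)),
      OR = Reduce(function(a, b) {
        .poly_add(.poly_add(a, b), .poly_mul(a, b))
      }, lapply(x$args, conv)),
      XOR = Reduce(.poly_add, lapply(x$args, conv)),
      stop("unknown expression kind: ", x$kind)
    )
  }
  bad <- setdiff(expression_vars(e), variables)
  if (length(bad)) stop("expression references variables outside `variables`: ",
                        paste(bad, collapse = ", "))
  .poly_from_ranks(conv(e), variables)
}

# Polynomial of one AND-NOT node function, in rank space. A conjunction of
# positive literals P and negated literals N expands to
# prod(P) * prod(n + 1) = sum over subsets T of N of prod(P) * prod(T),
# all monomials distinct, so the polynomial is written down directly.
.andnot_poly <- function(fn, rank_of) {
  if (!is.null(fn$const)) {
    return(if (fn$const == 1L) .poly_one else .poly_zero)
  }
  ranks <- unname(rank_of[fn$reg])
  pos <- sort.int(ranks[fn$sign > 0L])
  neg <- ranks[fn$sign < 0L]
  nn <- length(neg)
  if (nn > 20L) {
    stop("conjunction with ", nn, " negated literals would expand to 2^", nn,
         " monomials; split the rule (boolean_to_andnot() caps widths)")
  }
  if (nn == 0L) {
    monos <- list(pos)
  } else {
    monos <- vector("list", 2^nn)
    for (b in 0:(2^nn - 1L)) {
      sub <- neg[bitwAnd(b, 2^(seq_len(nn) - 1L)) > 0L]
      monos[[b + 1L]] <- sort.int(c(pos, sub))
    }
  }
  keys <- .mono_keys(monos)
  o <- order(keys, decreasing = TRUE, method = "radix")
  list(monos = monos[o], keys = keys[o])
}

#' Fixed-point polynomial system of an AND-NOT network
#'
#' Encodes the steady-state condition of each node as the GF(2) equation
#' `poly(h_i) + x_i = 0` (subtraction and addition coincide mod 2). A node
#' `x = !x` yields the inconsistent equation `1 = 0` (no steady state); an
#' identity node `x = x` yields `0 = 0` (a free environmental input).
#'
#' @param h An `andnot_network`.
#' @return A `gf2_system`: the variable sequence plus one `gf2_poly` per
#'   node, each understood as `= 0`. A feedback-guided elimination order is
#'   attached (field `suggested_order`) and used as the default by
#'   [groebner_basis()] and [enumerate_solutions()].
#' @export
steady_state_system <- function(h) {
  stopifnot(is_andnot_network(h))
  vars <- h$variables
  rank_of <- seq_along(vars)
  names(rank_of) <- vars
  polys <- vector("list", length(vars))
  for (i in seq_along(vars)) {
    xi <- list(monos = list(i), keys = .mono_keys(list(i)))
    p <- .poly_add(.andnot_poly(h$funcs[[i]], rank_of), xi)
    polys[[i]] <- .poly_from_ranks(p, vars)
  }
  structure(list(variables = vars, polys = polys,
                 suggested_order = .feedback_order(h)),
            class = "gf2_system")
}

# Elimination order for the fixed-point system of an AND-NOT network: a
# (greedy) feedback vertex set goes lowest; the acyclic remainder is placed
# in reverse topological order, so every remaining variable sits lexically
# above all of its regulators. Each such equation x_i + poly(regulators)
# then has the linear leading term x_i, and the Groebner computation is
# essentially the triangular elimination the lex order is meant to enable;
# only the |FVS| feedback variables carry nonlinear leading terms.
# Implemented in plain R (trim the acyclic fringe, pick max in*out degree,
# Kahn topological sort) -- it runs on every solve, so it must be cheap.
.feedback_order <- function(h) {
  vars <- h$variables
  m <- length(vars)
  idx <- seq_len(m)
  names(idx) <- vars
  preds <- lapply(h$funcs, function(fn)
    if (is.null(fn$const)) unname(idx[fn$reg]) else integer(0))
  succs <- vector("list", m)
  for (i in seq_len(m)) for (p in preds[[i]]) succs[[p]] <- c(succs[[p]], i)
  indeg <- lengths(preds)
  outdeg <- lengths(succs)
  selfloop <- vapply(seq_len(m), function(i) i %in% preds[[i]], logical(1))
  alive <- rep(TRUE, m)
  S <- integer(0)

  drop_node <- function(v) {
    alive[[v]] <<- FALSE
    for (s in succs[[v]]) if (alive[[s]]) indeg[[s]] <<- indeg[[s]] - 1L
    for (p in preds[[v]]) if (alive[[p]]) outdeg[[p]] <<- outdeg[[p]] - 1L
  }

  repeat {
    # trim the acyclic fringe (self-loops keep indeg/outdeg >= 1)
    repeat {
      fringe <- which(alive & (indeg == 0L | outdeg == 0L))
      if (length(fringe) == 0L) break
      for (v in fringe) if (alive[[v]]) drop_node(v)
    }
    left <- which(alive)
    if (length(left) == 0L) break
    sl <- left[selfloop[left]]
    v <- if (length(sl)) sl[[1L]]
         else left[[which.max(indeg[left] * outdeg[left])]]
    S <- c(S, v)
    drop_node(v)
  }

  # Kahn topological sort of the graph without S (sources first)
  rest <- setdiff(seq_len(m), S)
  in_rest <- rep(FALSE, m)
  in_rest[rest] <- TRUE
  ind <- vapply(seq_len(m), function(i)
    sum(in_rest[preds[[i]]] & preds[[i]] != i), integer(1))
  queue <- rest[ind[rest] == 0L]
  topo <- integer(0)
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    topo <- c(topo, v)
    for (s in succs[[v]]) {
      if (in_rest[[s]] && s != v) {
        ind[[s]] <- ind[[s]] - 1L
        if (ind[[s]] == 0L) queue <- c(queue, s)
      }
    }
  }
  vars[c(rev(topo), S)]
}

#' @export
print.gf2_system <- function(x, ...) {
  cat("GF(2) polynomial system:", length(x$polys), "equations over",
      length(x$variables), "variables\n")
  for (p in x$polys) cat("  ", format(p), " = 0\n", sep = "")
  invisible(x)
}

# Default elimination order: the feedback-guided order computed with the
# system when available (see .feedback_order); otherwise rare variables
# first (ascending occurrence count, ties by declaration index). Returns
# variable names, highest first.
.default_order <- function(sys) {
  if (!is.null(sys$suggested_order)) return(sys$suggested_order)
  counts <- setNames(rep(0L, length(sys$variables)), sys$variables)
  for (p in sys$polys) {
    used <- unique(unlist(p$monomials, use.names = FALSE))
    if (length(used)) counts[used] <- counts[used] + 1L
  }
  sys$variables[order(counts, seq_along(counts), method = "radix")]
}

#' Reduced lexicographic Gröbner basis over GF(2)
#'
#' Computes the reduced Gröbner basis of the system's ideal in the Boolean
#' quotient ring (the field relations x^2 = x are built into the arithmetic),
#' under the lexicographic order induced by `order` (first element =
#' highest variable). Buchberger's algorithm is used with S-polynomials
#' against the field relations included; no coprimality pruning is applied,
#' as the product criterion does not carry over to the quotient ring. The
#' basis has the same 0/1 solution set as the input system and equals `{1}`
#' exactly when the system has no solutions.
#'
#' @param sys A `gf2_system` from [steady_state_system()].
#' @param order Character vector: a permutation of the system's variables
#'   giving the elimination order. Defaults to ascending occurrence count
#'   (rare variables eliminated first), ties by declaration order.
#' @return A list of `gf2_poly`, sorted by decreasing leading monomial.
#' @export
groebner_basis <- function(sys, order = NULL) {
  stopifnot(inherits(sys, "gf2_system"))
  if (is.null(order)) order <- .default_order(sys)
  stopifnot(setequal(order, sys$variables), length(order) == length(sys$variables))
  rank_of <- seq_along(order)
  names(rank_of) <- order
  ranked <- lapply(sys$polys, .poly_to_ranks, rank_of = rank_of)
  G <- .gb_cpp(lapply(ranked, .ranked_to_cpp))
  lapply(G, function(monos) .poly_from_ranks(.cpp_to_ranked(monos), order))
}

#' Enumerate all 0/1 solutions of a GF(2) polynomial system
#'
#' Finds exactly the assignments on which every polynomial vanishes. The
#' system is first split into connected components (equations linked by
#' shared variables); each component is solved by a lexicographic Gröbner
#' basis followed by back-substitution from the lowest variable of the
#' elimination order upward, branching where a variable is unconstrained and
#' pruning any branch whose partially substituted basis contains 1. Variables
#' appearing in no equation are free and contribute a factor of 2 each; the
#' component solutions are combined as a Cartesian product.
#'
#' @param sys A `gf2_system`.
#' @param order Optional variable ordering (as in [groebner_basis()]).
#' @param max_solutions Cap on the number of solutions; exceeding it raises
#'   an error of class `bnsteady_cap_error` (this signals combinatorial
#'   explosion, e.g. very many free input nodes, rather than a failure of
#'   the computation).
#' @return A [steady_state_set()] over the system's variables.
#' @examples
#' h <- andnot_network(c("x1", "x2"),
#'   list(x1 = list(reg = "x2", sign = -1L), x2 = list(reg = "x1", sign = -1L)))
#' enumerate_solutions(steady_state_system(h))
#' @export
enumerate_solutions <- function(sys, order = NULL, max_solutions = 1e5) {
  stopifnot(inherits(sys, "gf2_system"))
  vars <- sys$variables
  if (is.null(order)) order <- .default_order(sys)
  stopifnot(setequal(order, vars))
  rank_of <- seq_along(order)
  names(rank_of) <- order
  ranked <- lapply(sys$polys, .poly_to_ranks, rank_of = rank_of)
  ranked <- Filter(Negate(.poly_is_zero), ranked)

  l <- length(vars)
  # Union-find over ranks to split into independent components.
  parent <- seq_len(l)
  find <- function(a) { while (parent[[a]] != a) { parent[[a]] <<- parent[[parent[[a]]]]; a <- parent[[a]] }; a }
  for (p in ranked) {
    used <- unique(unlist(p$monos, use.names = FALSE))
    if (length(used) > 1L) {
      r0 <- find(used[[1L]])
      for (u in used[-1L]) parent[[find(u)]] <- r0
    }
  }
  comp_of <- vapply(seq_len(l), find, integer(1))
  poly_comp <- vapply(ranked, function(p) {
    used <- unlist(p$monos, use.names = FALSE)
    if (length(used) == 0L) 0L else comp_of[[used[[1L]]]]
  }, integer(1))
  if (any(poly_comp == 0L)) {
    # a constant nonzero polynomial: 1 = 0, no solutions
    return(steady_state_set(NULL, vars))
  }

  constrained <- sort(unique(comp_of[unique(unlist(lapply(ranked, function(p)
    unlist(p$monos, use.names = FALSE))))]))
  free_ranks <- setdiff(seq_len(l), which(comp_of %in% constrained))

  comp_ids <- constrained
  blocks <- list()
  total <- 1
  gb_size <- 0L
  branches <- 0
  for (cid in comp_ids) {
    ranks <- which(comp_of == cid)
    polys <- ranked[poly_comp == cid]
    res <- .solve_component_cpp(lapply(polys, .ranked_to_cpp),
                                as.integer(ranks), max_solutions)
    if (isTRUE(res$capped)) .cap_stop(max_solutions)
    gb_size <- gb_size + res$gb_size
    branches <- branches + res$branches
    blk <- res$states
    if (nrow(blk) == 0L) {
      out <- steady_state_set(NULL, vars)
      attr(out, "gb_size") <- gb_size
      attr(out, "branches") <- branches
      return(out)
    }
    blocks[[length(blocks) + 1L]] <- list(ranks = ranks, states = blk)
    total <- total * nrow(blk)
    if (total > max_solutions) .cap_stop(max_solutions)
  }
  total <- total * 2^length(free_ranks)
  if (total > max_solutions) .cap_stop(max_solutions)

  # Cartesian product of component blocks and free variables, in rank space.
  mat <- matrix(0L, nrow = 1L, ncol = l)
  for (blk in blocks) {
    r <- nrow(blk$states)
    mat <- mat[rep(seq_len(nrow(mat)), each = r), , drop = FALSE]
    mat[, blk$ranks] <- blk$states[rep(seq_len(r), times = nrow(mat) / r), , drop = FALSE]
  }
  for (fr in free_ranks) {
    mat <- rbind(mat, mat)
    mat[, fr] <- rep(c(0L, 1L), each = nrow(mat) / 2L)
  }
  # columns of `mat` are in rank space; reorder to declaration order
  out <- steady_state_set(mat[, rank_of[vars], drop = FALSE], vars)
  attr(out, "gb_size") <- gb_size
  attr(out, "branches") <- branches
  out
}
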