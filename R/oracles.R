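# Independent verification oracles: exhaustive state-space enumeration and
# feedback-vertex-set candidate enumeration.

#' Dependency graph of a network
#'
#' Edges follow syntactic occurrence: `x -> y` when `x` appears in the update
#' rule of `y` after constant folding (folding removes phantom dependencies
#' such as `x & 0`). For an AND-NOT network this coincides with the node
#' structure of [wiring_diagram()] but drops the signs.
#'
#' @param network A `boolean_network` or `andnot_network`.
#' @return An [igraph::graph] object (directed; self-loops retained).
#' @export
dependency_graph <- function(network) {
  vars <- network$variables
  from <- character(0); to <- character(0)
  if (is_boolean_network(network)) {
    for (v in vars) {
      used <- expression_vars(fold_constants(network$exprs[[v]]))
      from <- c(from, used)
      to <- c(to, rep(v, length(used)))
    }
  } else if (is_andnot_network(network)) {
    for (v in vars) {
      fn <- network$funcs[[v]]
      if (is.null(fn$const)) {
        from <- c(from, fn$reg)
        to <- c(to, rep(v, length(fn$reg)))
      }
    }
  } else {
    stop("expected a boolean_network or andnot_network")
  }
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = vars, stringsAsFactors = FALSE))
}

# All 2^n states as a logical matrix, rows sorted ascending as binary
# integers with the first variable as the most significant bit.
all_states_matrix <- function(n) {
  if (n > 30L) stop("state matrix for n > 30 is not representable")
  total <- 2^n
  ints <- 0:(total - 1)
  m <- matrix(FALSE, nrow = total, ncol = n)
  for (j in seq_len(n)) {
    m[, j] <- bitwAnd(ints, 2^(n - j)) > 0
  }
  m
}

#' Enumerate steady states by exhaustive state-space scan
#'
#' Scans all 2^n states and keeps those fixed by the synchronous update map.
#' This is the ground-truth oracle for small networks; the cap prevents an
#' accidental 2^50 scan.
#'
#' @param network A `boolean_network` or `andnot_network`.
#' @param cap Refuse networks with more than this many variables.
#' @return A [steady_state_set()].
#' @export
enumerate_exhaustive <- function(network, cap = 22L) {
  n <- length(network$variables)
  if (n > cap) {
    stop("exhaustive enumeration refused: ", n, " variables exceeds cap ", cap,
         " (2^", n, " states)")
  }
  states <- all_states_matrix(n)
  nxt <- eval_states(network, states)
  fixed <- rowSums(nxt != states) == 0L
  steady_state_set(matrix(as.integer(states[fixed, , drop = FALSE]), ncol = n),
                   network$variables)
}

.as_igraph <- function(d) {
  if (inherits(d, "signed_digraph")) {
    igraph::graph_from_data_frame(d$edges[, c("from", "to")], directed = TRUE,
                                  vertices = data.frame(name = d$nodes,
                                                        stringsAsFactors = FALSE))
  } else if (igraph::is_igraph(d)) {
    d
  } else {
    dependency_graph(d)
  }
}

# TRUE when the directed graph (self-loops included) has no cycle.
.is_acyclic <- function(gr) {
  if (any(igraph::which_loop(gr))) return(FALSE)
  igraph::is_dag(gr)
}

# Find one shortest directed cycle in the graph; returns vertex names or NULL.
.find_shortest_cycle <- function(gr) {
  loops <- igraph::E(gr)[igraph::which_loop(gr)]
  if (length(loops) > 0L) {
    v <- igraph::tail_of(gr, loops[[1L]])
    return(igraph::V(gr)$name[[as.integer(v)]])
  }
  best <- NULL
  best_len <- Inf
  vs <- igraph::V(gr)
  for (v in as.integer(vs)) {
    # shortest path from any out-neighbor of v back to v
    nb <- as.integer(igraph::neighbors(gr, v, mode = "out"))
    nb <- setdiff(nb, v)
    if (length(nb) == 0L) next
    dv <- suppressWarnings(igraph::distances(gr, v = nb, to = v, mode = "out"))
    reachable <- which(is.finite(dv[, 1L]))
    if (length(reachable) == 0L) next
    k <- reachable[[which.min(dv[reachable, 1L])]]
    len <- dv[k, 1L] + 1L
    if (len < best_len) {
      path <- suppressWarnings(igraph::shortest_paths(gr, from = nb[[k]], to = v,
                                                      mode = "out", output = "vpath"))
      best <- c(v, as.integer(path$vpath[[1L]])[-length(path$vpath[[1L]])])
      best_len <- len
      if (best_len == 2L) break
    }
  }
  if (is.null(best)) NULL else igraph::V(gr)$name[unique(best)]
}

# Exact minimum FVS by branch and bound: every vertex of some cycle must be
# in the set; branch over the vertices of a shortest cycle.
.fvs_exact <- function(gr, best_size) {
  if (.is_acyclic(gr)) return(character(0))
  if (best_size <= 0L) return(NULL)
  cyc <- .find_shortest_cycle(gr)
  best <- NULL
  for (v in cyc) {
    sub <- igraph::delete_vertices(gr, v)
    rest <- .fvs_exact(sub, best_size - 1L)
    if (!is.null(rest) && (1L + length(rest)) <= best_size) {
      best <- c(v, rest)
      best_size <- length(best) - 1L  # look for strictly smaller
      if (length(best) == 1L) break
    }
  }
  best
}

# Greedy heuristic: repeatedly restrict to the cyclic part, take self-looped
# vertices outright, otherwise remove the vertex lying on the most shortest
# cycles (ties by declaration order).
.fvs_greedy <- function(gr, declaration) {
  fvs <- character(0)
  repeat {
    loops <- unique(igraph::V(gr)$name[as.integer(igraph::tail_of(
      gr, igraph::E(gr)[igraph::which_loop(gr)]))])
    if (length(loops) > 0L) {
      fvs <- c(fvs, loops)
      gr <- igraph::delete_vertices(gr, loops)
      next
    }
    # keep only vertices inside non-trivial strongly connected components
    sc <- igraph::components(gr, mode = "strong")
    sizes <- sc$csize[sc$membership]
    cyclic <- igraph::V(gr)$name[sizes > 1L]
    if (length(cyclic) == 0L) break
    gr <- igraph::induced_subgraph(gr, cyclic)
    # shortest cycle length through each vertex
    nv <- igraph::vcount(gr)
    dmat <- igraph::distances(gr, mode = "out")
    adj <- igraph::as_adjacency_matrix(gr, sparse = FALSE) > 0
    cyc_len <- rep(Inf, nv)
    for (v in seq_len(nv)) {
      nb <- which(adj[v, ])
      if (length(nb)) cyc_len[[v]] <- 1 + min(dmat[nb, v])
    }
    gmin <- min(cyc_len)
    cand <- which(cyc_len == gmin)
    # among candidates, prefer the one covering the most 2-step interactions
    score <- igraph::degree(gr, mode = "in") * igraph::degree(gr, mode = "out")
    cand <- cand[order(-score[cand],
                       match(igraph::V(gr)$name[cand], declaration))]
    pick <- igraph::V(gr)$name[[cand[[1L]]]]
    fvs <- c(fvs, pick)
    gr <- igraph::delete_vertices(gr, pick)
  }
  fvs
}

#' Find a feedback vertex set
#'
#' A feedback vertex set (FVS) is a set of nodes whose deletion leaves the
#' directed graph acyclic (self-loops count as cycles). Fixing the
#' coordinates of an FVS at a steady state determines all other coordinates,
#' so an FVS of size s yields 2^s candidate steady states. For graphs with
#' at most `exact_cap` nodes the exact minimum is computed by branch and
#' bound over shortest cycles; larger graphs use a greedy heuristic
#' (self-loops first, then the vertex on the most shortest cycles, ties by
#' declaration order). Validity is always verified by an acyclicity check.
#'
#' @param d A [signed_digraph()], an igraph graph, or a network (whose
#'   [dependency_graph()] is used).
#' @param exact_cap Largest node count for which the exact minimum is
#'   attempted.
#' @return Character vector of node names (possibly empty), sorted.
#' @export
find_fvs <- function(d, exact_cap = 25L) {
  gr <- .as_igraph(d)
  declaration <- igraph::V(gr)$name
  if (igraph::vcount(gr) <= exact_cap) {
    # greedy first to obtain an upper bound, then branch and bound
    ub <- .fvs_greedy(gr, declaration)
    exact <- .fvs_exact(gr, length(ub))
    fvs <- if (is.null(exact)) ub else exact
  } else {
    fvs <- .fvs_greedy(gr, declaration)
  }
  sub <- igraph::delete_vertices(gr, fvs)
  if (!.is_acyclic(sub)) stop("internal error: candidate FVS leaves a cycle")
  sort(fvs)
}

#' Enumerate steady states via a feedback vertex set
#'
#' For each of the 2^|S| assignments to the FVS nodes, the remaining
#' variables are evaluated in topological order of the acyclic remainder of
#' the dependency graph; the completed candidate is kept exactly when it is
#' fixed by the full update map. Agrees with [enumerate_exhaustive()]
#' whenever both are computable.
#'
#' @param network A `boolean_network` or `andnot_network`.
#' @param S Character vector of node names forming a valid FVS of the
#'   network's dependency graph; defaults to [find_fvs()].
#' @param cap Refuse |S| larger than this (2^|S| candidates).
#' @return A [steady_state_set()].
#' @export
enumerate_via_fvs <- function(network, S = NULL, cap = 24L) {
  vars <- network$variables
  gr <- dependency_graph(network)
  if (is.null(S)) S <- find_fvs(gr)
  stopifnot(all(S %in% vars), !anyDuplicated(S))
  if (length(S) > cap) {
    stop("FVS enumeration refused: |S| = ", length(S), " exceeds cap ", cap)
  }
  rest_gr <- igraph::delete_vertices(gr, S)
  if (!.is_acyclic(rest_gr)) stop("S is not a valid feedback vertex set")
  topo <- igraph::V(rest_gr)$name[as.integer(igraph::topo_sort(rest_gr, mode = "out"))]

  s <- length(S)
  rows <- 2^s
  states <- matrix(FALSE, nrow = rows, ncol = length(vars))
  colnames(states) <- vars
  if (s > 0L) {
    ints <- 0:(rows - 1)
    for (j in seq_len(s)) states[, S[[j]]] <- bitwAnd(ints, 2^(s - j)) > 0
  }

  # evaluate the acyclic remainder in topological order
  if (is_boolean_network(network)) {
    env <- new.env(parent = baseenv())
    for (v in vars) assign(v, states[, v], envir = env)
    for (v in topo) {
      val <- eval(network$calls[[v]], env)
      if (length(val) == 1L) val <- rep(val, rows)
      states[, v] <- val
      assign(v, val, envir = env)
    }
  } else {
    for (v in topo) {
      fn <- network$funcs[[v]]
      if (!is.null(fn$const)) {
        states[, v] <- fn$const == 1L
      } else {
        acc <- rep(TRUE, rows)
        for (k in seq_along(fn$reg)) {
          src <- states[, fn$reg[[k]]]
          acc <- acc & (if (fn$sign[[k]] > 0L) src else !src)
        }
        states[, v] <- acc
      }
    }
  }

  nxt <- eval_states(network, states)
  fixed <- rowSums(nxt != states) == 0L
  steady_state_set(matrix(as.integer(states[fixed, , drop = FALSE]),
                          ncol = length(vars)),
                   vars)
}
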