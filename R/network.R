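# Network containers: general Boolean networks, AND-NOT networks, signed
# digraphs, and steady-state sets.

#' Construct a Boolean network
#'
#' A Boolean network over the two-element state alphabet \{0,1\} assigns one
#' update expression to each of an ordered list of variables; synchronous
#' application of all updates defines a map \{0,1\}^n -> \{0,1\}^n whose fixed
#' points are the model's steady states.
#'
#' @param variables Character vector of variable names, in declaration order.
#' @param exprs Named list of expression trees (see [b_var()]), one per
#'   variable. Every variable referenced by an expression must be declared.
#' @return An object of class `boolean_network`.
#' @examples
#' f <- boolean_network(c("x1", "x2", "x3"),
#'   list(x1 = b_and(b_var("x2"), b_var("x3")), x2 = b_var("x1"),
#'        x3 = b_not(b_var("x1"))))
#' evaluate_network(f, c(0, 0, 1))
#' @export
boolean_network <- function(variables, exprs) {
  stopifnot(is.character(variables), length(variables) >= 1L,
            !anyDuplicated(variables), is.list(exprs))
  if (!setequal(names(exprs), variables) || length(exprs) != length(variables)) {
    stop("exactly one update expression per declared variable is required")
  }
  exprs <- exprs[variables]
  for (v in variables) {
    used <- expression_vars(exprs[[v]])
    bad <- setdiff(used, variables)
    if (length(bad)) {
      stop("update rule for '", v, "' references undeclared variable(s): ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(variables = variables, exprs = exprs,
                 calls = lapply(exprs, expr_to_call)),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network with", length(x$variables), "nodes\n")
  for (v in x$variables) cat("  ", v, " = ", deparse_expression(x$exprs[[v]]), "\n", sep = "")
  invisible(x)
}

#' Construct an AND-NOT network
#'
#' An AND-NOT network is a Boolean network in which every update function is
#' either a constant or a conjunction of signed literals (a variable or its
#' negation). It is fully determined by its signed wiring diagram. A
#' conjunction containing both a variable and its negation is normalized to
#' the constant 0 at construction; duplicate literals are merged.
#'
#' @param variables Character vector of variable names, in declaration order.
#' @param funcs Named list, one entry per variable: either
#'   `list(const = 0L)` / `list(const = 1L)`, or
#'   `list(reg = <character vector of regulator names>,
#'         sign = <integer vector of +1/-1>)` with at least one regulator.
#' @return An object of class `andnot_network`.
#' @examples
#' h <- andnot_network(c("x1", "x2"),
#'   list(x1 = list(reg = "x2", sign = -1L), x2 = list(reg = "x1", sign = -1L)))
#' enumerate_exhaustive(h)
#' @export
andnot_network <- function(variables, funcs) {
  stopifnot(is.character(variables), length(variables) >= 1L,
            !anyDuplicated(variables), is.list(funcs))
  if (!setequal(names(funcs), variables) || length(funcs) != length(variables)) {
    stop("exactly one update function per declared variable is required")
  }
  funcs <- funcs[variables]
  out <- vector("list", length(variables))
  names(out) <- variables
  for (v in variables) {
    fn <- funcs[[v]]
    if (!is.null(fn$const)) {
      cv <- as.integer(fn$const)
      stopifnot(length(cv) == 1L, cv %in% c(0L, 1L))
      out[[v]] <- list(const = cv)
    } else {
      reg <- as.character(fn$reg)
      sign <- as.integer(fn$sign)
      if (length(reg) == 0L) stop("node '", v, "': empty conjunction; use a constant")
      if (length(reg) != length(sign) || !all(sign %in% c(-1L, 1L))) {
        stop("node '", v, "': regulators and signs must align, signs in {-1,+1}")
      }
      bad <- setdiff(reg, variables)
      if (length(bad)) stop("node '", v, "' references undeclared variable(s): ",
                            paste(bad, collapse = ", "))
      nf <- normalize_conjunction(reg, sign)
      out[[v]] <- nf
    }
  }
  structure(list(variables = variables, funcs = out), class = "andnot_network")
}

# Merge duplicate literals; x AND NOT x -> constant 0.
normalize_conjunction <- function(reg, sign) {
  if (anyDuplicated(reg)) {
    keep_reg <- character(0)
    keep_sign <- integer(0)
    for (i in seq_along(reg)) {
      j <- match(reg[[i]], keep_reg)
      if (is.na(j)) {
        keep_reg <- c(keep_reg, reg[[i]])
        keep_sign <- c(keep_sign, sign[[i]])
      } else if (keep_sign[[j]] != sign[[i]]) {
        return(list(const = 0L))
      }
    }
    reg <- keep_reg
    sign <- keep_sign
  }
  list(reg = reg, sign = sign)
}

#' @export
print.andnot_network <- function(x, ...) {
  cat("AND-NOT network with", length(x$variables), "nodes\n")
  for (v in x$variables) {
    fn <- x$funcs[[v]]
    if (!is.null(fn$const)) {
      cat("  ", v, " = ", fn$const, "\n", sep = "")
    } else {
      lits <- ifelse(fn$sign > 0L, fn$reg, paste0("!", fn$reg))
      cat("  ", v, " = ", paste(lits, collapse = " & "), "\n", sep = "")
    }
  }
  invisible(x)
}

network_variables <- function(network) network$variables

is_boolean_network <- function(x) inherits(x, "boolean_network")
is_andnot_network <- function(x) inherits(x, "andnot_network")

# Vectorized synchronous update. `states` is a logical matrix with one row
# per state and one column per variable (declaration order). Returns a
# logical matrix of the same shape with the updated states.
eval_states <- function(network, states) {
  nvar <- length(network$variables)
  stopifnot(is.matrix(states), ncol(states) == nvar)
  nr <- nrow(states)
  out <- matrix(FALSE, nrow = nr, ncol = nvar)
  if (is_boolean_network(network)) {
    env <- new.env(parent = baseenv())
    for (j in seq_len(nvar)) assign(network$variables[[j]], states[, j], envir = env)
    for (j in seq_len(nvar)) {
      v <- eval(network$calls[[j]], env)
      if (length(v) == 1L) v <- rep(v, nr)  # constant rule
      out[, j] <- v
    }
  } else if (is_andnot_network(network)) {
    idx <- seq_len(nvar)
    names(idx) <- network$variables
    for (j in seq_len(nvar)) {
      fn <- network$funcs[[j]]
      if (!is.null(fn$const)) {
        out[, j] <- fn$const == 1L
      } else {
        acc <- rep(TRUE, nr)
        ri <- idx[fn$reg]
        for (k in seq_along(ri)) {
          acc <- acc & (if (fn$sign[[k]] > 0L) states[, ri[[k]]] else !states[, ri[[k]]])
        }
        out[, j] <- acc
      }
    }
  } else {
    stop("expected a boolean_network or andnot_network")
  }
  out
}

#' Apply one synchronous update step
#'
#' Evaluates every update function of the network on the given state,
#' returning the successor state under synchronous update. The input is not
#' modified.
#'
#' @param network A `boolean_network` or `andnot_network`.
#' @param state Numeric/integer vector of 0/1 values, ordered by the
#'   network's variable declaration order, with one entry per variable.
#' @return Integer 0/1 vector: the updated state.
#' @export
evaluate_network <- function(network, state) {
  nvar <- length(network$variables)
  if (length(state) != nvar) {
    stop("state length (", length(state), ") does not match network size (", nvar, ")")
  }
  if (!all(state %in% c(0, 1))) stop("state entries must be 0 or 1")
  m <- matrix(as.logical(state), nrow = 1L)
  as.integer(eval_states(network, m)[1L, ])
}

#' Test whether a state is a steady state
#'
#' A steady state (fixed point) is a state x with f(x) = x under synchronous
#' update of all nodes.
#'
#' @inheritParams evaluate_network
#' @return `TRUE` if the state is fixed by the network's update map.
#' @export
is_steady_state <- function(network, state) {
  identical(evaluate_network(network, state), as.integer(state))
}

#' Construct a signed directed graph
#'
#' @param nodes Character vector of node names.
#' @param from,to Character vectors of edge endpoints.
#' @param sign Character vector of `"+"` / `"-"` edge signs.
#' @return An object of class `signed_digraph` with fields `nodes` and
#'   `edges` (a data frame with columns `from`, `to`, `sign`).
#' @export
signed_digraph <- function(nodes, from = character(0), to = character(0),
                           sign = character(0)) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes),
            length(from) == length(to), length(from) == length(sign),
            all(sign %in% c("+", "-")),
            all(from %in% nodes), all(to %in% nodes))
  edges <- data.frame(from = as.character(from), to = as.character(to),
                      sign = as.character(sign), stringsAsFactors = FALSE)
  if (anyDuplicated(edges)) stop("duplicate signed edge")
  o <- order(edges$from, edges$to, edges$sign)
  structure(list(nodes = nodes, edges = edges[o, , drop = FALSE]),
            class = "signed_digraph")
}

#' @export
print.signed_digraph <- function(x, ...) {
  cat("Signed digraph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Wiring diagram of an AND-NOT network
#'
#' The signed wiring diagram has one edge per signed regulator: an edge
#' `x -> y` with sign `+` when `x` appears unnegated in `y`'s conjunction and
#' sign `-` when it appears negated. Constant nodes have in-degree 0.
#'
#' @param network An `andnot_network`.
#' @return A `signed_digraph`.
#' @export
wiring_diagram <- function(network) {
  stopifnot(is_andnot_network(network))
  from <- character(0); to <- character(0); sg <- character(0)
  for (v in network$variables) {
    fn <- network$funcs[[v]]
    if (is.null(fn$const)) {
      from <- c(from, fn$reg)
      to <- c(to, rep(v, length(fn$reg)))
      sg <- c(sg, ifelse(fn$sign > 0L, "+", "-"))
    }
  }
  signed_digraph(network$variables, from, to, sg)
}

#' Construct a set of steady states
#'
#' Stores states as a 0/1 matrix with one row per state and one column per
#' variable, deduplicated and sorted ascending as binary integers (first
#' variable = most significant bit), so output order is deterministic.
#'
#' @param states 0/1 matrix (or vector for a single state / `NULL` for the
#'   empty set), columns ordered by `variables`.
#' @param variables Character vector naming the columns.
#' @return An object of class `steady_state_set`.
#' @export
steady_state_set <- function(states, variables) {
  stopifnot(is.character(variables), length(variables) >= 1L)
  if (is.null(states) || (is.matrix(states) && nrow(states) == 0L) || length(states) == 0L) {
    states <- matrix(integer(0), nrow = 0L, ncol = length(variables))
  }
  if (!is.matrix(states)) states <- matrix(as.integer(states), nrow = 1L)
  storage.mode(states) <- "integer"
  stopifnot(ncol(states) == length(variables), all(states %in% c(0L, 1L)))
  colnames(states) <- variables
  if (nrow(states) > 1L) {
    # sort ascending as binary integers (first variable = MSB), then drop
    # adjacent duplicates; radix order on columns avoids per-row string keys
    o <- do.call(order, lapply(seq_len(ncol(states)), function(j) states[, j]))
    states <- states[o, , drop = FALSE]
    dup <- c(FALSE, rowSums(states[-1L, , drop = FALSE] !=
                              states[-nrow(states), , drop = FALSE]) == 0L)
    states <- states[!dup, , drop = FALSE]
  }
  structure(list(states = states, variables = variables),
            class = "steady_state_set")
}

#' @export
print.steady_state_set <- function(x, ...) {
  n <- nrow(x$states)
  cat("Steady-state set:", n, if (n == 1L) "state" else "states",
      "over", length(x$variables), "variables\n")
  if (n > 0L && n <= 32L) {
    cat(paste0("  ", apply(x$states, 1L, paste, collapse = "")), sep = "\n")
  }
  invisible(x)
}

#' @export
length.steady_state_set <- function(x) nrow(x$states)

#' Compare two steady-state sets
#'
#' @param a,b `steady_state_set` objects over the same variables.
#' @return `TRUE` if both sets contain exactly the same states.
#' @export
same_steady_states <- function(a, b) {
  stopifnot(inherits(a, "steady_state_set"), inherits(b, "steady_state_set"))
  identical(a$variables, b$variables) && identical(unname(a$states), unname(b$states))
}
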