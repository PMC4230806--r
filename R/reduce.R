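# Steady-state-preserving reduction of an AND-NOT network's signed wiring
# diagram, with a replayable trace for backtracking.
#
# Four motif rules are applied to a fixpoint; each preserves a bijection
# between the steady states of the network before and after:
#   R1 constant propagation: a node with a constant function is substituted
#      into its targets (a satisfied literal is dropped; an unsatisfied one
#      makes the target constant 0) and removed.
#   R2 unit-input elimination: a node y whose conjunction is a single literal
#      of another node x (and no self-loop) is an exact alias y = x or
#      y = !x at any fixed point; every occurrence of y is replaced by the
#      sign-composed literal of x and y is removed. Opposite-sign collisions
#      make the target constant 0.
#   R3 sink elimination: a node with out-degree 0 and no self-loop constrains
#      nothing; its fixed-point value is determined by its conjunction, so it
#      is removed and reconstructed during backtracking.
#   R4 feed-forward redundancy: with edges x->y (sign s), y->z (sign +) and
#      x->z (sign s), the direct x-literal in z is absorbed: y = 1 at a fixed
#      point already forces the x-literal to 1, and y = 0 forces z = 0
#      regardless. The edge x->z is deleted (no variable is removed).
#
# Nodes with self-loops are never removed (except via R1 when their function
# has become constant); in particular environmental inputs written as
# `x = x` survive to the algebra stage, where they become free variables.

#' Reduce an AND-NOT network while preserving steady states
#'
#' Applies the rule set R1-R4 (constant propagation, unit-input elimination,
#' sink elimination, feed-forward edge redundancy) to a fixpoint, in a
#' deterministic order (constants first, then aliases, then redundant edges,
#' then sinks; ties broken by declaration order). The reduced network `h` is
#' an AND-NOT network over a subset of the input's variables, and the
#' recorded trace replays in reverse to lift any steady state of `h` to a
#' steady state of the input (see [backtrack_states()]); this lift is a
#' bijection between the two steady-state sets.
#'
#' @param g An `andnot_network`.
#' @return A list with components `network` (the reduced `andnot_network`,
#'   or `NULL` when every variable was eliminated), `trace` (a
#'   `reduction_trace`: ordered removal records plus per-rule application
#'   counts), and `input` (the original network, kept for backtracking).
#' @examples
#' g <- boolean_to_andnot(parse_rules("x1 = !x2\nx2 = x3\nx3 = x3"))$network
#' reduce_andnot(g)$network
#' @export
reduce_andnot <- function(g) {
  stopifnot(is_andnot_network(g))
  vars <- g$variables
  m <- length(vars)
  idx_of <- seq_len(m)
  names(idx_of) <- vars

  cst <- rep(NA_integer_, m)
  reg <- vector("list", m)
  sgn <- vector("list", m)
  targets <- vector("list", m)  # maintained as a superset; entries re-checked
  for (i in seq_len(m)) {
    fn <- g$funcs[[i]]
    if (!is.null(fn$const)) {
      cst[[i]] <- fn$const
    } else {
      reg[[i]] <- unname(idx_of[fn$reg])
      sgn[[i]] <- fn$sign
    }
  }
  for (i in seq_len(m)) {
    for (r in reg[[i]]) targets[[r]] <- c(targets[[r]], i)
  }

  alive <- rep(TRUE, m)
  records <- list()
  counts <- c(R1 = 0L, R2 = 0L, R3 = 0L, R4 = 0L)

  const_q <- sort(which(!is.na(cst)))
  unit_q <- integer(0)

  push_const <- function(i) const_q <<- unique(sort(c(const_q, i)))
  push_unit <- function(i) unit_q <<- unique(sort(c(unit_q, i)))

  record <- function(rec) records[[length(records) + 1L]] <<- rec

  set_const <- function(z, value) {
    cst[[z]] <<- value
    reg[z] <<- list(NULL)   # [z] <- list(NULL) keeps the slot, [[z]] <- NULL would drop it
    sgn[z] <<- list(NULL)
    push_const(z)
  }

  # Drop the literal of node y from z's conjunction (it is satisfied).
  drop_literal <- function(z, pos) {
    reg[[z]] <<- reg[[z]][-pos]
    sgn[[z]] <<- sgn[[z]][-pos]
    if (length(reg[[z]]) == 0L) {
      set_const(z, 1L)
    } else if (length(reg[[z]]) == 1L) {
      push_unit(z)
    }
  }

  run_r1 <- function() {
    while (length(const_q) > 0L) {
      y <- const_q[[1L]]
      const_q <<- const_q[-1L]
      if (!alive[[y]]) next
      cv <- cst[[y]]
      for (z in targets[[y]]) {
        if (!alive[[z]] || is.na(cst[[z]]) == FALSE) next
        pos <- match(y, reg[[z]])
        if (is.na(pos)) next
        satisfied <- (sgn[[z]][[pos]] > 0L) == (cv == 1L)
        if (satisfied) drop_literal(z, pos) else set_const(z, 0L)
      }
      alive[[y]] <<- FALSE
      record(list(var = vars[[y]], kind = "constant", value = cv))
      counts[["R1"]] <<- counts[["R1"]] + 1L
    }
  }

  run_r2 <- function() {
    applied <- FALSE
    while (length(unit_q) > 0L) {
      if (length(const_q) > 0L) run_r1()
      if (length(unit_q) == 0L) break
      y <- unit_q[[1L]]
      unit_q <<- unit_q[-1L]
      if (!alive[[y]] || !is.na(cst[[y]]) || length(reg[[y]]) != 1L) next
      x <- reg[[y]][[1L]]
      if (x == y) next  # self-input or negative self-loop: never reduced here
      s_y <- sgn[[y]][[1L]]
      for (z in targets[[y]]) {
        if (!alive[[z]] || z == y || !is.na(cst[[z]])) next
        pos <- match(y, reg[[z]])
        if (is.na(pos)) next
        composed <- sgn[[z]][[pos]] * s_y
        xpos <- match(x, reg[[z]])
        if (!is.na(xpos)) {
          if (sgn[[z]][[xpos]] == composed) {
            drop_literal(z, pos)              # duplicate literal: merge
          } else {
            set_const(z, 0L)                  # x & !x: contradiction
          }
        } else {
          reg[[z]][[pos]] <<- x
          sgn[[z]][[pos]] <<- composed
          targets[[x]] <<- c(targets[[x]], z)
        }
      }
      alive[[y]] <<- FALSE
      record(list(var = vars[[y]], kind = "alias", source = vars[[x]], sign = s_y))
      counts[["R2"]] <<- counts[["R2"]] + 1L
      applied <- TRUE
    }
    applied
  }

  run_r4 <- function() {
    changed <- FALSE
    for (z in which(alive)) {
      if (!is.na(cst[[z]])) next
      repeat {
        dropped <- FALSE
        rz <- reg[[z]]
        sz <- sgn[[z]]
        for (k in seq_along(rz)) {
          y <- rz[[k]]
          if (sz[[k]] != 1L || y == z || !alive[[y]] || !is.na(cst[[y]])) next
          ry <- reg[[y]]
          sy <- sgn[[y]]
          for (q in seq_along(ry)) {
            x <- ry[[q]]
            if (x == z || x == y) next
            xpos <- match(x, rz)
            if (!is.na(xpos) && sz[[xpos]] == sy[[q]]) {
              drop_literal(z, xpos)
              counts[["R4"]] <<- counts[["R4"]] + 1L
              changed <- TRUE
              dropped <- TRUE
              break
            }
          }
          if (dropped) break
        }
        if (!dropped || !is.na(cst[[z]]) || length(reg[[z]]) < 2L) break
      }
    }
    changed
  }

  run_r3 <- function() {
    changed <- FALSE
    outdeg <- rep(0L, m)
    for (z in which(alive)) {
      for (r in reg[[z]]) outdeg[[r]] <- outdeg[[r]] + 1L
    }
    queue <- sort(which(alive & outdeg == 0L & is.na(cst)))
    while (length(queue) > 0L) {
      y <- queue[[1L]]
      queue <- queue[-1L]
      if (!alive[[y]]) next
      record(list(var = vars[[y]], kind = "sink",
                  reg = vars[reg[[y]]], sign = sgn[[y]]))
      for (r in reg[[y]]) {
        outdeg[[r]] <- outdeg[[r]] - 1L
        if (alive[[r]] && outdeg[[r]] == 0L && is.na(cst[[r]])) {
          queue <- sort(unique(c(queue, r)))
        }
      }
      alive[[y]] <<- FALSE
      counts[["R3"]] <<- counts[["R3"]] + 1L
      changed <- TRUE
    }
    changed
  }

  # every rule application removes a node or an edge, so the fixpoint loop
  # can cycle at most m + |edges| times; exceeding that signals a rule bug
  max_cycles <- m + sum(lengths(reg)) + 2L
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    if (cycles > max_cycles) stop("internal error: reduction fixpoint loop did not terminate")
    run_r1()
    unit_q <- sort(which(alive & is.na(cst) &
                           vapply(seq_len(m), function(i) length(reg[[i]]) == 1L, logical(1))))
    any_r2 <- run_r2()
    any_r4 <- run_r4()
    if (any_r4) next
    any_r3 <- run_r3()
    if (!any_r3 && !any_r2 && length(const_q) == 0L) break
  }

  keep <- which(alive)
  h <- NULL
  if (length(keep) > 0L) {
    hv <- vars[keep]
    hf <- vector("list", length(keep))
    names(hf) <- hv
    for (j in seq_along(keep)) {
      i <- keep[[j]]
      hf[[j]] <- if (!is.na(cst[[i]])) list(const = cst[[i]])
                 else list(reg = vars[reg[[i]]], sign = sgn[[i]])
    }
    h <- andnot_network(hv, hf)
  }
  trace <- structure(list(records = records, counts = counts,
                          nodes_before = m, nodes_after = length(keep)),
                     class = "reduction_trace")
  list(network = h, trace = trace, input = g)
}

#' @export
print.reduction_trace <- function(x, ...) {
  cat("Reduction trace:", x$nodes_before, "->", x$nodes_after, "nodes;",
      "rule applications:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Lift steady states of the reduced network back to the full network
#'
#' Replays the reduction trace in reverse: each removed variable is assigned
#' from its record (a constant its value, an alias the sign-applied value of
#' its source, a sink its recorded conjunction evaluated on already-known
#' values). Every reconstructed state is verified against the full network
#' with [is_steady_state()]; a failure indicates an internal error in a
#' reduction rule and is reported as such.
#'
#' @param trace A `reduction_trace` from [reduce_andnot()].
#' @param states_h A [steady_state_set()] of the reduced network, or `NULL`
#'   when the reduction eliminated every variable (the empty network has
#'   exactly one, empty, steady state).
#' @param g The original `andnot_network` the trace was produced from.
#' @return A [steady_state_set()] over `g`'s variables, of the same size.
#' @export
backtrack_states <- function(trace, states_h, g) {
  stopifnot(inherits(trace, "reduction_trace"), is_andnot_network(g))
  if (is.null(states_h)) {
    hvars <- character(0)
    mat <- matrix(integer(0), nrow = 1L, ncol = 0L)
  } else {
    stopifnot(inherits(states_h, "steady_state_set"))
    hvars <- states_h$variables
    mat <- states_h$states
  }
  r <- nrow(mat)
  cols <- vector("list", length(hvars))
  names(cols) <- hvars
  for (j in seq_along(hvars)) cols[[j]] <- mat[, j]

  for (rec in rev(trace$records)) {
    v <- rec$var
    col <- switch(rec$kind,
      constant = rep(rec$value, r),
      alias = {
        src <- cols[[rec$source]]
        if (is.null(src)) stop("internal consistency error: alias source '",
                               rec$source, "' not yet reconstructed")
        if (rec$sign > 0L) src else 1L - src
      },
      sink = {
        acc <- rep(TRUE, r)
        for (k in seq_along(rec$reg)) {
          src <- cols[[rec$reg[[k]]]]
          if (is.null(src)) stop("internal consistency error: sink input '",
                                 rec$reg[[k]], "' not yet reconstructed")
          acc <- acc & (if (rec$sign[[k]] > 0L) src == 1L else src == 0L)
        }
        as.integer(acc)
      },
      stop("unknown trace record kind: ", rec$kind)
    )
    cols[[v]] <- col
  }

  if (!setequal(names(cols), g$variables)) {
    stop("internal consistency error: reconstructed variables do not match the network")
  }
  full <- matrix(0L, nrow = r, ncol = length(g$variables))
  for (j in seq_along(g$variables)) full[, j] <- cols[[g$variables[[j]]]]
  if (r > 0L) {
    upd <- eval_states(g, full == 1L)
    if (!all(upd == (full == 1L))) {
      stop("internal consistency error: a backtracked state is not steady in g")
    }
  }
  steady_state_set(full, g$variables)
}
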