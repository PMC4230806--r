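# Conversion of an arbitrary Boolean network into an AND-NOT network with the
# same steady states (under projection), and the reverse projection.
#
# The rewrite is structural on the negation normal form of each rule:
#   * a literal maps to itself;
#   * an AND of parts maps to the conjunction of the parts' literals, with an
#     auxiliary node introduced for any part that is not itself a literal;
#   * an OR of parts e1,...,ek maps to the negated literal of an auxiliary
#     node a defined by De Morgan as a = !l(e1) & ... & !l(ek).
# Auxiliary variables are appended after the original n variables, so the
# steady states of the original network are exactly the projections of the
# steady states of the AND-NOT network onto the first n coordinates, and the
# projection is a bijection between the two steady-state sets.

#' Transform a Boolean network into an AND-NOT network
#'
#' Rewrites every update rule using only conjunction and negation, introducing
#' auxiliary variables for OR-subexpressions (by De Morgan duality) and for
#' non-literal conjuncts. For example `x1 = !x2 & (x3 | x4)` becomes
#' `x1 = !x2 & !a` with a new node `a = !x3 & !x4`. Constants are folded and
#' XOR is expanded before conversion, and a network already in AND-NOT form
#' gains no auxiliary variables.
#'
#' The original variables occupy the first `n` coordinates of the result;
#' projecting the AND-NOT network's steady states onto those coordinates is a
#' bijection onto the steady states of the input network.
#'
#' @param f A `boolean_network`.
#' @param aux_prefix Prefix for auxiliary variable names (a counter is
#'   appended; names are made unique against the declared variables).
#' @param max_width Conjunctions wider than this are split into a chain of
#'   sub-auxiliaries. The square-free GF(2) polynomial of a conjunction of
#'   `w` negated literals has 2^w monomials, so bounding `w` keeps every
#'   polynomial handed to the algebra stage small at the cost of a few
#'   extra variables.
#' @return A list with components `network` (the `andnot_network` `g`) and
#'   `map` (a `variable_map`: `n` originals, the auxiliary names, and each
#'   auxiliary's defining conjunction).
#' @examples
#' f <- parse_rules("x1 = !x2 & (x3 | x4)\nx2 = x1\nx3 = x3\nx4 = x4")
#' boolean_to_andnot(f)$network
#' @export
boolean_to_andnot <- function(f, aux_prefix = "_aux", max_width = 6L) {
  stopifnot(is_boolean_network(f), max_width >= 2L)
  vars <- f$variables
  n <- length(vars)
  aux_names <- character(0)
  aux_funcs <- list()
  counter <- 0L

  new_aux_raw <- function(reg, sign) {
    repeat {
      counter <<- counter + 1L
      nm <- paste0(aux_prefix, counter)
      if (!(nm %in% vars) && !(nm %in% aux_names)) break
    }
    aux_names[[length(aux_names) + 1L]] <<- nm
    aux_funcs[[nm]] <<- list(reg = reg, sign = sign)
    nm
  }

  # chunk a wide conjunction into sub-auxiliaries of bounded width
  cap_width <- function(reg, sign) {
    while (length(reg) > max_width) {
      head_idx <- seq_len(max_width)
      nm <- new_aux_raw(reg[head_idx], sign[head_idx])
      reg <- c(nm, reg[-head_idx])
      sign <- c(1L, sign[-head_idx])
    }
    list(reg = reg, sign = sign)
  }

  new_aux <- function(reg, sign) {
    cw <- cap_width(reg, sign)
    new_aux_raw(cw$reg, cw$sign)
  }

  # Returns list(reg=, sign=) for a single literal equivalent to `e` at a
  # steady state, creating auxiliary nodes as needed. `e` is in NNF.
  as_literal <- function(e) {
    switch(e$kind,
      VAR = list(reg = e$name, sign = 1L),
      NOT = list(reg = e$args[[1L]]$name, sign = -1L),
      AND = {
        lits <- lapply(e$args, as_literal)
        list(reg = new_aux(vapply(lits, `[[`, character(1), "reg"),
                           vapply(lits, `[[`, integer(1), "sign")),
             sign = 1L)
      },
      OR = {
        lits <- lapply(e$args, as_literal)
        list(reg = new_aux(vapply(lits, `[[`, character(1), "reg"),
                           -vapply(lits, `[[`, integer(1), "sign")),
             sign = -1L)
      },
      stop("unexpected kind in AND-NOT conversion: ", e$kind)
    )
  }

  funcs <- vector("list", n)
  names(funcs) <- vars
  for (v in vars) {
    e <- to_nnf(f$exprs[[v]])
    funcs[[v]] <- switch(e$kind,
      CONST = list(const = e$value),
      VAR = ,
      NOT = {
        l <- as_literal(e)
        list(reg = l$reg, sign = l$sign)
      },
      AND = {
        lits <- lapply(e$args, as_literal)
        cap_width(vapply(lits, `[[`, character(1), "reg"),
                  vapply(lits, `[[`, integer(1), "sign"))
      },
      OR = {
        l <- as_literal(e)
        list(reg = l$reg, sign = l$sign)
      },
      stop("unexpected kind: ", e$kind)
    )
  }

  g <- andnot_network(c(vars, aux_names), c(funcs, aux_funcs))
  map <- structure(list(n = n, original = vars, aux = aux_names,
                        aux_funcs = aux_funcs),
                   class = "variable_map")
  list(network = g, map = map)
}

#' @export
print.variable_map <- function(x, ...) {
  cat("Variable map:", x$n, "original variables,", length(x$aux), "auxiliary\n")
  invisible(x)
}

#' Project steady states of the AND-NOT network back to the original variables
#'
#' Truncates each steady state of the transformed network to the first `n`
#' coordinates (the original variables). On steady states this projection is
#' injective; a duplicate after projection indicates an internal error in the
#' transform and is reported as such.
#'
#' @param states_g A [steady_state_set()] over the transformed variables.
#' @param map The `variable_map` returned by [boolean_to_andnot()].
#' @return A [steady_state_set()] over the original variables, of the same
#'   size as the input.
#' @export
project_steady_states <- function(states_g, map) {
  stopifnot(inherits(states_g, "steady_state_set"), inherits(map, "variable_map"))
  if (!identical(states_g$variables[seq_len(map$n)], map$original)) {
    stop("state variable order does not start with the original variables")
  }
  proj <- states_g$states[, seq_len(map$n), drop = FALSE]
  out <- steady_state_set(proj, map$original)
  if (nrow(out$states) != nrow(states_g$states)) {
    stop("internal consistency error: projection of steady states is not injective")
  }
  out
}
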