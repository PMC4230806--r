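# Boolean expression trees.
#
# An expression is a plain list with a `kind` field:
#   VAR   : list(kind = "VAR",  name = <character>)
#   CONST : list(kind = "CONST", value = 0L or 1L)
#   NOT   : list(kind = "NOT",  args = list(<one child>))
#   AND / OR / XOR : list(kind = ..., args = list(<two or more children>))
# Trees are finite, acyclic, and reference only variables declared by the
# enclosing network.

#' Build Boolean expression nodes
#'
#' Low-level constructors for update-rule expression trees. Most users will
#' obtain expressions by parsing rule text with [parse_rules()]; these are
#' exported for programmatic model construction.
#'
#' @param name Variable name (character scalar).
#' @param value Constant value, 0 or 1.
#' @param ... Child expressions (at least two for `b_and`, `b_or`, `b_xor`).
#' @param e Child expression for `b_not`.
#' @return An expression node (a list with a `kind` field).
#' @examples
#' e <- b_and(b_not(b_var("x2")), b_or(b_var("x3"), b_var("x4")))
#' deparse_expression(e)
#' @export
b_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  list(kind = "VAR", name = name)
}

#' @rdname b_var
#' @export
b_const <- function(value) {
  value <- as.integer(value)
  stopifnot(length(value) == 1L, value %in% c(0L, 1L))
  list(kind = "CONST", value = value)
}

#' @rdname b_var
#' @export
b_not <- function(e) list(kind = "NOT", args = list(e))

.b_nary <- function(kind, parts) {
  stopifnot(length(parts) >= 1L)
  if (length(parts) == 1L) return(parts[[1L]])
  list(kind = kind, args = parts)
}

#' @rdname b_var
#' @export
b_and <- function(...) .b_nary("AND", list(...))

#' @rdname b_var
#' @export
b_or <- function(...) .b_nary("OR", list(...))

#' @rdname b_var
#' @export
b_xor <- function(...) .b_nary("XOR", list(...))

is_expression <- function(e) is.list(e) && !is.null(e$kind)

#' Variables referenced by an expression
#'
#' @param e An expression tree.
#' @return Character vector of distinct variable names, in first-occurrence
#'   order (left-to-right).
#' @export
expression_vars <- function(e) {
  out <- character(0)
  walk <- function(x) {
    if (x$kind == "VAR") {
      out[[length(out) + 1L]] <<- x$name
    } else if (x$kind != "CONST") {
      for (a in x$args) walk(a)
    }
  }
  walk(e)
  unique(out)
}

# Rewrite a XOR b (n-ary, left fold) into AND/OR/NOT:
# a XOR b -> (a AND NOT b) OR (NOT a AND b).
expand_xor <- function(e) {
  switch(e$kind,
    VAR = ,
    CONST = e,
    NOT = list(kind = "NOT", args = list(expand_xor(e$args[[1L]]))),
    AND = ,
    OR = list(kind = e$kind, args = lapply(e$args, expand_xor)),
    XOR = {
      parts <- lapply(e$args, expand_xor)
      acc <- parts[[1L]]
      for (i in seq_along(parts)[-1L]) {
        b <- parts[[i]]
        acc <- list(kind = "OR", args = list(
          list(kind = "AND", args = list(acc, list(kind = "NOT", args = list(b)))),
          list(kind = "AND", args = list(list(kind = "NOT", args = list(acc)), b))
        ))
      }
      acc
    },
    stop("unknown expression kind: ", e$kind)
  )
}

# Constant folding: evaluates away CONST children (x AND 0 -> 0, x OR 0 -> x,
# NOT 1 -> 0, ...). Applied before the AND-NOT conversion so that constants
# never spawn spurious auxiliary variables.
fold_constants <- function(e) {
  switch(e$kind,
    VAR = ,
    CONST = e,
    NOT = {
      a <- fold_constants(e$args[[1L]])
      if (a$kind == "CONST") b_const(1L - a$value) else list(kind = "NOT", args = list(a))
    },
    AND = {
      parts <- lapply(e$args, fold_constants)
      keep <- list()
      for (p in parts) {
        if (p$kind == "CONST") {
          if (p$value == 0L) return(b_const(0L))
        } else keep[[length(keep) + 1L]] <- p
      }
      if (length(keep) == 0L) b_const(1L) else .b_nary("AND", keep)
    },
    OR = {
      parts <- lapply(e$args, fold_constants)
      keep <- list()
      for (p in parts) {
        if (p$kind == "CONST") {
          if (p$value == 1L) return(b_const(1L))
        } else keep[[length(keep) + 1L]] <- p
      }
      if (length(keep) == 0L) b_const(0L) else .b_nary("OR", keep)
    },
    XOR = {
      parts <- lapply(e$args, fold_constants)
      flip <- 0L
      keep <- list()
      for (p in parts) {
        if (p$kind == "CONST") flip <- bitwXor(flip, p$value)
        else keep[[length(keep) + 1L]] <- p
      }
      if (length(keep) == 0L) return(b_const(flip))
      acc <- .b_nary("XOR", keep)
      if (flip == 1L) list(kind = "NOT", args = list(acc)) else acc
    },
    stop("unknown expression kind: ", e$kind)
  )
}

#' Negation normal form
#'
#' Rewrites an expression so that negations apply only to variables, using
#' De Morgan's laws and double-negation elimination; nested AND-under-AND and
#' OR-under-OR are flattened. XOR nodes are expanded to AND/OR/NOT first and
#' constants are folded, so the result contains only variables, literals,
#' AND and OR (or is a bare constant). The result has the same truth table
#' as the input.
#'
#' @param e An expression tree.
#' @return A logically equivalent expression in negation normal form.
#' @examples
#' deparse_expression(to_nnf(b_not(b_and(b_var("x"), b_var("y")))))
#' @export
to_nnf <- function(e) {
  e <- fold_constants(expand_xor(e))
  nnf <- function(x, neg) {
    switch(x$kind,
      VAR = if (neg) list(kind = "NOT", args = list(x)) else x,
      CONST = b_const(if (neg) 1L - x$value else x$value),
      NOT = nnf(x$args[[1L]], !neg),
      AND = ,
      OR = {
        kind <- x$kind
        if (neg) kind <- if (kind == "AND") "OR" else "AND"
        parts <- lapply(x$args, nnf, neg = neg)
        flat <- list()
        for (p in parts) {
          if (p$kind == kind) flat <- c(flat, p$args) else flat[[length(flat) + 1L]] <- p
        }
        .b_nary(kind, flat)
      },
      stop("unexpected kind in NNF rewrite: ", x$kind)
    )
  }
  nnf(e, FALSE)
}

# Compile an expression into an R call evaluating on logical vectors
# (variables bound in an environment; vectorized over states).
expr_to_call <- function(e) {
  switch(e$kind,
    VAR = as.name(e$name),
    CONST = if (e$value == 1L) TRUE else FALSE,
    NOT = call("!", expr_to_call(e$args[[1L]])),
    AND = Reduce(function(a, b) call("&", a, b), lapply(e$args, expr_to_call)),
    OR = Reduce(function(a, b) call("|", a, b), lapply(e$args, expr_to_call)),
    XOR = Reduce(function(a, b) call("xor", a, b), lapply(e$args, expr_to_call)),
    stop("unknown expression kind: ", e$kind)
  )
}

#' Render an expression as rule text
#'
#' Produces the textual form used by rule files (`!` for NOT, `&` for AND,
#' `|` for OR, `^` for XOR), inserting parentheses only where precedence
#' (NOT > AND > XOR > OR) requires them.
#'
#' @param e An expression tree.
#' @return A character scalar.
#' @export
deparse_expression <- function(e) {
  prec <- c(OR = 1L, XOR = 2L, AND = 3L, NOT = 4L, VAR = 5L, CONST = 5L)
  render <- function(x) {
    p <- prec[[x$kind]]
    txt <- switch(x$kind,
      VAR = x$name,
      CONST = as.character(x$value),
      NOT = {
        child <- x$args[[1L]]
        inner <- render(child)
        if (prec[[child$kind]] < p) inner <- paste0("(", inner, ")")
        paste0("!", inner)
      },
      {
        opsym <- c(AND = " & ", OR = " | ", XOR = " ^ ")[[x$kind]]
        parts <- vapply(x$args, function(a) {
          inner <- render(a)
          if (prec[[a$kind]] < p) paste0("(", inner, ")") else inner
        }, character(1))
        paste(parts, collapse = opsym)
      }
    )
    txt
  }
  render(e)
}
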