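# Writers: rule files, steady-state sets, and signed-digraph exports.

#' Render a network as rule text
#'
#' Writes one `name = expression` line per node in declaration order. The
#' output round-trips through [parse_rules()] to a network whose update
#' functions have the same truth tables.
#'
#' @param network A `boolean_network` or `andnot_network`.
#' @param path Optional file path; when given, the text is also written there.
#' @return The rule text as a single character scalar (invisibly when `path`
#'   is given).
#' @export
write_rules <- function(network, path = NULL) {
  if (is_boolean_network(network)) {
    body <- vapply(network$variables, function(v) {
      paste0(v, " = ", deparse_expression(network$exprs[[v]]))
    }, character(1))
  } else if (is_andnot_network(network)) {
    body <- vapply(network$variables, function(v) {
      fn <- network$funcs[[v]]
      rhs <- if (!is.null(fn$const)) {
        as.character(fn$const)
      } else {
        paste(ifelse(fn$sign > 0L, fn$reg, paste0("!", fn$reg)), collapse = " & ")
      }
      paste0(v, " = ", rhs)
    }, character(1))
  } else {
    stop("expected a boolean_network or andnot_network")
  }
  text <- paste0(paste(body, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", text), path)
    return(invisible(text))
  }
  text
}

#' Write a steady-state set as text
#'
#' @param states A [steady_state_set()].
#' @param format One of `"csv"` (one row per state, one column per variable),
#'   `"bits"` (one bitstring per line, declaration order left to right), or
#'   `"json"` (array of name-to-value objects). States are emitted sorted
#'   ascending as binary integers, so output is deterministic.
#' @param path Optional file path to also write the text to.
#' @return Character scalar with the formatted text.
#' @export
write_steady_states <- function(states, format = c("csv", "json", "bits"),
                                path = NULL) {
  stopifnot(inherits(states, "steady_state_set"))
  format <- match.arg(format)
  m <- states$states
  text <- switch(format,
    csv = {
      header <- paste(states$variables, collapse = ",")
      if (nrow(m) == 0L) paste0(header, "\n")
      else paste0(header, "\n", paste(apply(m, 1L, paste, collapse = ","), collapse = "\n"), "\n")
    },
    bits = {
      if (nrow(m) == 0L) ""
      else paste0(paste(apply(m, 1L, paste, collapse = ""), collapse = "\n"), "\n")
    },
    json = {
      rows <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
      as.character(jsonlite::toJSON(rows, auto_unbox = TRUE))
    }
  )
  if (!is.null(path)) writeLines(sub("\n$", "", text), path)
  text
}

#' Export a signed digraph
#'
#' @param d A [signed_digraph()].
#' @param dialect `"sif"` (one `source activates|inhibits target` line per
#'   edge) or `"dot"` (Graphviz digraph with a `sign` edge attribute).
#' @param path Optional file path to also write the text to.
#' @return Character scalar with the export text; edges are sorted
#'   lexicographically.
#' @export
export_digraph <- function(d, dialect = c("sif", "dot"), path = NULL) {
  stopifnot(inherits(d, "signed_digraph"))
  dialect <- match.arg(dialect)
  e <- d$edges
  text <- switch(dialect,
    sif = {
      if (nrow(e) == 0L) ""
      else {
        rel <- ifelse(e$sign == "+", "activates", "inhibits")
        paste0(paste(e$from, rel, e$to, collapse = "\n"), "\n")
      }
    },
    dot = {
      lines <- c("digraph wiring {",
                 paste0("  \"", d$nodes, "\";"))
      if (nrow(e) > 0L) {
        arrow <- ifelse(e$sign == "+", "normal", "tee")
        lines <- c(lines, paste0("  \"", e$from, "\" -> \"", e$to,
                                 "\" [sign=\"", e$sign, "\", arrowhead=", arrow, "];"))
      }
      paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
    }
  )
  if (!is.null(path)) writeLines(sub("\n$", "", text), path)
  text
}
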