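# Rule-file parsing.
#
# Two plain-text dialects are accepted:
#   * line rules:    one `name = expression` per line, `#` comments
#   * BoolNet table: a `targets, factors` header followed by `name, expression`
#     rows (the factors column uses the same expression grammar)
# Operator precedence: NOT > AND > XOR > OR; parentheses override.

NAME_RE <- "^[A-Za-z_][A-Za-z0-9_]*$"

tokenize_expression <- function(text, line = NA_integer_) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value) tokens[[length(tokens) + 1L]] <<- list(type = type, value = value)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[ \t]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("&", "|", "!", "^", "(", ")")) {
      push(switch(ch, "&" = "AND", "|" = "OR", "!" = "NOT", "^" = "XOR",
                  "(" = "LPAREN", ")" = "RPAREN"), ch)
      i <- i + 1L
      next
    }
    if (grepl("^[01]$", ch)) {
      # a constant must not be glued to an identifier character
      nxt <- if (i < n) substr(text, i + 1L, i + 1L) else ""
      if (grepl("^[A-Za-z0-9_]$", nxt)) {
        stop("syntax error", line_tag(line), ": unexpected token near '",
             substr(text, i, min(n, i + 8L)), "'")
      }
      push("CONST", as.integer(ch))
      i <- i + 1L
      next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      m <- regmatches(substr(text, i, n), regexpr("^[A-Za-z0-9_]+", substr(text, i, n)))
      word <- m[[1L]]
      upper <- toupper(word)
      if (upper %in% c("AND", "OR", "NOT", "XOR")) push(upper, word)
      else push("NAME", word)
      i <- i + nchar(word)
      next
    }
    stop("syntax error", line_tag(line), ": unexpected character '", ch, "'")
  }
  tokens
}

line_tag <- function(line) if (is.na(line)) "" else paste0(" at line ", line)

# Recursive-descent parser over the token list.
parse_expression_tokens <- function(tokens, line = NA_integer_) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]]$type else "EOF"
  advance <- function() { tok <- tokens[[pos]]; pos <<- pos + 1L; tok }
  expect <- function(type) {
    if (peek() != type) {
      stop("syntax error", line_tag(line), ": expected ", type, ", found ", peek())
    }
    advance()
  }
  parse_or <- function() {
    parts <- list(parse_xor())
    while (peek() == "OR") { advance(); parts[[length(parts) + 1L]] <- parse_xor() }
    .b_nary("OR", parts)
  }
  parse_xor <- function() {
    parts <- list(parse_and())
    while (peek() == "XOR") { advance(); parts[[length(parts) + 1L]] <- parse_and() }
    .b_nary("XOR", parts)
  }
  parse_and <- function() {
    parts <- list(parse_unary())
    while (peek() == "AND") { advance(); parts[[length(parts) + 1L]] <- parse_unary() }
    .b_nary("AND", parts)
  }
  parse_unary <- function() {
    t <- peek()
    if (t == "NOT") { advance(); return(b_not(parse_unary())) }
    if (t == "LPAREN") {
      advance()
      e <- parse_or()
      expect("RPAREN")
      return(e)
    }
    if (t == "NAME") return(b_var(advance()$value))
    if (t == "CONST") return(b_const(advance()$value))
    stop("syntax error", line_tag(line), ": unexpected ", t)
  }
  e <- parse_or()
  if (peek() != "EOF") {
    stop("syntax error", line_tag(line), ": trailing tokens after expression")
  }
  e
}

#' Parse a single Boolean expression
#'
#' @param text Expression text, e.g. `"!x2 & (x3 | x4)"`. Keywords
#'   `AND`/`OR`/`NOT`/`XOR` (case-insensitive) are synonyms for
#'   `&`/`|`/`!`/`^`.
#' @return An expression tree.
#' @export
parse_expression <- function(text) {
  parse_expression_tokens(tokenize_expression(text))
}

#' Read a Boolean network from rule text
#'
#' Accepts either the line-rule dialect (`name = expression`, one per line,
#' `#` comments) or a BoolNet-compatible table (header `targets, factors`,
#' one `name, expression` row per node). Every symbol referenced by a rule
#' must itself be defined by some rule; an unregulated node must therefore be
#' written explicitly as a constant (`x = 0`) or as a self-input (`x = x`,
#' a free environmental input that can take either value at a steady state).
#'
#' @param text Character vector: either a single string (possibly with
#'   newlines), several lines, or a file path when `file = TRUE`.
#' @param file If `TRUE`, `text` is a path to read with [readLines()].
#' @return A [boolean_network()] with variables in declaration order.
#' @examples
#' f <- parse_rules("x1 = !x2 & (x3 | x4)\nx2 = x1\nx3 = x3\nx4 = x4")
#' f
#' @export
parse_rules <- function(text, file = FALSE) {
  if (file) text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines_nocomment <- sub("#.*$", "", lines)
  trimmed <- trimws(lines_nocomment)
  nonempty <- which(nzchar(trimmed))
  if (length(nonempty) == 0L) stop("no rules found")

  first <- trimmed[[nonempty[[1L]]]]
  boolnet <- grepl("^targets[ \t]*,[ \t]*factors$", first, ignore.case = TRUE)

  vars <- character(0)
  exprs <- list()
  body_idx <- if (boolnet) nonempty[-1L] else nonempty
  for (ln in body_idx) {
    row <- trimmed[[ln]]
    if (boolnet) {
      cm <- regexpr(",", row, fixed = TRUE)
      if (cm < 0L) stop("syntax error at line ", ln, ": expected 'target, factor'")
      lhs <- trimws(substr(row, 1L, cm - 1L))
      rhs <- trimws(substr(row, cm + 1L, nchar(row)))
    } else {
      em <- regexpr("=", row, fixed = TRUE)
      if (em < 0L) stop("syntax error at line ", ln, ": expected 'name = expression'")
      lhs <- trimws(substr(row, 1L, em - 1L))
      rhs <- trimws(substr(row, em + 1L, nchar(row)))
    }
    if (!grepl(NAME_RE, lhs)) stop("invalid node name '", lhs, "' at line ", ln)
    if (lhs %in% vars) stop("duplicate definition of '", lhs, "' at line ", ln)
    if (!nzchar(rhs)) stop("empty rule for '", lhs, "' at line ", ln)
    vars <- c(vars, lhs)
    exprs[[lhs]] <- parse_expression_tokens(tokenize_expression(rhs, ln), ln)
  }
  for (v in vars) {
    bad <- setdiff(expression_vars(exprs[[v]]), vars)
    if (length(bad)) {
      stop("undefined symbol(s) in rule for '", v, "': ", paste(bad, collapse = ", "),
           " (write inputs as 'x = x' or constants as 'x = 0/1')")
    }
  }
  boolean_network(vars, exprs)
}
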