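# End-to-end steady-state computation:
#   f --(AND-NOT transform)--> g --(wiring-diagram reduction)--> h
#     --(GF(2) polynomial system + Groebner basis)--> solutions of h
#     --(backtracking)--> steady states of g --(projection)--> states of f.

#' Compute all steady states of a Boolean network
#'
#' The default pipeline converts the network to AND-NOT form, reduces the
#' signed wiring diagram with steady-state-preserving rules, solves the
#' remaining fixed-point conditions as a square-free GF(2) polynomial system
#' (lexicographic Gröbner basis with back-substitution), backtracks the
#' removed variables and projects onto the original coordinates. Two
#' independent oracle methods are available for verification: `"brute"`
#' (exhaustive 2^n scan) and `"fvs"` (feedback-vertex-set candidates).
#' Every state emitted by any method is re-checked with [is_steady_state()]
#' before being returned, so a wrong answer surfaces as an error rather than
#' silently.
#'
#' @param f A `boolean_network` (or `andnot_network`), or rule text / a file
#'   accepted by [parse_rules()].
#' @param method `"auto"` (brute force up to `auto_brute_cap` variables,
#'   pipeline above), `"pipeline"`, `"brute"`, or `"fvs"`.
#' @param max_solutions Cap on the number of steady states enumerated by the
#'   algebra stage (guards against, e.g., dozens of free environmental
#'   inputs); exceeding it raises an error of class `bnsteady_cap_error`.
#' @param brute_cap,fvs_cap Size caps forwarded to
#'   [enumerate_exhaustive()] / [enumerate_via_fvs()].
#' @param auto_brute_cap Largest n for which `method = "auto"` picks brute
#'   force.
#' @param timeout Optional wall-clock limit in seconds for the solve
#'   (enforced with [setTimeLimit()]); `NULL` disables it.
#' @return A `solve_report`: list with `steady_states` (a
#'   [steady_state_set()] over `f`'s variables), `method`, stage sizes `n`
#'   (original), `m` (AND-NOT), `l` (reduced), `rule_counts`, `basis_size`
#'   (number of Gröbner basis elements over all components) and
#'   `branch_count` (branches explored during back-substitution), both
#'   pipeline only, and `timings` (seconds per stage).
#' @examples
#' f <- parse_rules("x1 = x2 | x3\nx2 = x1\nx3 = x1")
#' solve_network(f, method = "pipeline")
#' @export
solve_network <- function(f, method = c("auto", "pipeline", "brute", "fvs"),
                          max_solutions = 1e5, brute_cap = 22L, fvs_cap = 24L,
                          auto_brute_cap = 18L, timeout = NULL) {
  method <- match.arg(method)
  if (is.character(f)) {
    f <- if (length(f) == 1L && file.exists(f)) parse_rules(f, file = TRUE) else parse_rules(f)
  }
  stopifnot(is_boolean_network(f) || is_andnot_network(f))
  n <- length(f$variables)
  if (method == "auto") method <- if (n <= auto_brute_cap) "brute" else "pipeline"

  if (!is.null(timeout)) {
    setTimeLimit(elapsed = timeout, transient = TRUE)
    on.exit(setTimeLimit(elapsed = Inf), add = TRUE)
  }

  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  report <- list(method = method, n = n, m = NA_integer_, l = NA_integer_,
                 rule_counts = NULL, basis_size = NA_integer_)

  if (method == "brute") {
    t0 <- tic()
    ss <- enumerate_exhaustive(f, cap = brute_cap)
    timings <- c(scan = tic() - t0)
  } else if (method == "fvs") {
    t0 <- tic()
    S <- find_fvs(f)
    timings <- c(fvs = tic() - t0)
    t0 <- tic()
    ss <- enumerate_via_fvs(f, S, cap = fvs_cap)
    timings <- c(timings, candidates = tic() - t0)
    report$fvs_size <- length(S)
  } else {
    # Step 1: AND-NOT transform (identity when already AND-NOT)
    t0 <- tic()
    if (is_andnot_network(f)) {
      g <- f
      map <- NULL
    } else {
      tr <- boolean_to_andnot(f)
      g <- tr$network
      map <- tr$map
    }
    report$m <- length(g$variables)
    timings <- c(transform = tic() - t0)

    # Steps 2-4: wiring-diagram reduction
    t0 <- tic()
    red <- reduce_andnot(g)
    h <- red$network
    report$l <- if (is.null(h)) 0L else length(h$variables)
    report$rule_counts <- red$trace$counts
    timings <- c(timings, reduce = tic() - t0)

    # Steps 5-6: polynomial system and solutions of h
    t0 <- tic()
    if (is.null(h)) {
      states_h <- NULL
    } else {
      sys <- steady_state_system(h)
      states_h <- enumerate_solutions(sys, max_solutions = max_solutions)
      report$basis_size <- attr(states_h, "gb_size")
      report$branch_count <- attr(states_h, "branches")
    }
    timings <- c(timings, algebra = tic() - t0)

    # Step 7: backtrack to g; Step 8: project to f's coordinates
    t0 <- tic()
    states_g <- backtrack_states(red$trace, states_h, g)
    ss <- if (is.null(map)) states_g else project_steady_states(states_g, map)
    timings <- c(timings, backtrack = tic() - t0)
  }

  # Self-verification: every emitted state must be fixed by f.
  if (nrow(ss$states) > 0L) {
    upd <- eval_states(f, ss$states == 1L)
    if (!all(upd == (ss$states == 1L))) {
      stop("internal consistency error: an emitted state is not a steady state")
    }
  }

  report$steady_states <- ss
  report$timings <- timings
  structure(report, class = "solve_report")
}

#' @export
print.solve_report <- function(x, ...) {
  cat("Steady-state solve (method:", x$method, ")\n")
  cat("  stage sizes: n =", x$n,
      if (!is.na(x$m)) paste0("-> m = ", x$m) else "",
      if (!is.na(x$l)) paste0("-> l = ", x$l) else "", "\n")
  if (!is.null(x$rule_counts)) {
    cat("  reduction:", paste(names(x$rule_counts), x$rule_counts,
                              sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$fvs_size)) cat("  |FVS| =", x$fvs_size, "\n")
  cat("  elapsed:", sprintf("%.3fs", sum(x$timings)), "\n")
  print(x$steady_states)
  invisible(x)
}

#' Cross-check two steady-state methods on one model
#'
#' Runs both methods and reports whether they returned exactly the same set,
#' together with the symmetric difference (empty on agreement). This mirrors
#' the validation design of checking the pipeline against an independent
#' oracle.
#'
#' @param f A network or rule text (see [solve_network()]).
#' @param methods Character vector of length 2.
#' @param ... Passed on to [solve_network()].
#' @return A list with `agree` (logical), `only_first` and `only_second`
#'   (0/1 matrices of states found by only one method), and the two
#'   `solve_report`s.
#' @export
verify_steady_states <- function(f, methods = c("pipeline", "brute"), ...) {
  stopifnot(length(methods) == 2L)
  r1 <- solve_network(f, method = methods[[1L]], ...)
  r2 <- solve_network(f, method = methods[[2L]], ...)
  k1 <- apply(r1$steady_states$states, 1L, paste, collapse = "")
  k2 <- apply(r2$steady_states$states, 1L, paste, collapse = "")
  list(agree = setequal(k1, k2),
       only_first = r1$steady_states$states[!(k1 %in% k2), , drop = FALSE],
       only_second = r2$steady_states$states[!(k2 %in% k1), , drop = FALSE],
       first = r1, second = r2)
}
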