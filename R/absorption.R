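#' Expected absorption time of neutral evolution on a graph
#'
#' Front end to the package's estimators of the expected number of
#' birth-death events until a population that starts with a distinct type on
#' every vertex becomes homogeneous (the consensus / total coalescence
#' time). Dispatches on `method`:
#'
#' * `"auto"` — closed form when the graph is a recognized family
#'   (complete graph, cycle), otherwise the lumped solver when `N <= 8`,
#'   otherwise simulation.
#' * `"lumped"` — exact, partition-lumped chain ([absorption_time_lumped]).
#' * `"full"` — exact, full labeled chain, `N <= 5` ([absorption_time_full]).
#' * `"closed_form"` — family closed forms ([complete_time], [cycle_time]);
#'   errors for graphs without one.
#' * `"simulate"` — Monte-Carlo ([estimate_absorption_time]); honours
#'   `reps`, `seed`, `max_steps`.
#'
#' @param g A strongly connected [evograph].
#' @param rule `"bd"` or `"db"`.
#' @param method See above.
#' @param reps,seed,max_steps Simulation controls.
#' @return An object of class `evodiv_absorption` with fields
#'   `expected_time`, `se` (`NA` for exact methods), `method`, `rule`,
#'   `state_count` and the underlying result in `$detail`.
#' @examples
#' absorption_time(make_cycle(10))             # exact: 165
#' absorption_time(make_star(6), rule = "bd")  # lumped solver
#' @export
absorption_time <- function(g, rule = c("bd", "db"),
                            method = c("auto", "lumped", "full",
                                       "closed_form", "simulate"),
                            reps = 250, seed = 1, max_steps = 1e9) {
  rule <- match.arg(rule)
  method <- match.arg(method)
  fam <- family_of(g)
  if (method == "auto") {
    method <- if (fam %in% c("complete", "complete_no_loops", "cycle"))
      "closed_form"
    else if (g$n <= 8L) "lumped" else "simulate"
  }
  detail <- switch(method,
    closed_form = {
      lam <- rep(1L, g$n)
      switch(fam,
        complete = complete_time(lam, self_loops = TRUE),
        complete_no_loops = complete_time(lam, self_loops = FALSE),
        cycle = cycle_time(lam),
        stop("no closed form is available for this graph; use method = ",
             "'lumped' or 'simulate'", call. = FALSE))
    },
    lumped = absorption_time_lumped(g, rule),
    full = absorption_time_full(g, rule),
    simulate = estimate_absorption_time(g, rule, reps = reps, seed = seed,
                                        max_steps = max_steps))
  if (inherits(detail, "evodiv_sim")) {
    est <- detail$mean; se <- detail$se; states <- NA_integer_
  } else {
    est <- detail$expected_time; se <- NA_real_; states <- detail$state_count
  }
  structure(list(expected_time = est, se = se, method = method, rule = rule,
                 state_count = states, n = g$n, graph = g$name,
                 detail = detail),
            class = "evodiv_absorption")
}

# recognize the constructors' family tags; unnamed graphs are "generic"
family_of <- function(g) {
  if (is.null(g$name)) return("generic")
  sub("_[0-9]+(_b[0-9]+)?$", "", g$name)
}

#' @export
print.evodiv_absorption <- function(x, ...) {
  cat(sprintf("Expected absorption time on %s (N = %d, %s updating)\n",
              if (is.null(x$graph)) "graph" else x$graph, x$n, x$rule))
  if (is.na(x$se)) {
    cat(sprintf("  %.10g steps   [%s%s]\n", x$expected_time, x$method,
                if (is.na(x$state_count)) ""
                else sprintf(", %d states", x$state_count)))
  } else {
    cat(sprintf("  %.6g +/- %.3g steps   [simulation]\n",
                x$expected_time, x$se))
  }
  invisible(x)
}

#' @export
summary.evodiv_absorption <- function(object, ...) {
  print(object)
  cat(sprintf("  generations (steps / N): %.6g\n",
              object$expected_time / object$n))
  if (!is.na(object$se) && inherits(object$detail, "evodiv_sim")) {
    q <- stats::quantile(object$detail$times, c(0.25, 0.5, 0.75))
    cat(sprintf("  replicate quartiles: %.4g / %.4g / %.4g (%d reps)\n",
                q[1], q[2], q[3], object$detail$reps))
  }
  invisible(object)
}
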