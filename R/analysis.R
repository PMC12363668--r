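#' Exhaustive exact sweep over small connected graphs
#'
#' Runs the partition-lumped solver from maximal diversity on every
#' isomorphism class of connected undirected graphs on `N` vertices and
#' tabulates the bd and db expected absorption times, the normalized degree
#' entropy, and the db/bd time ratio. At `N <= 6` this is a desk-scale
#' computation (112 graphs, 203 lumped states at `N = 6`); `N` of 7 or 8 is
#' allowed but long-running.
#'
#' @param N Number of vertices (`2 <= N <= 8`).
#' @param rules Which update rules to solve (default both).
#' @return Data frame with columns `graph_id` (canonical graph6), `bd_time`,
#'   `db_time`, `degree_entropy`, `ratio` (db/bd), `method`.
#' @export
sweep_exact <- function(N, rules = c("bd", "db")) {
  N <- as.integer(N)
  if (N < 2L || N > 8L) stop("sweep supports 2 <= N <= 8", call. = FALSE)
  rules <- match.arg(rules, c("bd", "db"), several.ok = TRUE)
  graphs <- enumerate_connected_graphs(N)
  rows <- lapply(graphs, function(g) {
    bd <- if ("bd" %in% rules)
      absorption_time_lumped(g, "bd")$expected_time else NA_real_
    db <- if ("db" %in% rules)
      absorption_time_lumped(g, "db")$expected_time else NA_real_
    data.frame(graph_id = g$name, bd_time = bd, db_time = db,
               degree_entropy = degree_entropy(g),
               ratio = db / bd, method = "lumped",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pareto front of absorption times
#'
#' Subset of records not dominated in the `(bd_time, db_time)` plane: a
#' record is kept when no other record is at least as large in both
#' coordinates and strictly larger in one. Returned in increasing `bd_time`
#' order.
#'
#' @param records Data frame with `bd_time` and `db_time` columns
#'   (e.g. from [sweep_exact]).
#' @return The non-dominated rows.
#' @export
pareto_front <- function(records) {
  if (NROW(records) == 0L) stop("records must be nonempty", call. = FALSE)
  bd <- records$bd_time; db <- records$db_time
  keep <- vapply(seq_along(bd), function(i) {
    dominated <- bd >= bd[i] & db >= db[i] & (bd > bd[i] | db > db[i])
    !any(dominated)
  }, logical(1))
  out <- records[keep, , drop = FALSE]
  out[order(out$bd_time), , drop = FALSE]
}

#' Log-log scaling slope of absorption time vs population size
#'
#' Computes `T(N)` for each size by the chosen route (closed forms or the
#' lumped solver in `exact` mode; the Monte-Carlo engine in `simulated`
#' mode) and returns the least-squares slope of `log T` against `log N`.
#' At these sizes the slope reflects the leading power law only up to
#' subleading corrections, so comparisons should use generous windows.
#'
#' @param family Family tag understood by [make_family].
#' @param rule `"bd"` or `"db"`.
#' @param sizes At least three population sizes.
#' @param mode `"exact"` or `"simulated"`.
#' @param reps Replicates per size (simulated mode).
#' @param seed Base seed (simulated mode).
#' @param b Blade count for contracting-star families.
#' @return List with `slope`, `sizes`, `times`, `mode`.
#' @export
scaling_slope <- function(family, rule = c("bd", "db"), sizes,
                          mode = c("exact", "simulated"), reps = 100,
                          seed = 1, b = 2L) {
  rule <- match.arg(rule)
  mode <- match.arg(mode)
  sizes <- as.integer(sizes)
  if (length(sizes) < 3L) stop("need at least three sizes", call. = FALSE)
  times <- vapply(seq_along(sizes), function(i) {
    N <- sizes[i]
    g <- make_family(family, N, b = b)
    if (mode == "exact") {
      fam <- family_of(g)
      if (fam %in% c("complete", "complete_no_loops", "cycle")) {
        absorption_time(g, rule, method = "closed_form")$expected_time
      } else {
        absorption_time_lumped(g, rule)$expected_time
      }
    } else {
      estimate_absorption_time(g, rule, reps = reps, seed = seed + i)$mean
    }
  }, numeric(1))
  if (any(times <= 0) || diff(range(times)) == 0)
    stop("degenerate times; cannot fit a log-log slope", call. = FALSE)
  fit <- stats::lm(log(times) ~ log(sizes))
  list(slope = unname(stats::coef(fit)[2L]), sizes = sizes, times = times,
       mode = mode, rule = rule, family = family)
}

#' Undirected path vs contracting structures
#'
#' Simulated mean absorption times, from maximal diversity with shared
#' seeds, for the undirected path on `N` vertices, the contracting path
#' (contracting star with `b = 2` blades), and — when `3` divides `N - 1` —
#' the contracting star with `b = 3` blades. Censored replicates are
#' reported, never silently dropped.
#'
#' @param N Population size (`N <= 15` is the sensible range; contracting
#'   times explode superexponentially).
#' @param reps Replicates per structure.
#' @param seed Seed shared across structures.
#' @param max_steps Cap per replicate.
#' @return Data frame with columns `structure`, `mean_time`, `se`,
#'   `censored`, `reps`; the per-structure simulation objects are attached
#'   as attribute `sims`.
#' @export
contracting_comparison <- function(N, reps = 100, seed = 1,
                                   max_steps = 1e9) {
  N <- as.integer(N)
  structures <- list(path = make_path(N))
  if ((N - 1L) %% 2L == 0L)
    structures$contracting_path <- make_contracting_star(N, b = 2L)
  if ((N - 1L) %% 3L == 0L)
    structures$contracting_star_b3 <- make_contracting_star(N, b = 3L)
  sims <- lapply(structures, function(g)
    estimate_absorption_time(g, "bd", reps = reps, seed = seed,
                             max_steps = max_steps))
  out <- data.frame(structure = names(sims),
                    mean_time = vapply(sims, `[[`, numeric(1), "mean"),
                    se = vapply(sims, `[[`, numeric(1), "se"),
                    censored = vapply(sims, function(s)
                      sum(s$censored), numeric(1)),
                    reps = reps, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "sims") <- sims
  out
}
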