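#' One update step
#'
#' Performs a single replacement event on a type configuration using R's own
#' random number generator (so `set.seed()` controls it). Under bd updating
#' a birth vertex `u` is drawn uniformly from the population and a death
#' vertex `v` uniformly from `u`'s out-neighbors, each ordered event having
#' probability `1/(N deg+(u))`; under db a death vertex `v` is drawn
#' uniformly and a birth vertex `u` uniformly from `v`'s in-neighbors, with
#' probability `1/(N deg-(v))`. The offspring copies its parent's type into
#' the death location; a self-loop self-replacement is a legal no-change
#' step and still consumes one unit of time.
#'
#' @param g A strongly connected [evograph].
#' @param x Integer type configuration, one label per vertex.
#' @param rule `"bd"` or `"db"`.
#' @return The updated configuration.
#' @export
step_once <- function(g, x, rule = c("bd", "db")) {
  rule <- match.arg(rule)
  N <- g$n
  if (length(x) != N) stop("x must have one type per vertex", call. = FALSE)
  if (rule == "bd") {
    u <- sample.int(N, 1L)
    nb <- g$edges[g$edges[, 1L] == u, 2L]
    if (length(nb) == 0L)
      stop("vertex without out-neighbors; graph is not strongly connected",
           call. = FALSE)
    v <- nb[sample.int(length(nb), 1L)]
  } else {
    v <- sample.int(N, 1L)
    nb <- g$edges[g$edges[, 2L] == v, 1L]
    if (length(nb) == 0L)
      stop("vertex without in-neighbors; graph is not strongly connected",
           call. = FALSE)
    u <- nb[sample.int(length(nb), 1L)]
  }
  x[v] <- x[u]
  x
}

# adjacency list the engine needs: out-neighbors for bd, in-neighbors for db
engine_adjacency <- function(g, rule) {
  adj <- if (rule == "bd") neighbors_out(g) else neighbors_in(g)
  if (any(lengths(adj) == 0L))
    stop("every vertex needs a ", if (rule == "bd") "successor" else
         "predecessor", "; graph is not strongly connected", call. = FALSE)
  adj
}

check_seed <- function(seed) {
  seed <- as.numeric(seed)
  if (length(seed) != 1L || is.na(seed) || seed < 0 || seed != floor(seed))
    stop("seed must be a single nonnegative integer", call. = FALSE)
  seed
}

#' Simulate one trajectory to absorption
#'
#' Runs the process until the population is homogeneous (or `max_steps` is
#' hit, in which case the run is flagged as censored rather than silently
#' truncated) and returns the exact step count and the winning type.
#'
#' @inheritParams step_once
#' @param x0 Initial configuration; default maximal diversity (type `i` at
#'   vertex `i`).
#' @param seed Nonnegative integer seed for the replicate's private stream.
#' @param max_steps Step cap (default `1e9`).
#' @return List with `time`, `winner` (`NA` if censored) and `censored`.
#' @export
simulate_to_absorption <- function(g, rule = c("bd", "db"),
                                   x0 = seq_len(g$n), seed = 1,
                                   max_steps = 1e9) {
  rule <- match.arg(rule)
  res <- .cpp_simulate_batch(engine_adjacency(g, rule), rule == "bd",
                             as.integer(x0), 1L, check_seed(seed),
                             as.numeric(max_steps))
  list(time = res$times[1L], winner = res$winners[1L],
       censored = res$censored[1L])
}

#' Estimate the expected absorption time by simulation
#'
#' Runs `reps` independent replicates; replicate `r` uses a random stream
#' derived deterministically from `(seed, r)`, so results are reproducible
#' and order-independent. Returns per-replicate times, their mean and
#' standard error, and the winner of each replicate.
#'
#' @inheritParams simulate_to_absorption
#' @param reps Number of replicates (`>= 1`).
#' @return An `evodiv_sim` object (fields `times`, `winners`, `censored`,
#'   `mean`, `se`, `reps`, `rule`, `seed`).
#' @examples
#' \donttest{
#' estimate_absorption_time(make_complete(8), "bd", reps = 250, seed = 1)
#' }
#' @export
estimate_absorption_time <- function(g, rule = c("bd", "db"), reps,
                                     seed = 1, x0 = seq_len(g$n),
                                     max_steps = 1e9) {
  rule <- match.arg(rule)
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop("reps must be >= 1", call. = FALSE)
  if (length(x0) != g$n)
    stop("x0 must have one type per vertex", call. = FALSE)
  res <- .cpp_simulate_batch(engine_adjacency(g, rule), rule == "bd",
                             as.integer(x0), reps, check_seed(seed),
                             as.numeric(max_steps))
  times <- res$times
  structure(list(times = times, winners = res$winners,
                 censored = res$censored,
                 mean = mean(times),
                 se = stats::sd(times) / sqrt(reps),
                 reps = reps, rule = rule, seed = seed,
                 graph = g$name),
            class = "evodiv_sim")
}

#' @export
print.evodiv_sim <- function(x, ...) {
  cat(sprintf("Simulated absorption time: %.6g +/- %.3g (SE), %d replicates\n",
              x$mean, x$se, x$reps))
  cat(sprintf("  rule: %s   seed: %s%s\n", x$rule, format(x$seed),
              if (any(x$censored)) sprintf("   censored: %d", sum(x$censored))
              else ""))
  if (!is.null(x$graph)) cat(sprintf("  graph: %s\n", x$graph))
  invisible(x)
}

#' Characteristic curve: expected diversity over time
#'
#' For each replicate the number of distinct types is recorded at each
#' requested time point (the configuration is frozen at 1 type once
#' absorbed); the curve is the per-time-point mean over replicates. At
#' `T = 0` from maximal diversity the curve starts at `N`, and it decreases
#' monotonically towards 1.
#'
#' @inheritParams estimate_absorption_time
#' @param time_points Strictly increasing nonnegative integers.
#' @return A data frame (class `evodiv_curve`) with columns `time` and
#'   `mean_diversity`, plus attributes `rule`, `reps`, `seed`.
#' @export
characteristic_curve <- function(g, rule = c("bd", "db"), reps, time_points,
                                 seed = 1, x0 = seq_len(g$n)) {
  rule <- match.arg(rule)
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop("reps must be >= 1", call. = FALSE)
  tp <- as.numeric(time_points)
  if (length(tp) == 0L || any(tp < 0) || any(diff(tp) <= 0))
    stop("time_points must be nonnegative and strictly increasing",
         call. = FALSE)
  mean_div <- .cpp_diversity_curve(engine_adjacency(g, rule), rule == "bd",
                                   as.integer(x0), reps, check_seed(seed),
                                   tp, max(tp))
  out <- data.frame(time = tp, mean_diversity = mean_div)
  attr(out, "rule") <- rule
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  attr(out, "graph") <- g$name
  class(out) <- c("evodiv_curve", "data.frame")
  out
}

#' @export
plot.evodiv_curve <- function(x, log = "xy", ...) {
  tp <- x$time
  if (grepl("x", log)) tp <- pmax(tp, 1)
  graphics::plot(tp, x$mean_diversity, log = log, type = "b", pch = 16,
                 xlab = "time (steps)", ylab = "mean diversity", ...)
  invisible(x)
}

#' Log-spaced time grid
#'
#' Helper for characteristic curves: `count` roughly log-spaced integer time
#' points between `from` and `to` (duplicates collapsed).
#'
#' @param from,to Positive range endpoints.
#' @param count Number of grid points before deduplication.
#' @return Strictly increasing integer vector.
#' @export
log_time_grid <- function(from, to, count = 50L) {
  unique(round(exp(seq(log(max(1, from)), log(to), length.out = count))))
}
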