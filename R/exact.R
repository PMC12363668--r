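#' Abundance histogram profile
#'
#' For a sorted abundance vector `lambda` (type frequencies summing to `N`)
#' and height `h`, returns the number of histogram boxes above the line
#' `y = h`: `sum(max(lambda_i - h, 0))`. In particular `b_profile(lambda, 0)`
#' is `N`. This profile drives the closed-form absorption times for complete
#' graphs and cycles.
#'
#' @param lambda Positive integer abundances (any order; ties allowed).
#' @param h Nonnegative integer height.
#' @return Nonnegative integer.
#' @examples
#' b_profile(c(3, 2), 1) # 3
#' @export
b_profile <- function(lambda, h) {
  lambda <- as.integer(lambda)
  if (length(lambda) == 0L || any(is.na(lambda)) || any(lambda < 1L))
    stop("lambda must be positive integers", call. = FALSE)
  sum(pmax(lambda - as.integer(h), 0L))
}

#' Exact absorption time: complete graph
#'
#' Expected number of steps until one type remains, for a well-mixed
#' population (complete graph with self-loops) started from abundance
#' configuration `lambda`. Two equivalent closed forms are evaluated —
#' the double sum
#' \deqn{T = N^2 - N - \sum_i \sum_{\ell=1}^{\lambda_i - 1}
#'       (N + \lambda_i - 2\ell)\,\frac{\ell}{N-\ell}}
#' and the histogram form
#' \deqn{T = N\Big(N - \sum_{h=0}^{N-1} \frac{b_h}{N-h}\Big)}
#' — and their agreement is asserted before returning. From maximal
#' diversity (`lambda = rep(1, N)`) the value is `N (N - 1)`. Without
#' self-loops the maximal-diversity value is `(N - 1)^2`.
#'
#' @param lambda Positive integer abundances.
#' @param self_loops Complete graph with self-loops (the default) or without;
#'   the loop-free closed form is available for maximal diversity only.
#' @return An `evodiv_exact` result.
#' @examples
#' complete_time(rep(1, 8)) # 56
#' @export
complete_time <- function(lambda, self_loops = TRUE) {
  lambda <- as.integer(lambda)
  if (length(lambda) == 0L || any(is.na(lambda)) || any(lambda < 1L))
    stop("lambda must be a nonempty vector of positive integers",
         call. = FALSE)
  N <- sum(lambda)
  if (!self_loops) {
    if (!all(lambda == 1L))
      stop("the loop-free closed form covers maximal diversity only",
           call. = FALSE)
    return(exact_result((N - 1)^2, "closed_form", NA_integer_,
                        rule = "bd/db", graph = sprintf("complete_no_loops_%d", N)))
  }
  # double-sum form
  t1 <- N^2 - N - sum(vapply(lambda, function(li) {
    if (li < 2L) return(0)
    l <- seq_len(li - 1L)
    sum((N + li - 2 * l) * l / (N - l))
  }, numeric(1)))
  # histogram form
  h <- seq.int(0L, N - 1L)
  bh <- vapply(h, function(hh) b_profile(lambda, hh), numeric(1))
  t2 <- N * (N - sum(bh / (N - h)))
  if (abs(t1 - t2) > 1e-9 * max(1, abs(t1)))
    stop("internal inconsistency between the two closed forms", call. = FALSE)
  exact_result(t1, "closed_form", NA_integer_,
               rule = "bd/db", graph = sprintf("complete_%d", N))
}

#' Exact absorption time: cycle
#'
#' Expected absorption time on the undirected cycle from a configuration
#' whose types occupy contiguous arcs with abundances `lambda`:
#' \deqn{T = \frac{(N+1)N(N-1)}{6} - \sum_{h=0}^{N-1} b_h\, h.}
#' From maximal diversity this is `(N+1) N (N-1) / 6`. Contiguity of the
#' clusters is the caller's responsibility (it holds automatically along any
#' trajectory started from maximal diversity); the value depends only on
#' `lambda` given contiguity.
#'
#' @param lambda Positive integer abundances of the contiguous clusters.
#' @return An `evodiv_exact` result.
#' @examples
#' cycle_time(rep(1, 10)) # 165
#' @export
cycle_time <- function(lambda) {
  lambda <- as.integer(lambda)
  if (length(lambda) == 0L || any(is.na(lambda)) || any(lambda < 1L))
    stop("lambda must be positive integers", call. = FALSE)
  N <- sum(lambda)
  h <- seq.int(0L, N - 1L)
  bh <- vapply(h, function(hh) b_profile(lambda, hh), numeric(1))
  val <- (N + 1) * N * (N - 1) / 6 - sum(bh * h)
  exact_result(val, "closed_form", NA_integer_,
               rule = "bd/db", graph = sprintf("cycle_%d", N))
}

#' Conjectured exact absorption time: star under bd updating
#'
#' For the star on `N = n + 1` vertices (hub plus `n` leaves) under bd
#' updating from maximal diversity, the conjectured exact expected absorption
#' time is
#' \deqn{T = n^3 - n^2 + n H_n,}
#' with `H_n` the `n`-th harmonic number. The returned result is flagged as a
#' conjecture; the lumped solver verifies it exactly for small `n` and any
#' disagreement should be treated as a finding, not silenced.
#'
#' @param n Number of leaves (`n >= 1`).
#' @return An `evodiv_exact` result with `conjecture = TRUE`.
#' @examples
#' star_time_conjecture(3) # 23.5
#' @export
star_time_conjecture <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("need n >= 1 leaves", call. = FALSE)
  val <- n^3 - n^2 + n * sum(1 / seq_len(n))
  res <- exact_result(val, "closed_form", NA_integer_,
                      rule = "bd", graph = sprintf("star_%d", n + 1L))
  res$conjecture <- TRUE
  res
}

#' Number of lumped states
#'
#' The partition-lumped chain has one state per set partition of the `N`
#' vertices, so its size is the `N`-th Bell number (4140 for `N = 8`).
#' Computed by the Bell-triangle recurrence; exact as long as the value is
#' below 2^53.
#'
#' @param N Population size.
#' @return The Bell number `B(N)`.
#' @examples
#' partition_state_count(8) # 4140
#' @export
partition_state_count <- function(N) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 1L)
    stop("need N >= 1", call. = FALSE)
  row <- 1
  for (i in seq_len(N - 1L)) row <- cumsum(c(row[length(row)], row))
  row[length(row)]
}

# ---- state-space machinery ----------------------------------------------

# All set partitions of 1..n as restricted-growth strings: a matrix with one
# row per partition, entries in 1..n, a[1]=1, a[i] <= max(a[1..i-1]) + 1.
# Rows are in lexicographic RGS order, so indexing is reproducible.
rgs_enumerate <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  prev <- rgs_enumerate(n - 1L)
  maxes <- apply(prev, 1L, max)
  reps <- maxes + 1L
  out <- matrix(0L, sum(reps), n)
  r <- 1L
  for (i in seq_len(nrow(prev))) {
    k <- reps[i]
    rows <- seq.int(r, r + k - 1L)
    out[rows, seq_len(n - 1L)] <- matrix(prev[i, ], k, n - 1L, byrow = TRUE)
    out[rows, n] <- seq_len(k)
    r <- r + k
  }
  out
}

# canonicalize a block-label vector to restricted-growth form
rgs_canonical <- function(labels) {
  match(labels, unique(labels))
}

rgs_key <- function(labels) paste(labels, collapse = ",")

# ordered replacement events (u gives birth into v) and their per-step
# probabilities under a rule; identical merge semantics for bd and db
event_table <- function(g, rule) {
  rule <- match.arg(rule, c("bd", "db"))
  N <- g$n
  if (rule == "bd") {
    dout <- degree_out(g)
    if (any(dout == 0L))
      stop("bd updating needs every vertex to have an out-neighbor",
           call. = FALSE)
    u <- g$edges[, 1L]; v <- g$edges[, 2L]
    p <- 1 / (N * dout[u])
  } else {
    din <- degree_in(g)
    if (any(din == 0L))
      stop("db updating needs every vertex to have an in-neighbor",
           call. = FALSE)
    u <- g$edges[, 1L]; v <- g$edges[, 2L]
    p <- 1 / (N * din[v])
  }
  list(u = u, v = v, p = p)
}

#' Exact absorption time: partition-lumped chain
#'
#' Because all types are neutral and never mutate, the labeled chain on type
#' vectors can be lumped: a state is the set partition of vertices by shared
#' type, and a replacement event (`u` gives birth into `v`) moves `v` into
#' `u`'s block. This reduces the state space from `N^N` to the `N`-th Bell
#' number. The expected absorption times solve
#' `tau = 0` on the single-block state and
#' `tau(P) = 1 + sum_P' p(P -> P') tau(P')` otherwise; the sparse linear
#' system is solved in double precision with Matrix.
#'
#' @param g A strongly connected [evograph].
#' @param rule `"bd"` or `"db"`.
#' @param partition Initial state: a length-`N` vector of block labels
#'   (vertices sharing a label share a type). Default: maximal diversity,
#'   every vertex its own block.
#' @return An `evodiv_exact` result; `state_count` is the number of lumped
#'   states instantiated (the Bell number).
#' @examples
#' absorption_time_lumped(make_complete(4), "bd") # 12
#' @export
absorption_time_lumped <- function(g, rule = c("bd", "db"),
                                   partition = seq_len(g$n)) {
  rule <- match.arg(rule)
  N <- g$n
  if (N > 10L)
    stop("lumped solver capacity exceeded (N <= 10); use simulation",
         call. = FALSE)
  if (length(partition) != N)
    stop("partition must assign a block label to each vertex", call. = FALSE)
  if (N == 1L)  # a single vertex is always homogeneous
    return(exact_result(0, "lumped", 1L, rule = rule, graph = g$name))
  ev <- event_table(g, rule)
  states <- rgs_enumerate(N)
  S <- nrow(states)
  keys <- apply(states, 1L, rgs_key)
  index <- new.env(hash = TRUE, size = 2L * S)
  for (i in seq_len(S)) assign(keys[i], i, envir = index)
  nblocks <- apply(states, 1L, max)
  transient <- which(nblocks > 1L)
  if (length(transient) == 0L)  # N = 1: the single state is absorbing
    return(exact_result(0, "lumped", S, rule = rule, graph = g$name))
  tmap <- integer(S); tmap[transient] <- seq_along(transient)

  M <- length(ev$u)
  trip_i <- vector("list", length(transient))
  trip_j <- vector("list", length(transient))
  trip_x <- vector("list", length(transient))
  rhs <- rep(1, length(transient))
  for (si in seq_along(transient)) {
    s <- transient[si]
    lab <- states[s, ]
    ui <- lab[ev$u]; vi <- lab[ev$v]
    active <- which(ui != vi)
    stay <- 1 - sum(ev$p[active])
    tj <- integer(0); tx <- numeric(0)
    if (length(active)) {
      tgt <- vapply(active, function(a) {
        lab2 <- lab
        lab2[ev$v[a]] <- lab[ev$u[a]]
        get(rgs_key(rgs_canonical(lab2)), envir = index)
      }, integer(1))
      agg <- rowsum(ev$p[active], tgt)
      tj <- as.integer(rownames(agg)); tx <- agg[, 1L]
    }
    # tau(s) = 1 + stay*tau(s) + sum tx*tau(tj)  (absorbing targets drop out)
    keep <- nblocks[tj] > 1L
    trip_i[[si]] <- rep.int(si, 1L + sum(keep))
    trip_j[[si]] <- c(si, tmap[tj[keep]])
    trip_x[[si]] <- c(1 - stay, -tx[keep])
  }
  A <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x),
                            dims = c(length(transient), length(transient)))
  tau <- as.numeric(Matrix::solve(A, rhs))
  tau_all <- numeric(S)
  tau_all[transient] <- tau
  names(tau_all) <- keys
  s0 <- get(rgs_key(rgs_canonical(as.integer(partition))), envir = index)
  res <- exact_result(tau_all[[s0]], "lumped", S, rule = rule, graph = g$name)
  res$all_times <- tau_all  # expected time from every lumped state, by RGS key
  res
}

#' Exact absorption time: full labeled chain
#'
#' Solves the first-step system on the full space of type vectors
#' `x in {1..N}^N` (states `tau(x) = 0` when homogeneous, else
#' `tau(x) = 1 + sum p(x -> x') tau(x')`). The state space is `N^N`, so this
#' solver is capped at `N <= 5`; it exists chiefly as the independent oracle
#' for the lumped solver.
#'
#' @inheritParams absorption_time_lumped
#' @param x0 Initial type vector (default maximal diversity `1..N`).
#' @return An `evodiv_exact` result with `state_count = N^N`.
#' @export
absorption_time_full <- function(g, rule = c("bd", "db"),
                                 x0 = seq_len(g$n)) {
  rule <- match.arg(rule)
  N <- g$n
  if (N > 5L)
    stop("full-chain capacity exceeded (N^N states); use absorption_time_lumped",
         call. = FALSE)
  if (length(x0) != N || any(x0 < 1L) || any(x0 > N))
    stop("x0 must be a length-N vector of types in 1..N", call. = FALSE)
  if (N == 1L)
    return(exact_result(0, "full", 1L, rule = rule, graph = g$name))
  ev <- event_table(g, rule)
  S <- N^N
  # state index s in 0..S-1 encodes digits x_i - 1 base N
  pow <- N^(seq_len(N) - 1L)
  digit <- function(s, i) (s %/% pow[i]) %% N  # vectorized over s
  xdig <- vapply(seq_len(N), function(i) digit(0:(S - 1L), i), numeric(S))
  homog <- rowSums(xdig == xdig[, 1L]) == N
  transient <- which(!homog)
  if (length(transient) == 0L)
    return(exact_result(0, "full", S, rule = rule, graph = g$name))
  tmap <- integer(S); tmap[transient] <- seq_along(transient)
  # accumulate sparse triplets per event, fully vectorized over states
  ti <- list(); tj <- list(); tx <- list()
  diag_extra <- numeric(length(transient))  # probability mass of no-change
  for (e in seq_along(ev$u)) {
    u <- ev$u[e]; v <- ev$v[e]; p <- ev$p[e]
    xu <- xdig[transient, u]; xv <- xdig[transient, v]
    tgt <- transient + (xu - xv) * pow[v]  # new state index (+1-based offset kept)
    same <- xu == xv
    diag_extra[same] <- diag_extra[same] + p
    mv <- which(!same)
    if (length(mv)) {
      tt <- tgt[mv]
      keep <- !homog[tt]
      ti[[length(ti) + 1L]] <- mv[keep]
      tj[[length(tj) + 1L]] <- tmap[tt[keep]]
      tx[[length(tx) + 1L]] <- rep.int(-p, sum(keep))
    }
  }
  nT <- length(transient)
  A <- Matrix::sparseMatrix(i = c(seq_len(nT), unlist(ti)),
                            j = c(seq_len(nT), unlist(tj)),
                            x = c(1 - diag_extra, unlist(tx)),
                            dims = c(nT, nT))
  tau <- as.numeric(Matrix::solve(A, rep(1, nT)))
  s0 <- sum((as.integer(x0) - 1L) * pow) + 1L
  val <- if (homog[s0]) 0 else tau[tmap[s0]]
  exact_result(val, "full", S, rule = rule, graph = g$name)
}

#' Two-type fixation probability
#'
#' Probability that the type initially occupying `focal` takes over the
#' population, when every other vertex carries a second (pooled) type. The
#' chain on occupied subsets of vertices has `2^N` states; the first-step
#' system `phi(S) = sum p(e) phi(S after e)` with `phi(V) = 1`, `phi({}) = 0`
#' is solved sparsely. Under neutrality the pooling is exact, so summing the
#' singleton fixation probabilities over all vertices gives 1.
#'
#' For the star on `n + 1` vertices under bd updating, `focal = hub`
#' reproduces the known fixation probability `1 / (1 + n^2)`.
#'
#' @inheritParams absorption_time_lumped
#' @param focal Vertex indices initially occupied by the focal type.
#' @return Fixation probability in `[0, 1]`.
#' @examples
#' fixation_probability(make_star(3), "bd", focal = 1) # 1/5
#' @export
fixation_probability <- function(g, rule = c("bd", "db"), focal) {
  rule <- match.arg(rule)
  N <- g$n
  if (N > 14L)
    stop("subset-chain capacity exceeded (N <= 14)", call. = FALSE)
  focal <- unique(as.integer(focal))
  if (length(focal) == 0L || any(focal < 1L) || any(focal > N))
    stop("focal must be a nonempty subset of vertices", call. = FALSE)
  if (length(focal) == N) return(1)
  ev <- event_table(g, rule)
  S <- 2^N
  states <- 0:(S - 1L)
  bit <- 2L^(seq_len(N) - 1L)
  transient <- states[states != 0L & states != S - 1L]
  tmap <- integer(S); tmap[transient + 1L] <- seq_along(transient)
  nT <- length(transient)
  diag_extra <- numeric(nT)
  rhs <- numeric(nT)
  ti <- list(); tj <- list(); tx <- list()
  for (e in seq_along(ev$u)) {
    u <- ev$u[e]; v <- ev$v[e]; p <- ev$p[e]
    uin <- bitwAnd(transient, bit[u]) > 0L
    vin <- bitwAnd(transient, bit[v]) > 0L
    tgt <- transient
    gain <- uin & !vin
    lose <- !uin & vin
    tgt[gain] <- tgt[gain] + bit[v]
    tgt[lose] <- tgt[lose] - bit[v]
    same <- !(gain | lose)
    diag_extra[same] <- diag_extra[same] + p
    mv <- which(!same)
    if (length(mv)) {
      tt <- tgt[mv]
      full <- tt == S - 1L
      rhs[mv[full]] <- rhs[mv[full]] + p
      keep <- !full & tt != 0L
      ti[[length(ti) + 1L]] <- mv[keep]
      tj[[length(tj) + 1L]] <- tmap[tt[keep] + 1L]
      tx[[length(tx) + 1L]] <- rep.int(-p, sum(keep))
    }
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(nT), unlist(ti)),
                            j = c(seq_len(nT), unlist(tj)),
                            x = c(1 - diag_extra, unlist(tx)),
                            dims = c(nT, nT))
  phi <- as.numeric(Matrix::solve(A, rhs))
  s0 <- sum(bit[focal])
  phi[tmap[s0 + 1L]]
}

# ---- result container ----------------------------------------------------

exact_result <- function(time, method, state_count, rule, graph = NULL) {
  structure(list(expected_time = as.numeric(time), method = method,
                 state_count = state_count, rule = rule,
                 graph = graph, conjecture = FALSE),
            class = "evodiv_exact")
}

#' @export
print.evodiv_exact <- function(x, ...) {
  cat(sprintf("Expected absorption time: %.10g steps\n", x$expected_time))
  cat(sprintf("  method: %s%s   rule: %s%s\n", x$method,
              if (isTRUE(x$conjecture)) " (conjecture)" else "",
              x$rule,
              if (is.na(x$state_count)) ""
              else sprintf("   states: %d", x$state_count)))
  if (!is.null(x$graph)) cat(sprintf("  graph : %s\n", x$graph))
  invisible(x)
}

#' All integer partitions of N
#'
#' Non-increasing positive parts summing to `N`, used to check the two
#' closed forms for the complete graph against each other across every
#' abundance configuration.
#'
#' @param N Positive integer.
#' @return List of integer vectors.
#' @export
integer_partitions <- function(N) {
  rec <- function(n, maxpart) {
    if (n == 0L) return(list(integer(0)))
    out <- list()
    for (k in seq.int(min(n, maxpart), 1L)) {
      for (rest in rec(n - k, k)) out[[length(out) + 1L]] <- c(k, rest)
    }
    out
  }
  rec(as.integer(N), as.integer(N))
}
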