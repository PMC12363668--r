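#' Canonical code of an undirected graph
#'
#' A byte string identifying the isomorphism class: the graph is relabeled
#' by igraph's canonical permutation (BLISS) and the canonical form is
#' serialized as graph6. Two undirected simple graphs receive the same code
#' exactly when they are isomorphic.
#'
#' @param g An undirected [evograph] without self-loops.
#' @return Character scalar.
#' @examples
#' canonical_code(make_path(4)) != canonical_code(make_star(4))
#' @export
canonical_code <- function(g) {
  if (!is_undirected(g))
    stop("canonical_code supports undirected graphs", call. = FALSE)
  if (has_self_loops(g))
    stop("canonical_code supports simple graphs (no self-loops)",
         call. = FALSE)
  canonical_code_edges(g$n, g$edges[g$edges[, 1L] < g$edges[, 2L], ,
                                    drop = FALSE])
}

# canonical graph6 code from n and unordered pairs (u < v); avoids evograph
# construction overhead on the enumeration hot path
canonical_code_edges <- function(n, pairs) {
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(pairs)) ig <- igraph::add_edges(ig, t(pairs))
  perm <- igraph::canonical_permutation(ig)$labeling
  if (nrow(pairs)) {
    a <- perm[pairs[, 1L]]; b <- perm[pairs[, 2L]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  } else {
    a <- integer(0); b <- integer(0)
  }
  graph6_from_pairs(n, a, b)
}

# graph6 straight from unordered pair vectors (u < v), no evograph object
graph6_from_pairs <- function(n, a, b) {
  if (n > 62L) stop("graph6 writer supports N <= 62", call. = FALSE)
  nbits <- n * (n - 1L) / 2L
  bits <- logical(nbits)
  if (length(a)) {
    # upper-triangle column-major position of (i, j), i < j
    pos <- (b - 1L) * (b - 2L) / 2L + a
    bits[pos] <- TRUE
  }
  pad <- (6L - nbits %% 6L) %% 6L
  bits <- c(bits, rep(FALSE, pad))
  vals <- if (length(bits)) {
    colSums(matrix(as.integer(bits), nrow = 6L) * c(32L, 16L, 8L, 4L, 2L, 1L))
  } else integer(0)
  rawToChar(as.raw(c(n + 63L, vals + 63L)))
}

#' Enumerate connected graphs up to isomorphism
#'
#' Generates exactly one representative per isomorphism class of connected
#' undirected simple graphs on `N` vertices, by vertex augmentation: each
#' representative on `N - 1` vertices is extended by a new vertex attached
#' to every nonempty subset of the old vertices, and candidates are
#' deduplicated by canonical code. Removing a non-cut vertex from any
#' connected graph leaves a connected graph, so every class is reached.
#' Counts for `N = 1..8` are 1, 1, 2, 6, 21, 112, 853, 11117.
#'
#' @param N Number of vertices, `1 <= N <= 8` (the `N = 8` run takes on the
#'   order of a minute; larger `N` is out of capacity).
#' @param as_graph6 Return graph6 strings instead of [evograph] objects.
#' @return List of [evograph] (or character vector of graph6 codes), sorted
#'   by canonical code for a deterministic order.
#' @export
enumerate_connected_graphs <- function(N, as_graph6 = FALSE) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 1L)
    stop("need N >= 1", call. = FALSE)
  if (N > 8L)
    stop("enumeration capacity is N <= 8", call. = FALSE)
  # representatives kept as lists of unordered pair matrices
  reps <- list(matrix(integer(0), 0L, 2L))  # K1
  n <- 1L
  while (n < N) {
    n <- n + 1L
    seen <- new.env(hash = TRUE, size = 4096L)
    nxt <- list()
    subsets <- lapply(seq_len(2L^(n - 1L) - 1L), function(m)
      which(bitwAnd(m, 2L^(seq_len(n - 1L) - 1L)) > 0L))
    for (g in reps) {
      for (S in subsets) {
        cand <- rbind(g, cbind(S, rep.int(n, length(S))))
        code <- canonical_code_edges(n, cand)
        if (!exists(code, envir = seen, inherits = FALSE)) {
          assign(code, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- list(edges = cand, code = code)
        }
      }
    }
    nxt <- nxt[order(vapply(nxt, `[[`, character(1), "code"))]
    reps <- lapply(nxt, `[[`, "edges")
    codes <- vapply(nxt, `[[`, character(1), "code")
  }
  if (N == 1L) codes <- graph6_from_pairs(1L, integer(0), integer(0))
  if (as_graph6) return(codes)
  out <- lapply(seq_along(reps), function(i) {
    e <- reps[[i]]
    edges <- if (nrow(e)) both_ways(e) else matrix(integer(0), 0L, 2L)
    evograph(N, edges, name = codes[i])
  })
  out
}

#' Random connected graph fixtures
#'
#' `random_connected_graph` draws an Erdos-Renyi undirected graph and
#' resamples until it is connected; `random_strong_digraph` does the same
#' for directed graphs (each ordered pair independently, self-loops
#' excluded) until strongly connected. These are test fixtures, not study
#' objects. Both use R's RNG (`set.seed()`).
#'
#' @param N Number of vertices (`>= 2`).
#' @param p Edge probability in `(0, 1]`.
#' @param max_tries Resampling bound (error past it).
#' @return An [evograph].
#' @export
random_connected_graph <- function(N, p, max_tries = 1e4) {
  N <- as.integer(N)
  if (N < 2L) stop("need N >= 2", call. = FALSE)
  if (p <= 0 || p > 1) stop("p must be in (0, 1]", call. = FALSE)
  idx <- t(utils::combn(N, 2L))
  for (k in seq_len(max_tries)) {
    keep <- stats::runif(nrow(idx)) < p
    if (!any(keep)) next
    g <- evograph(N, both_ways(idx[keep, , drop = FALSE]))
    if (is_strongly_connected(g)) return(g)
  }
  stop("failed to draw a connected graph in ", max_tries, " tries",
       call. = FALSE)
}

#' @rdname random_connected_graph
#' @export
random_strong_digraph <- function(N, p, max_tries = 1e4) {
  N <- as.integer(N)
  if (N < 2L) stop("need N >= 2", call. = FALSE)
  if (p <= 0 || p > 1) stop("p must be in (0, 1]", call. = FALSE)
  all_pairs <- cbind(rep(seq_len(N), each = N), rep.int(seq_len(N), N))
  all_pairs <- all_pairs[all_pairs[, 1L] != all_pairs[, 2L], , drop = FALSE]
  for (k in seq_len(max_tries)) {
    keep <- stats::runif(nrow(all_pairs)) < p
    if (!any(keep)) next
    g <- evograph(N, all_pairs[keep, , drop = FALSE])
    if (is_strongly_connected(g)) return(g)
  }
  stop("failed to draw a strongly connected digraph in ", max_tries,
       " tries", call. = FALSE)
}

#' Graph edit distance (equal order)
#'
#' Minimum number of edge insertions/deletions needed to turn `g` into a
#' graph isomorphic to `h`, computed as the minimum over all vertex
#' bijections of the symmetric difference of edge sets (brute force over
#' `N!` permutations with a degree-sequence shortcut). Both graphs must be
#' undirected, simple, and of the same order; `N <= 8`.
#'
#' @param g,h Undirected [evograph]s of equal order.
#' @return Nonnegative integer.
#' @examples
#' graph_edit_distance(make_path(3), make_cycle(3)) # 1
#' @export
graph_edit_distance <- function(g, h) {
  if (!is_undirected(g) || !is_undirected(h))
    stop("edit distance supports undirected graphs", call. = FALSE)
  if (g$n != h$n)
    stop("edit distance is implemented for graphs of equal order",
         call. = FALSE)
  if (g$n > 8L) stop("edit distance capacity is N <= 8", call. = FALSE)
  n <- g$n
  A <- matrix(FALSE, n, n); A[g$edges] <- TRUE
  B <- matrix(FALSE, n, n); B[h$edges] <- TRUE
  if (identical(canonical_code(g), canonical_code(h))) return(0L)
  best <- Inf
  for (p in all_permutations(n)) {
    d <- sum(A[p, p] != B) / 2L
    if (d < best) best <- d
  }
  as.integer(best)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  prev <- all_permutations(n - 1L)
  out <- vector("list", n * length(prev))
  k <- 0L
  for (p in prev) {
    for (pos in seq_len(n)) {
      out[[k <- k + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
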