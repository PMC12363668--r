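#' Canonical graph families
#'
#' Constructors for the population structures studied throughout the package.
#' All constructors return strongly connected [evograph] objects with vertices
#' `1..N`; the roles of special vertices (centers, clique attachment points)
#' are documented per family.
#'
#' * `make_complete(N)` — well-mixed population. With `self_loops = TRUE`
#'   the edge set is the full Cartesian product (every vertex has out-degree
#'   `N`); without, all ordered pairs `u != v`.
#' * `make_cycle(N)` — 2-regular closed loop, `N >= 3`.
#' * `make_path(N)` — undirected path, `N >= 2`; endpoints are vertices 1
#'   and `N`.
#' * `make_star(N)` — one hub (vertex 1) connected to `n = N - 1` leaves.
#' * `make_double_star(N)` — two adjacent hubs (vertices 1 and 2) sharing
#'   the `N - 2` leaves; for odd `N` hub 1 carries the extra leaf.
#' * `make_barbell(n)` — two `n`-cliques joined by an `n`-vertex path
#'   (`N = 3n`). Vertices `1..n` form clique 1 (vertex 1 is its attachment
#'   point), `n+1 .. 2n` the path (endpoints `n+1`, `2n`), `2n+1 .. 3n`
#'   clique 2 (attachment `2n+1`). Each path endpoint attaches to exactly one
#'   clique vertex, so path endpoints have degree 2 and attachment vertices
#'   degree `n`.
#' * `make_contracting_star(N, b)` — directed: a center (vertex 1) with `b`
#'   blades of `m = (N-1)/b` vertices. Each blade is a bidirectional path,
#'   ordered innermost to outermost, plus one-way "contracting" edges from
#'   every outer blade vertex to every inner blade vertex; the innermost
#'   vertex links bidirectionally to the center. The center itself receives
#'   no long-range contracting edges.
#'
#' @param N Number of vertices.
#' @param self_loops Include loops `(u,u)` (complete graph only).
#' @param n Clique / path size for the barbell (`N = 3n`).
#' @param b Number of blades; must divide `N - 1`.
#' @return An [evograph].
#' @examples
#' make_star(10)
#' make_contracting_star(9, b = 2)
#' @name families
NULL

#' @rdname families
#' @export
make_complete <- function(N, self_loops = TRUE) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 1L)
    stop("complete graph needs N >= 1", call. = FALSE)
  e <- cbind(rep(seq_len(N), each = N), rep.int(seq_len(N), N))
  if (!self_loops) {
    if (N < 2L) stop("complete graph without loops needs N >= 2", call. = FALSE)
    e <- e[e[, 1L] != e[, 2L], , drop = FALSE]
  }
  evograph(N, e, name = if (self_loops) sprintf("complete_%d", N)
                        else sprintf("complete_no_loops_%d", N))
}

#' @rdname families
#' @export
make_cycle <- function(N) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 3L)
    stop("cycle needs N >= 3", call. = FALSE)
  pairs <- cbind(seq_len(N), c(seq_len(N)[-1L], 1L))
  evograph(N, both_ways(pairs), name = sprintf("cycle_%d", N))
}

#' @rdname families
#' @export
make_path <- function(N) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 2L)
    stop("path needs N >= 2", call. = FALSE)
  pairs <- cbind(seq_len(N - 1L), seq_len(N - 1L) + 1L)
  evograph(N, both_ways(pairs), name = sprintf("path_%d", N))
}

#' @rdname families
#' @export
make_star <- function(N) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 2L)
    stop("star needs N >= 2", call. = FALSE)
  pairs <- cbind(1L, seq.int(2L, N))
  evograph(N, both_ways(pairs), name = sprintf("star_%d", N))
}

#' @rdname families
#' @export
make_double_star <- function(N) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 4L)
    stop("double star needs N >= 4", call. = FALSE)
  n1 <- as.integer(ceiling((N - 2L) / 2))   # leaves on hub 1
  leaves1 <- if (n1 > 0L) seq.int(3L, 2L + n1) else integer(0)
  leaves2 <- if (N - 2L - n1 > 0L) seq.int(3L + n1, N) else integer(0)
  pairs <- rbind(c(1L, 2L),
                 cbind(1L, leaves1),
                 cbind(2L, leaves2))
  evograph(N, both_ways(pairs), name = sprintf("double_star_%d", N))
}

#' @rdname families
#' @export
make_barbell <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("barbell needs clique size n >= 2", call. = FALSE)
  N <- 3L * n
  clique_pairs <- function(v) {
    idx <- t(utils::combn(v, 2L))
    matrix(as.integer(idx), ncol = 2L)
  }
  path_v <- seq.int(n + 1L, 2L * n)
  pairs <- rbind(
    clique_pairs(seq_len(n)),
    clique_pairs(seq.int(2L * n + 1L, 3L * n)),
    if (n > 1L) cbind(path_v[-n], path_v[-1L]),
    c(1L, n + 1L),          # clique-1 attachment <-> path start
    c(2L * n + 1L, 2L * n)  # clique-2 attachment <-> path end
  )
  evograph(N, both_ways(pairs), name = sprintf("barbell_%d", n))
}

#' @rdname families
#' @export
make_contracting_star <- function(N, b) {
  N <- as.integer(N); b <- as.integer(b)
  if (length(N) != 1L || is.na(N) || N < 3L)
    stop("contracting star needs N >= 3", call. = FALSE)
  if (length(b) != 1L || is.na(b) || b < 1L || (N - 1L) %% b != 0L)
    stop("blade count b must be >= 1 and divide N - 1", call. = FALSE)
  m <- (N - 1L) %/% b
  edges <- list()
  for (k in seq_len(b)) {
    blade <- 1L + (k - 1L) * m + seq_len(m)  # innermost .. outermost
    edges[[length(edges) + 1L]] <- rbind(c(1L, blade[1L]), c(blade[1L], 1L))
    if (m > 1L) {
      path <- cbind(blade[-m], blade[-1L])
      edges[[length(edges) + 1L]] <- both_ways(path)
      # one-way contracting edges: outer -> inner, skipping the immediate
      # predecessor already covered by the bidirectional path
      if (m >= 3L) for (j in seq.int(3L, m))
        edges[[length(edges) + 1L]] <- cbind(blade[j], blade[seq_len(j - 2L)])
    }
  }
  e <- do.call(rbind, edges)
  evograph(N, e, name = sprintf("contracting_star_%d_b%d", N, b))
}

#' Build a graph family by name
#'
#' Dispatch helper used by the analysis drivers and the command line:
#' maps a family tag and size to the matching constructor.
#'
#' @param family One of `"complete"`, `"complete_no_loops"`, `"cycle"`,
#'   `"path"`, `"star"`, `"double_star"`, `"barbell"`, `"contracting_star"`.
#' @param N Number of vertices (for the barbell, `N` must be `3n`).
#' @param b Blade count (contracting star only).
#' @return An [evograph].
#' @export
make_family <- function(family, N, b = 2L) {
  family <- match.arg(family, c("complete", "complete_no_loops", "cycle",
                                "path", "star", "double_star", "barbell",
                                "contracting_star"))
  switch(family,
    complete = make_complete(N, self_loops = TRUE),
    complete_no_loops = make_complete(N, self_loops = FALSE),
    cycle = make_cycle(N),
    path = make_path(N),
    star = make_star(N),
    double_star = make_double_star(N),
    barbell = {
      if (N %% 3L != 0L) stop("barbell needs N divisible by 3", call. = FALSE)
      make_barbell(N %/% 3L)
    },
    contracting_star = make_contracting_star(N, b)
  )
}
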