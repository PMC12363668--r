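#' Population-structure graph
#'
#' An `evograph` stores a strongly-connected-capable directed graph on
#' vertices `1..N`. Edges are a set of ordered pairs; an undirected edge is
#' stored as both `(u,v)` and `(v,u)`, and self-loops are permitted. Vertices
#' are the locations of individuals; an edge `(u,v)` means the offspring of
#' the individual at `u` may replace the individual at `v`.
#'
#' @param n_vertices Number of vertices (positive integer).
#' @param edges Two-column integer matrix of ordered pairs `(from, to)`,
#'   indices in `1..n_vertices`. Duplicate ordered pairs are an error.
#' @param name Optional label (family tag or identifier) carried in outputs.
#' @return An object of class `evograph` with fields `n` and `edges`.
#' @examples
#' g <- evograph(3, rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2)))
#' degree_out(g)
#' @export
evograph <- function(n_vertices, edges, name = NULL) {
  n <- as.integer(n_vertices)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("n_vertices must be a positive integer", call. = FALSE)
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  if (nrow(edges) > 0L) {
    if (anyNA(edges) || any(edges < 1L) || any(edges > n))
      stop("edge endpoints must be vertex indices in 1..", n, call. = FALSE)
    key <- (edges[, 1L] - 1L) * n + edges[, 2L]
    if (anyDuplicated(key))
      stop("duplicate ordered edges are not allowed (edge set, not multiset)",
           call. = FALSE)
    edges <- edges[order(key), , drop = FALSE]
  }
  structure(list(n = n, edges = edges, name = name), class = "evograph")
}

#' @export
print.evograph <- function(x, ...) {
  kind <- if (is_undirected(x)) "undirected" else "directed"
  cat(sprintf("<evograph%s: %d vertices, %d ordered edges, %s>\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$n, nrow(x$edges), kind))
  invisible(x)
}

#' @export
summary.evograph <- function(object, ...) {
  cat(sprintf("Population-structure graph on %d vertices\n", object$n))
  cat(sprintf("  ordered edges      : %d\n", nrow(object$edges)))
  cat(sprintf("  undirected         : %s\n", is_undirected(object)))
  cat(sprintf("  regular            : %s\n", is_regular(object)))
  cat(sprintf("  strongly connected : %s\n", is_strongly_connected(object)))
  cat(sprintf("  out-degrees        : %s\n",
              paste(degree_out(object), collapse = " ")))
  invisible(object)
}

#' Vertex degrees
#'
#' Out-degree counts outgoing edges, in-degree incoming edges; a self-loop
#' counts once in each (so the complete graph with loops has out-degree N).
#' `degree_undirected` requires a symmetric edge set and excludes none.
#'
#' @param g An `evograph`.
#' @return Integer vector of length `g$n`.
#' @export
degree_out <- function(g) {
  tabulate(g$edges[, 1L], nbins = g$n)
}

#' @rdname degree_out
#' @export
degree_in <- function(g) {
  tabulate(g$edges[, 2L], nbins = g$n)
}

#' @rdname degree_out
#' @export
degree_undirected <- function(g) {
  if (!is_undirected(g)) stop("graph is not undirected", call. = FALSE)
  degree_out(g)
}

#' Structural predicates
#'
#' A graph is undirected when the ordered-edge set is symmetric; regular when
#' all vertices share the same out-degree and the same in-degree; strong
#' connectivity is checked with igraph.
#'
#' @param g An `evograph`.
#' @return Logical scalar.
#' @export
is_undirected <- function(g) {
  e <- g$edges
  if (nrow(e) == 0L) return(TRUE)
  fwd <- (e[, 1L] - 1L) * g$n + e[, 2L]
  rev <- (e[, 2L] - 1L) * g$n + e[, 1L]
  all(rev %in% fwd)
}

#' @rdname is_undirected
#' @export
is_regular <- function(g) {
  dout <- degree_out(g)
  din <- degree_in(g)
  all(dout == dout[1L]) && all(din == din[1L])
}

#' @rdname is_undirected
#' @export
is_strongly_connected <- function(g) {
  if (g$n == 1L) return(TRUE)
  if (nrow(g$edges) == 0L) return(FALSE)
  igraph::is_connected(as_igraph(g), mode = "strong")
}

#' @rdname is_undirected
#' @export
has_self_loops <- function(g) {
  any(g$edges[, 1L] == g$edges[, 2L])
}

#' Convert to an igraph object
#'
#' @param g An `evograph`.
#' @param undirected Collapse the symmetric ordered-pair representation to
#'   one undirected igraph edge per pair (requires an undirected graph).
#' @return An igraph graph.
#' @export
as_igraph <- function(g, undirected = FALSE) {
  if (undirected) {
    if (!is_undirected(g)) stop("graph is not undirected", call. = FALSE)
    e <- g$edges[g$edges[, 1L] <= g$edges[, 2L], , drop = FALSE]
    ig <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  } else {
    e <- g$edges
    ig <- igraph::make_empty_graph(n = g$n, directed = TRUE)
  }
  if (nrow(e)) ig <- igraph::add_edges(ig, t(e))
  ig
}

# out-/in-neighbor lists (list of integer vectors, one per vertex)
neighbors_out <- function(g) {
  split(g$edges[, 2L], factor(g$edges[, 1L], levels = seq_len(g$n)))
}

neighbors_in <- function(g) {
  split(g$edges[, 1L], factor(g$edges[, 2L], levels = seq_len(g$n)))
}

# symmetric (u,v)&(v,u) pairs from a two-column matrix of unordered pairs
both_ways <- function(pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  rbind(pairs, pairs[, 2:1, drop = FALSE])
}

#' Normalized degree entropy
#'
#' Shannon entropy of the degree-proportional distribution over vertices,
#' divided by `log N`:
#' \deqn{-\frac{1}{\log N}\sum_u p(u)\log p(u), \quad
#'       p(u) = \deg(u) / \sum_v \deg(v).}
#' Equals 1 exactly when the degree distribution is uniform (regular graphs)
#' and decreases as the graph becomes more hub-dominated; over undirected
#' graphs of a given size the star attains the minimum.
#'
#' @param g An undirected `evograph` with at least one edge, `N >= 2`.
#' @return A number in `[0, 1]`.
#' @examples
#' degree_entropy(make_star(8)) # about 0.8012
#' @export
degree_entropy <- function(g) {
  if (!is_undirected(g))
    stop("degree_entropy is defined for undirected graphs", call. = FALSE)
  if (g$n < 2L || nrow(g$edges) == 0L)
    stop("need N >= 2 and at least one edge", call. = FALSE)
  d <- degree_out(g)
  p <- d / sum(d)
  p <- p[p > 0]
  -sum(p * log(p)) / log(g$n)
}
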