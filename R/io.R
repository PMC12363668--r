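#' Graph file formats
#'
#' graph6 is the compact printable-ASCII encoding of undirected simple graphs
#' used by graph-enumeration tools: one header byte `N + 63` (for `N <= 62`),
#' then the upper-triangle adjacency bits in column-major order, packed into
#' 6-bit groups (zero-padded) and offset by 63. Only undirected graphs
#' without self-loops can be encoded. The TSV edge-list format carries
#' directed graphs: `#`-comment lines, a `directed=true|false` flag line,
#' then `u<TAB>v` ordered pairs with 0-based vertex indices on disk.
#'
#' @param text A graph6 string (one graph).
#' @param g An [evograph].
#' @param file Path or connection for the edge-list reader/writer.
#' @param name Optional name for the decoded graph.
#' @return `read_*` return an [evograph]; `write_graph6` a character scalar;
#'   `write_edge_list` (invisibly) the lines written.
#' @examples
#' write_graph6(make_cycle(3)) # "Bw"
#' read_graph6("Bg")           # path on 3 vertices
#' @name graph_io
NULL

#' @rdname graph_io
#' @export
write_graph6 <- function(g) {
  if (!is_undirected(g))
    stop("graph6 encodes undirected graphs only", call. = FALSE)
  if (has_self_loops(g))
    stop("graph6 cannot encode self-loops", call. = FALSE)
  n <- g$n
  if (n > 62L)
    stop("graph6 writer supports N <= 62", call. = FALSE)
  adj <- matrix(FALSE, n, n)
  if (nrow(g$edges)) adj[g$edges] <- TRUE
  bits <- logical(0)
  if (n >= 2L) {
    # columns j = 2..n, rows i = 1..j-1 (upper triangle, column-major)
    bits <- unlist(lapply(seq.int(2L, n), function(j) adj[seq_len(j - 1L), j]))
  }
  pad <- (6L - length(bits) %% 6L) %% 6L
  bits <- c(bits, rep(FALSE, pad))
  vals <- if (length(bits)) {
    colSums(matrix(as.integer(bits), nrow = 6L) * c(32L, 16L, 8L, 4L, 2L, 1L))
  } else integer(0)
  rawToChar(as.raw(c(n + 63L, vals + 63L)))
}

#' @rdname graph_io
#' @export
read_graph6 <- function(text, name = NULL) {
  if (length(text) != 1L || !is.character(text))
    stop("expected a single graph6 string", call. = FALSE)
  bytes <- as.integer(charToRaw(text))
  if (length(bytes) < 1L || any(bytes < 63L) || any(bytes > 126L))
    stop("malformed graph6 bytes", call. = FALSE)
  n <- bytes[1L] - 63L
  if (n == 63L)
    stop("graph6 reader supports N <= 62", call. = FALSE)
  nbits <- n * (n - 1L) / 2L
  need <- ceiling(nbits / 6L)
  if (length(bytes) - 1L != need)
    stop("graph6 payload length does not match vertex count", call. = FALSE)
  vals <- bytes[-1L] - 63L
  bits <- as.logical(unlist(lapply(vals, function(v)
    bitwAnd(bitwShiftR(v, 5:0), 1L))))
  if (any(bits[seq_len(need * 6L) > nbits]))
    stop("nonzero padding bits in graph6 payload", call. = FALSE)
  pairs <- NULL
  if (n >= 2L) {
    j <- rep(seq.int(2L, n), times = seq_len(n - 1L))
    i <- unlist(lapply(seq.int(2L, n), function(jj) seq_len(jj - 1L)))
    keep <- bits[seq_len(nbits)]
    pairs <- cbind(i[keep], j[keep])
  }
  edges <- if (is.null(pairs) || nrow(pairs) == 0L) {
    matrix(integer(0), ncol = 2L)
  } else both_ways(pairs)
  evograph(n, edges, name = name)
}

#' @rdname graph_io
#' @export
write_edge_list <- function(g, file) {
  lines <- c(sprintf("# evodiv edge list, N=%d", g$n),
             sprintf("directed=%s", if (is_undirected(g)) "false" else "true"),
             sprintf("%d\t%d", g$edges[, 1L] - 1L, g$edges[, 2L] - 1L))
  writeLines(lines, file)
  invisible(lines)
}

#' @rdname graph_io
#' @export
read_edge_list <- function(file, name = NULL) {
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L || !grepl("^directed=(true|false)$", lines[1L]))
    stop("edge list must start with a 'directed=true|false' line",
         call. = FALSE)
  directed <- identical(lines[1L], "directed=true")
  body <- lines[-1L]
  if (length(body) == 0L) stop("edge list has no edges", call. = FALSE)
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("edge lines must be 'u<TAB>v'", call. = FALSE)
  uv <- matrix(suppressWarnings(as.integer(unlist(parts))),
               ncol = 2L, byrow = TRUE)
  if (anyNA(uv) || any(uv < 0L))
    stop("vertex indices must be nonnegative integers", call. = FALSE)
  n <- max(uv) + 1L
  edges <- uv + 1L
  if (!directed) {
    # undirected files may list each pair once; symmetrize and dedupe
    edges <- unique(rbind(edges, edges[, 2:1, drop = FALSE]))
  }
  evograph(n, edges, name = name)
}

#' Read or write many graph6 graphs
#'
#' One graph6 string per line, the format used by the enumeration driver.
#'
#' @param graphs List of [evograph] objects.
#' @param file Path or connection.
#' @return `read_graph6_file` returns a list of [evograph].
#' @export
write_graph6_file <- function(graphs, file) {
  writeLines(vapply(graphs, write_graph6, character(1)), file)
  invisible(NULL)
}

#' @rdname write_graph6_file
#' @export
read_graph6_file <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, read_graph6)
}
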