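# Independent oracles and small fixtures shared across the suite. These are
# written against first principles (dense first-step systems, brute-force
# enumeration) and deliberately avoid the package's own solver internals.

# sorted "u>v" strings for edge-set comparison
edge_key <- function(g) {
  sort(sprintf("%d>%d", g$edges[, 1L], g$edges[, 2L]))
}

# Dense first-step oracle on the full labeled chain: expected steps to
# homogeneity from x0, built directly from the update-rule definition with
# its own state indexing and a dense solve.
oracle_absorption_full <- function(g, rule, x0 = seq_len(g$n)) {
  N <- g$n
  S <- N^N
  idx_of <- function(x) sum((x - 1L) * N^(seq_len(N) - 1L)) + 1L
  x_of <- function(s) ((s - 1L) %/% N^(seq_len(N) - 1L)) %% N + 1L
  if (rule == "bd") {
    dout <- tabulate(g$edges[, 1L], N)
    prob <- 1 / (N * dout[g$edges[, 1L]])
  } else {
    din <- tabulate(g$edges[, 2L], N)
    prob <- 1 / (N * din[g$edges[, 2L]])
  }
  P <- matrix(0, S, S)
  homog <- logical(S)
  for (s in seq_len(S)) {
    x <- x_of(s)
    homog[s] <- length(unique(x)) == 1L
    for (e in seq_len(nrow(g$edges))) {
      x2 <- x
      x2[g$edges[e, 2L]] <- x[g$edges[e, 1L]]
      P[s, idx_of(x2)] <- P[s, idx_of(x2)] + prob[e]
    }
  }
  tr <- which(!homog)
  tau <- solve(diag(length(tr)) - P[tr, tr, drop = FALSE], rep(1, length(tr)))
  s0 <- idx_of(as.integer(x0))
  if (homog[s0]) 0 else tau[match(s0, tr)]
}

# Brute-force isomorph-free census of connected graphs on n labeled
# vertices: every edge subset, connectivity by search, dedup by
# canonical_code. Independent of the augmentation generator.
oracle_connected_count <- function(n) {
  if (n == 1L) return(1L)
  pairs <- t(utils::combn(n, 2L))
  m <- nrow(pairs)
  seen <- new.env(hash = TRUE)
  count <- 0L
  for (mask in seq_len(2L^m - 1L)) {
    keep <- bitwAnd(mask, 2L^(seq_len(m) - 1L)) > 0L
    if (sum(keep) < n - 1L) next
    e <- pairs[keep, , drop = FALSE]
    # connectivity by union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (k in seq_len(nrow(e))) {
      a <- find(e[k, 1L]); b <- find(e[k, 2L])
      if (a != b) parent[a] <- b
    }
    if (length(unique(vapply(seq_len(n), find, integer(1)))) != 1L) next
    g <- evograph(n, rbind(e, e[, 2:1, drop = FALSE]))
    code <- canonical_code(g)
    if (!exists(code, envir = seen, inherits = FALSE)) {
      assign(code, TRUE, envir = seen)
      count <- count + 1L
    }
  }
  count
}

# every connected undirected graph on <= 4 vertices, one per iso class
fixture_connected_graphs <- function(max_n = 4L) {
  unlist(lapply(seq_len(max_n), enumerate_connected_graphs), recursive = FALSE)
}
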