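# One-step kernel audit helpers. From an all-distinct configuration every
# ordered replacement event (u gives birth into v) is identifiable from the
# changed vertex and its new type, so empirical event frequencies can be
# compared against the update-rule probabilities.

audit_kernel <- function(g, rule, draws = 1e5) {
  N <- g$n
  x <- seq_len(N)
  counts <- matrix(0L, N, N)  # counts[u, v]
  for (i in seq_len(draws)) {
    y <- step_once(g, x, rule)
    v <- which(y != x)
    stopifnot(length(v) == 1L)
    counts[y[v], v] <- counts[y[v], v] + 1L
  }
  counts
}

expected_kernel <- function(g, rule) {
  N <- g$n
  p <- matrix(0, N, N)
  if (rule == "bd") {
    dout <- degree_out(g)
    p[g$edges] <- 1 / (N * dout[g$edges[, 1L]])
  } else {
    din <- degree_in(g)
    p[g$edges] <- 1 / (N * din[g$edges[, 2L]])
  }
  p
}
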