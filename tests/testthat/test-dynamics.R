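test_that("one-step event frequencies match the update-rule probabilities", {
  set.seed(101)
  draws <- 1e5
  for (case in list(list(g = make_star(4), rule = "bd"),
                    list(g = make_star(4), rule = "db"),
                    list(g = make_cycle(4), rule = "bd"))) {
    counts <- audit_kernel(case$g, case$rule, draws)
    p <- expected_kernel(case$g, case$rule)
    for (e in seq_len(nrow(case$g$edges))) {
      u <- case$g$edges[e, 1L]; v <- case$g$edges[e, 2L]
      tol <- 4 * sqrt(draws * p[u, v] * (1 - p[u, v]))
      expect_lt(abs(counts[u, v] - draws * p[u, v]), tol)
    }
  }
})

test_that("star event probabilities have the known special values", {
  # bd: a given leaf's offspring replaces the hub with probability 1/4
  expect_equal(expected_kernel(make_star(4), "bd")[2, 1], 1 / 4)
  # db: each (leaf -> hub) event has probability 1/(N deg-(hub)) = 1/12,
  # and the hub is selected for death with total probability 1/N
  pdb <- expected_kernel(make_star(4), "db")
  expect_equal(sum(pdb[2:4, 1]), 1 / 4)
  # regular graph: every ordered edge event has probability 1/(N D), both rules
  expect_true(all(abs(expected_kernel(make_cycle(4), "bd") -
                      expected_kernel(make_cycle(4), "db")) < 1e-15))
})

test_that("absorption simulation has the contract's basic properties", {
  g2 <- make_path(2)
  # single edge, two types: exactly one step, always
  for (s in 1:25) {
    r <- simulate_to_absorption(g2, "bd", seed = s)
    expect_equal(r$time, 1)
    r <- simulate_to_absorption(g2, "db", seed = s)
    expect_equal(r$time, 1)
  }
  # homogeneous start absorbs in 0 steps
  r <- simulate_to_absorption(make_cycle(5), "bd", x0 = rep(2L, 5), seed = 1)
  expect_equal(r$time, 0)
  expect_equal(r$winner, 2L)
  # determinism under a fixed seed
  a <- simulate_to_absorption(make_star(6), "bd", seed = 77)
  b <- simulate_to_absorption(make_star(6), "bd", seed = 77)
  expect_identical(a, b)
  # censoring is explicit
  r <- simulate_to_absorption(make_cycle(8), "bd", seed = 1, max_steps = 3)
  expect_true(r$censored)
  expect_true(is.na(r$winner))
})

test_that("replicate estimates are reproducible and respect the step floor", {
  g <- make_complete(6)
  s1 <- estimate_absorption_time(g, "bd", reps = 50, seed = 9)
  s2 <- estimate_absorption_time(g, "bd", reps = 50, seed = 9)
  expect_identical(s1$times, s2$times)
  # at least N - 1 replacements are needed from maximal diversity
  expect_true(all(s1$times >= g$n - 1))
  # winners come from the initial types
  expect_true(all(s1$winners %in% seq_len(g$n)))
  expect_error(estimate_absorption_time(g, "bd", reps = 0), "reps")
})

test_that("simulated means match exact expectations within 3 standard errors", {
  s <- estimate_absorption_time(make_complete(8), "bd", reps = 250, seed = 5)
  expect_lt(abs(s$mean - 56), 3 * s$se)
  s <- estimate_absorption_time(make_cycle(10), "db", reps = 250, seed = 6)
  expect_lt(abs(s$mean - 165), 3 * s$se)
  s <- estimate_absorption_time(make_star(3), "bd", reps = 1000, seed = 7)
  expect_lt(abs(s$mean - 7), 3 * s$se)
})

test_that("diversity is non-increasing along trajectories", {
  set.seed(11)
  g <- make_cycle(6)
  x <- seq_len(6)
  div <- length(unique(x))
  for (t in 1:400) {
    x <- step_once(g, x, "bd")
    d <- length(unique(x))
    expect_lte(d, div)
    div <- d
  }
  expect_equal(div, 1L)  # cycle(6) absorbs well within 400 steps on average
})

test_that("bd and db absorption-time distributions coincide on regular graphs", {
  g <- make_cycle(8)
  t_bd <- estimate_absorption_time(g, "bd", reps = 2000, seed = 31)$times
  t_db <- estimate_absorption_time(g, "db", reps = 2000, seed = 32)$times
  ks <- suppressWarnings(stats::ks.test(t_bd, t_db))
  expect_gt(ks$p.value, 0.01)
})

test_that("winners are uniform over types on a vertex-transitive graph", {
  g <- make_cycle(6)
  w <- estimate_absorption_time(g, "bd", reps = 5000, seed = 41)$winners
  cs <- stats::chisq.test(tabulate(w, 6))
  expect_gt(cs$p.value, 0.01)
})

test_that("characteristic curves start at N, end at 1, and never increase", {
  g <- make_complete(10)
  cur <- characteristic_curve(g, "bd", reps = 250,
                              time_points = c(0, 10, 100, 1e5), seed = 51)
  expect_equal(cur$mean_diversity[1], 10)
  expect_equal(cur$mean_diversity[4], 1)
  expect_true(all(diff(cur$mean_diversity) <= 0))
  expect_error(characteristic_curve(g, "bd", reps = 10,
                                    time_points = c(5, 5), seed = 1),
               "increasing")
})
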