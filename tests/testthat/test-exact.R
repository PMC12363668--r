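test_that("b_profile counts histogram boxes above a height", {
  expect_equal(b_profile(c(3, 2), 0), 5)   # b0 = N
  expect_equal(b_profile(c(3, 2), 1), 3)
  expect_equal(b_profile(c(3, 2), 3), 0)
  expect_error(b_profile(integer(0), 0), "positive")
})

test_that("complete-graph closed form matches first principles", {
  # maximal diversity: N (N - 1)
  for (N in c(2, 5, 8, 12))
    expect_equal(complete_time(rep(1, N))$expected_time, N * (N - 1))
  # homogeneous start
  expect_equal(complete_time(7)$expected_time, 0)
  # lambda = (2,1): lazy gambler's-ruin oracle. The abundance of one type
  # walks on {0..3}; each direction moves with probability k(N-k)/N^2.
  # Solve the 2-state dense system directly.
  P <- matrix(0, 2, 2)          # states k = 1, 2
  move <- function(k) k * (3 - k) / 9
  P[1, 2] <- move(1); P[2, 1] <- move(2)
  tau <- solve(diag(2) - diag(1 - 2 * c(move(1), move(2))) - P, c(1, 1))
  expect_equal(complete_time(c(2, 1))$expected_time, tau[2])
  expect_equal(complete_time(c(2, 1))$expected_time, 4.5)
  # lambda = (3,1): histogram form by hand
  expect_equal(complete_time(c(3, 1))$expected_time, 22 / 3)
  # no self-loops, maximal diversity
  expect_equal(complete_time(rep(1, 6), self_loops = FALSE)$expected_time, 25)
  expect_error(complete_time(c(3, 1), self_loops = FALSE), "maximal")
  expect_error(complete_time(numeric(0)), "nonempty")
})

test_that("cycle closed form evaluates the cubic minus the profile term", {
  expect_equal(cycle_time(rep(1, 3))$expected_time, 4)
  expect_equal(cycle_time(rep(1, 10))$expected_time, 165)
  expect_equal(cycle_time(5)$expected_time, 0)
  # triangle cross-oracle: cycle(3) is also the loop-free complete graph
  expect_equal(cycle_time(rep(1, 3))$expected_time,
               complete_time(rep(1, 3), self_loops = FALSE)$expected_time)
})

test_that("star conjecture closed form matches its small-n oracles", {
  expect_equal(star_time_conjecture(1)$expected_time, 1)
  # n = 2 is the 3-vertex path: check against the dense full-chain oracle
  expect_equal(star_time_conjecture(2)$expected_time, 7)
  expect_equal(oracle_absorption_full(make_star(3), "bd"), 7)
  expect_equal(star_time_conjecture(3)$expected_time, 23.5)
  expect_true(isTRUE(star_time_conjecture(4)$conjecture))
})

test_that("Bell numbers count the lumped states", {
  expect_equal(partition_state_count(1), 1)
  expect_equal(partition_state_count(3), 5)
  expect_equal(partition_state_count(8), 4140)
  # matches the instantiated state space of a lumped solve
  for (N in 2:6)
    expect_equal(absorption_time_lumped(make_path(N), "bd")$state_count,
                 partition_state_count(N))
})

test_that("full labeled-chain solver reproduces closed forms and hand values", {
  expect_equal(absorption_time_full(make_complete(3), "bd")$expected_time, 6)
  expect_equal(absorption_time_full(make_path(3), "bd")$expected_time, 7)
  expect_equal(absorption_time_full(make_cycle(4), "db",
                                    x0 = c(2, 2, 2, 2))$expected_time, 0)
  expect_error(absorption_time_full(make_cycle(6), "bd"), "capacity")
})

test_that("lumped solver reproduces family closed forms", {
  for (N in 4:6) {
    expect_equal(absorption_time_lumped(make_complete(N), "bd")$expected_time,
                 N * (N - 1), tolerance = 1e-9)
    expect_equal(absorption_time_lumped(make_cycle(N), "db")$expected_time,
                 (N + 1) * N * (N - 1) / 6, tolerance = 1e-9)
  }
  expect_equal(absorption_time_lumped(make_complete(5, FALSE),
                                      "bd")$expected_time, 16,
               tolerance = 1e-9)
  # absorbing start
  expect_equal(absorption_time_lumped(make_cycle(4), "bd",
                                      partition = rep(1, 4))$expected_time, 0)
  expect_error(absorption_time_lumped(make_path(11), "bd"), "capacity")
})

test_that("cycle formula agrees with the lumped solver for clustered starts", {
  # contiguous clusters on the cycle, N <= 5
  cases <- list(c(1, 1, 2, 2, 3), c(1, 1, 1, 2, 3), c(1, 2, 2, 3, 3),
                c(1, 1, 2, 2, 2), c(1, 1, 2, 3, 3))
  for (part in cases) {
    lam <- sort(tabulate(part), decreasing = TRUE)
    lam <- lam[lam > 0]
    expect_equal(absorption_time_lumped(make_cycle(5), "bd",
                                        partition = part)$expected_time,
                 cycle_time(lam)$expected_time, tolerance = 1e-9,
                 info = paste(part, collapse = ""))
  }
  expect_equal(absorption_time_lumped(make_cycle(4), "db",
                                      partition = c(1, 1, 2, 2))$expected_time,
               cycle_time(c(2, 2))$expected_time, tolerance = 1e-9)
})

test_that("full and lumped chains agree on fixture graphs (lumpability)", {
  for (g in fixture_connected_graphs(4L)) {
    for (rule in c("bd", "db")) {
      full <- absorption_time_full(g, rule)$expected_time
      lump <- absorption_time_lumped(g, rule)$expected_time
      expect_equal(lump, full, tolerance = 1e-9, info = paste(g$name, rule))
    }
  }
  # and against the independent dense oracle on one graph per rule
  g <- make_star(4)
  expect_equal(absorption_time_lumped(g, "bd")$expected_time,
               oracle_absorption_full(g, "bd"), tolerance = 1e-9)
  expect_equal(absorption_time_lumped(g, "db")$expected_time,
               oracle_absorption_full(g, "db"), tolerance = 1e-9)
})

test_that("fixation probabilities follow neutral-drift symmetry and sum to one", {
  # singleton on a vertex-symmetric loop-free complete graph: 1/N
  for (N in c(4, 7, 10))
    expect_equal(fixation_probability(make_complete(N, FALSE), "bd", 1),
                 1 / N, tolerance = 1e-9)
  # focal = everything
  expect_equal(fixation_probability(make_star(5), "db", 1:5), 1)
  # singleton probabilities from maximal diversity sum to 1
  for (g in list(make_star(5), make_double_star(6), make_barbell(2))) {
    for (rule in c("bd", "db")) {
      tot <- sum(vapply(seq_len(g$n), function(v)
        fixation_probability(g, rule, v), numeric(1)))
      expect_equal(tot, 1, tolerance = 1e-9, info = paste(g$name, rule))
    }
  }
  expect_error(fixation_probability(make_star(16), "bd", 1), "capacity")
  expect_error(fixation_probability(make_star(4), "bd", integer(0)),
               "nonempty")
})

test_that("coarser starting partitions never absorb slower than maximal diversity", {
  for (g in list(make_star(5), make_cycle(5), make_double_star(6))) {
    for (rule in c("bd", "db")) {
      res <- absorption_time_lumped(g, rule)
      tmax <- res$expected_time
      n <- g$n
      for (mask in seq_len(2^(n - 1L) - 1L)) {
        part <- ifelse(bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0L, 2L, 1L)
        key <- paste(evodiv:::rgs_canonical(part), collapse = ",")
        expect_lte(res$all_times[[key]], tmax + 1e-9)
      }
    }
  }
})

test_that("integer partitions enumerate all abundance configurations", {
  expect_equal(length(integer_partitions(5)), 7L)
  expect_equal(length(integer_partitions(12)), 77L)
  expect_true(all(vapply(integer_partitions(6), sum, numeric(1)) == 6))
})
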