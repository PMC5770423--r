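# Energy, feedforward inputs, asynchronous threshold dynamics,
# convergence and p-corruption.

test_that("energy matches its defining quadratic form", {
  net <- hopfield_network(matrix(0, 5, 5), rep(1, 5))
  expect_identical(energy(rep(0L, 5), net), 0)           # empty sums
  expect_identical(energy(c(1, 1, 0, 1, 0), net), 3)     # E = theta.x

  # 4-clique in the (2/7, 0, 1) symmetric net on v = 6: hand expansion
  # of the orbit energy -x*S1 - y*S0 + z*#E with S1 = 12, S0 = 3, #E = 6
  p <- symmetric_params(x = 2 / 7, y = 0, z = 1, v = 6)
  net6 <- build_network(p)
  cl <- clique_state(1:4, 6)
  expect_equal(energy(cl, net6), 18 / 7, tolerance = 1e-12)
  expect_equal(energy(cl, net6), naive_energy(cl, net6$W, net6$theta),
               tolerance = 1e-12)

  expect_error(energy(c(0, 1), net), "length")
})

test_that("energy agrees with the naive quadratic form on random nets", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    net <- random_net(n)
    x <- rbinom(n, 1, 0.5)
    expect_equal(energy(x, net), naive_energy(x, net$W, net$theta),
                 tolerance = 1e-12)
  }
})

test_that("feedforward input is the weight-row inner product", {
  net <- hopfield_network(matrix(0, 4, 4), rep(0, 4))
  for (e in 1:4) expect_identical(feedforward_input(rep(1L, 4), net, e), 0)

  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 0.7
  net2 <- hopfield_network(W, c(0, 0))
  expect_equal(feedforward_input(c(0, 1), net2, 1), 0.7)

  # clique edge input = x * (number of active neighboring edges): K4 on
  # v = 6, edge (1,2) has active neighbors (1,3),(1,4),(2,3),(2,4)
  p <- symmetric_params(x = 2 / 7, y = 0, z = 1, v = 6)
  net6 <- build_network(p)
  cl <- clique_state(1:4, 6)
  e12 <- edge_index(1, 2, 6)
  expect_equal(feedforward_input(cl, net6, e12), 4 * 2 / 7,
               tolerance = 1e-12)
  expect_error(feedforward_input(cl, net6, 99), "range")
})

test_that("update rule is strict with ties mapping to 0", {
  net <- hopfield_network(matrix(0, 3, 3), rep(0, 3))
  up <- update_neuron(c(1L, 1L, 1L), net, 2)   # I = 0, theta = 0: tie
  expect_identical(up$state[2], 0L)
  expect_true(up$changed)

  # clique edge with 4 active neighbors in (2/7, 0, 1): 8/7 > 1, stays 1
  p <- symmetric_params(x = 2 / 7, y = 0, z = 1, v = 6)
  net6 <- build_network(p)
  cl <- clique_state(1:4, 6)
  up2 <- update_neuron(cl, net6, edge_index(1, 2, 6))
  expect_identical(up2$state, cl)
  expect_false(up2$changed)
})

test_that("single updates obey the energy identity and never increase energy", {
  set.seed(202)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    net <- random_net(n)
    x <- rbinom(n, 1, 0.5)
    e <- sample(n, 1)
    I <- feedforward_input(x, net, e)
    up <- update_neuron(x, net, e)
    dx <- up$state[e] - x[e]
    dE <- energy(up$state, net) - energy(x, net)
    expect_equal(dE, -dx * (I - net$theta[e]), tolerance = 1e-10)
    expect_lte(dE, 1e-12)
  }
})

test_that("sweep equals step-by-step application, for every order", {
  set.seed(303)
  for (i in 1:10) {
    net <- random_net(3)
    ord <- sample(3)
    for (bits in 0:7) {
      x <- as.integer(intToBits(bits))[1:3]
      expect_identical(run_sweep(x, net, ord),
                       naive_sweep(x, net$W, net$theta, ord))
    }
  }
  expect_error(run_sweep(c(1L, 0L, 1L), random_net(3), c(1, 1, 3)),
               "permutation")
})

test_that("a fixed point is idle under every sweep order", {
  p <- symmetric_params(x = 2 / 7, y = 0, z = 1, v = 6)
  net <- build_network(p)
  cl <- clique_state(2:5, 6)
  set.seed(7)
  for (i in 1:5) expect_identical(run_sweep(cl, net, sample(net$n)), cl)
  res <- converge(cl, net)
  expect_identical(res$fixed_point, cl)
  expect_identical(res$sweeps, 1L)     # one idle confirming pass
})

test_that("converge terminates on a verified fixed point with non-increasing energy", {
  set.seed(404)
  for (i in 1:15) {
    n <- 12
    net <- random_net(n)
    x <- rbinom(n, 1, 0.5)
    res <- converge(x, net)       # max_sweeps = n: must not error
    expect_true(res$converged)
    expect_true(all(diff(res$energy_trace) <= 1e-12))
    # exhaustive single-bit check of fixed-point property
    for (e in seq_len(n)) {
      expect_false(update_neuron(res$fixed_point, net, e)$changed)
    }
  }
})

test_that("dynamics is deterministic given state, net, order policy and seed", {
  set.seed(17)
  net <- random_net(10)
  x <- rbinom(10, 1, 0.5)
  r1 <- withr::with_seed(99, converge(x, net, order_policy = "random"))
  r2 <- withr::with_seed(99, converge(x, net, order_policy = "random"))
  expect_identical(r1$fixed_point, r2$fixed_point)
  expect_identical(r1$sweeps, r2$sweeps)
})

test_that("exhaustive scan: sweep-invariant states are exactly the fixed points", {
  set.seed(505)
  n <- 10
  net <- random_net(n)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  invariant <- logical(nrow(grid))
  for (s in seq_len(nrow(grid))) {
    x <- as.integer(grid[s, ])
    invariant[s] <- identical(run_sweep(x, net), x)
  }
  expect_identical(invariant, as.logical(is_fixed_point(t(grid), net)))
  expect_gte(sum(invariant), 1)  # symmetric nets always have an attractor
})

test_that("p_corrupt is a seeded binary symmetric channel", {
  x <- clique_state(1:4, 8)
  expect_identical(p_corrupt(x, 0), x)
  expect_identical(p_corrupt(x, 0.3, seed = 5), p_corrupt(x, 0.3, seed = 5))
  expect_error(p_corrupt(x, 0.6), "1/2")
  expect_error(p_corrupt(x, -0.1), "1/2")

  # mean flip count ~ p * n
  set.seed(606)
  n <- 500
  y <- rbinom(n, 1, 0.5)
  flips <- replicate(200, sum(p_corrupt(y, 0.15) != y))
  se <- sqrt(n * 0.15 * 0.85 / 200)
  expect_lt(abs(mean(flips) - 0.15 * n), 3 * se)

  # p = 1/2 destroys the input: bit frequencies near 1/2
  freqs <- rowMeans(replicate(400, p_corrupt(rep(1L, 50), 0.5)))
  expect_true(all(abs(freqs - 0.5) < 0.1))
})

test_that("network and state text serialization round-trips", {
  set.seed(707)
  net <- random_net(6)
  f <- withr::local_tempfile()
  write_network(net, f)
  net2 <- read_network(f)
  expect_equal(net2$W, net$W, tolerance = 1e-15)
  expect_equal(net2$theta, net$theta, tolerance = 1e-15)

  x <- rbinom(9, 1, 0.5)
  f2 <- withr::local_tempfile()
  write_state(x, f2)
  expect_identical(read_state(f2), as.integer(x))
  expect_identical(nchar(readLines(f2)[1]), 9L)  # one line, no separators
})

test_that("hopfield_network validates its invariants", {
  expect_error(hopfield_network(matrix(1:9, 3, 3), rep(0, 3)))
  W <- matrix(0, 3, 3); diag(W) <- 1
  expect_error(hopfield_network(W, rep(0, 3)), "diagonal")
  expect_error(hopfield_network(matrix(0, 3, 3), rep(0, 2)), "length")
})
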