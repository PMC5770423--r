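# The (x, y, z) family: construction, closed-form flow and its
# minimizer, large-deviation setting, stability certificates,
# enumeration oracle and clique-range feasibility.

test_that("build_network places x/y by overlap class", {
  z0 <- build_network(symmetric_params(x = 0, y = 0, z = 1, v = 5))
  expect_true(all(z0$W == 0))

  net <- build_network(symmetric_params(x = 0.3, y = -0.1, z = 2, v = 4))
  e12 <- edge_index(1, 2, 4); e13 <- edge_index(1, 3, 4)
  e34 <- edge_index(3, 4, 4)
  expect_identical(net$W[e12, e13], 0.3)
  expect_identical(net$W[e12, e34], -0.1)
  expect_identical(net$theta, rep(2, 6))
})

test_that("the symmetric W is invariant under vertex relabeling", {
  set.seed(131)
  v <- 7
  net <- build_network(symmetric_params(x = 0.4, y = 0.2, z = 1, v = v))
  perm <- sample(v)
  ends <- edge_endpoints(v)
  pe <- edge_index(pmin(perm[ends[1, ]], perm[ends[2, ]]),
                   pmax(perm[ends[1, ]], perm[ends[2, ]]), v)
  expect_equal(net$W[pe, pe], net$W, tolerance = 1e-15)
})

test_that("symmetric energy via graph stats matches the dense path", {
  pr <- symmetric_params(x = 2 / 7, y = 0, z = 1, v = 6)
  expect_identical(energy(integer(15), pr), 0)
  expect_equal(energy(clique_state(1:4, 6), pr), 18 / 7, tolerance = 1e-12)
  set.seed(132)
  net <- build_network(symmetric_params(x = 0.21, y = -0.05, z = 0.8,
                                        v = 10))
  pr10 <- symmetric_params(x = 0.21, y = -0.05, z = 0.8, v = 10)
  for (i in 1:100) {
    st <- rbinom(45, 1, 0.35)
    expect_equal(energy(st, pr10), energy(st, net), tolerance = 1e-9)
  }
})

test_that("restricted clique flow: boundary values and full-flow equality", {
  k <- 4
  expect_equal(restricted_clique_flow(k, 0, 0),
               choose(k, 2) + k * (k - 2) + choose(k - 2, 2))  # = n on v=6
  expect_error(restricted_clique_flow(3, 0.1), ">= 4")
  X <- all_cliques(6, 4)
  set.seed(133)
  for (x in runif(20, 0.05, 0.5)) {
    net <- build_network(symmetric_params(x = x, y = 0, z = 1, v = 6))
    expect_equal(probability_flow(X, net), restricted_clique_flow(4, x, 1),
                 tolerance = 1e-9)
  }
})

test_that("the closed-form minimizer matches 1-D numeric minimization", {
  for (k in c(4, 6, 10, 24, 64)) {
    for (z in c(0.5, 1, 2)) {
      expect_lt(abs(mpf_optimal_x(k, z) - numeric_flow_argmin(k, z)), 1e-8)
    }
  }
  expect_equal(mpf_optimal_x(10, 2), 2 * mpf_optimal_x(10, 1),
               tolerance = 1e-15)  # homogeneity in z
  expect_error(mpf_optimal_x(3), ">= 4")
})

test_that("large-deviation setting: printed forms agree and sit inside the window", {
  for (k in c(8, 16, 64, 200)) {
    for (p in c(0, 0.1, 0.25, 0.4, 0.49)) {
      mid <- 0.5 * (1 / (2 * k) + 1 / (k * (1 + 2 * p)))
      expect_equal(large_deviation_x(k, p), (3 + 2 * p) / (4 * k * (1 + 2 * p)),
                   tolerance = 1e-15)
      expect_equal(large_deviation_x(k, p), mid, tolerance = 1e-12)
      expect_gt(large_deviation_x(k, p), 1 / (2 * k))
      expect_lt(large_deviation_x(k, p), 1 / (k * (1 + 2 * p)))
    }
  }
  expect_equal(large_deviation_x(16, 0), 3 / (4 * 16), tolerance = 1e-15)
  expect_error(large_deviation_x(16, 0.5), "1/2")
})

test_that("stability certificate reduces to 1/4 < x < 1/3 at k = 4, r = 0", {
  mk <- function(x) symmetric_params(x = x, y = 0, z = 1, v = 6)
  expect_true(stability_certificate(4, 0, mk(2 / 7))$satisfied)
  expect_false(stability_certificate(4, 0, mk(0.24))$satisfied)
  expect_false(stability_certificate(4, 0, mk(0.34))$satisfied)
  # strictness at the boundary
  expect_false(stability_certificate(4, 0, mk(1 / 4))$satisfied)
  expect_error(stability_certificate(4, 5, mk(0.3)), "r")
})

test_that("certificates are invariant under positive rescaling", {
  set.seed(134)
  for (i in 1:20) {
    k <- sample(4:12, 1)
    r <- sample(0:2, 1)
    x <- runif(1, 0, 0.5); y <- runif(1, -0.1, 0.1); z <- runif(1, 0.5, 2)
    c1 <- stability_certificate(k, r, symmetric_params(x, y, z, v = 2 * k))
    cc <- runif(1, 0.1, 10)
    c2 <- stability_certificate(k, r, symmetric_params(cc * x, cc * y,
                                                       cc * z, v = 2 * k))
    expect_identical(c1$satisfied, c2$satisfied)
  }
})

test_that("feasible_x_interval exposes both candidate formulas", {
  iv <- feasible_x_interval(5, 2)
  expect_equal(unname(iv$printed_interval), c(1 / 6, 1 / 6),
               tolerance = 1e-15)
  expect_false(iv$printed_nonempty)   # k > 2r + 1 fails at equality

  iv9 <- feasible_x_interval(9, 1)
  expect_true(iv9$matrix_nonempty && iv9$printed_nonempty)
  x7 <- mpf_optimal_x(9)              # 2/22
  expect_gt(x7, iv9$matrix_interval[["lo"]])   # inside (1/13, 1/9)
  expect_lt(x7, iv9$matrix_interval[["hi"]])
})

test_that("exhaustive oracle: r = 0 is the fixed-point check, with witnesses", {
  pr <- symmetric_params(x = 2 / 7, y = 0, z = 1, v = 6)
  res <- exhaustive_r_stability(4, 6, 0, pr)
  expect_true(res$stable)
  expect_identical(res$checked, 15)
  bad <- exhaustive_r_stability(4, 6, 0,
                                symmetric_params(x = 0.35, y = 0, z = 1,
                                                 v = 6))
  expect_false(bad$stable)
  expect_false(is.null(bad$counterexample))
  # x above the r = 1 upper bound z/(k-1+r): a witness exists
  bad1 <- exhaustive_r_stability(4, 6, 1,
                                 symmetric_params(x = 0.26, y = 0, z = 1,
                                                  v = 6))
  expect_false(bad1$stable)
  expect_error(exhaustive_r_stability(4, 6, 1, pr, sample_cap = 10), "cap")
})

test_that("sparse symmetric dynamics equals the dense path (v <= 16)", {
  set.seed(135)
  for (i in 1:10) {
    v <- sample(c(8, 12, 16), 1)
    ks <- 4:(v / 2)
    k <- ks[sample.int(length(ks), 1)]
    pr <- symmetric_params(x = runif(1, 0.05, 0.4), y = runif(1, -0.02, 0.02),
                           z = 1, v = v)
    net <- build_network(pr)
    st <- p_corrupt(random_cliques(v, k, 1)[, 1], 0.15)
    a <- converge(st, net)
    b <- converge(st, pr)
    expect_identical(a$fixed_point, b$fixed_point)
    expect_equal(a$energy_trace[length(a$energy_trace)],
                 b$energy_trace[length(b$energy_trace)], tolerance = 1e-9)
  }
})

test_that("range feasibility: printed formulas, trivial cases, grid cross-check", {
  expect_true(range_bounds(5, 15)$feasible)      # stores 5 <= k <= 15
  expect_true(range_bounds(5, 5)$feasible)       # single size
  expect_true(range_feasible_grid(5, 15))
  expect_false(range_feasible_grid(5, 200))      # far beyond the ratio D
  expect_false(range_bounds(5, 200)$feasible)
  # threshold ratio approaches D ~ 13.93 for large m
  expect_true(range_bounds(1000, 13900)$feasible)
  expect_false(range_bounds(1000, 13950)$feasible)
  expect_lt(abs(13900 / 1000 - range_constants()$D) / range_constants()$D,
            0.005)
})

test_that("range constants have their exact closed forms", {
  con <- range_constants()
  expect_equal(con$D * (2 - sqrt(3)) - (2 + sqrt(3)), 0, tolerance = 1e-12)
  expect_identical(round(con$D, 2), 13.93)
  expect_identical(round(con$C, 2), 0.43)
})

test_that("storable fraction: bounds, monotonicity and Mill's-ratio ordering", {
  sf <- storable_fraction(20)
  expect_gt(sf$normal, 0); expect_lt(sf$normal, 1)
  con <- range_constants()
  t <- (con$D - 1) / con$D * sqrt(20)
  # upper tail below the Mill's ratio bound phi(t)/t
  expect_lte(1 - sf$normal, dnorm(t) / t)
  grid <- storable_fraction(seq(5, 400, by = 5))
  expect_true(all(diff(grid$normal) >= 0))
  expect_true(all(diff(grid$approx) >= 0))
  expect_equal(storable_fraction(1e4)$normal, 1, tolerance = 1e-9)
})
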