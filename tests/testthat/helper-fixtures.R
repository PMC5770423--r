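# Shared fixtures and independent reference (oracle) implementations.
# Oracles deliberately use naive formulations (full quadratic forms,
# explicit double-energy subtraction, step-by-step update loops) so they
# stay independent of the package's optimized code paths.

# all k-cliques on v vertices, one state per column
all_cliques <- function(v, k) {
  sets <- combn(v, k)
  vapply(seq_len(ncol(sets)), function(i) clique_state(sets[, i], v),
         integer(v * (v - 1) / 2))
}

# direct quadratic-form energy
naive_energy <- function(state, W, theta) {
  x <- as.numeric(state)
  drop(-0.5 * t(x) %*% W %*% x + sum(theta * x))
}

# probability flow by explicit two-energy subtraction per neighbor
naive_flow <- function(X, W, theta) {
  X <- as.matrix(X)
  n <- nrow(X)
  total <- 0
  for (c in seq_len(ncol(X))) {
    x <- X[, c]
    E0 <- naive_energy(x, W, theta)
    for (e in seq_len(n)) {
      xe <- x
      xe[e] <- 1L - xe[e]
      total <- total + exp((E0 - naive_energy(xe, W, theta)) / 2)
    }
  }
  total / ncol(X)
}

# step-by-step asynchronous sweep (reference for run_sweep)
naive_sweep <- function(state, W, theta, order) {
  x <- as.integer(state)
  for (e in order) {
    x[e] <- as.integer(sum(W[e, ] * x) > theta[e])
  }
  x
}

# random symmetric zero-diagonal Hopfield network
random_net <- function(n, scale = 0.5) {
  W <- matrix(rnorm(n * n, sd = scale), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  hopfield_network(W, rnorm(n, sd = scale))
}

# derangement with all cycles of length 2 (even k): no degenerate
# critical pairs, so the nominal count k(k-2) is attained
perfect_matching <- function(k) {
  stopifnot(k %% 2 == 0)
  sigma <- integer(k)
  sigma[seq(1, k, by = 2)] <- seq(2, k, by = 2)
  sigma[seq(2, k, by = 2)] <- seq(1, k, by = 2)
  sigma
}

# independent cycle counter (fixed points count as 1-cycles)
naive_cycle_count <- function(sigma) {
  seen <- logical(length(sigma))
  nc <- 0L
  for (s in seq_along(sigma)) {
    if (seen[s]) next
    nc <- nc + 1L
    i <- s
    while (!seen[i]) {
      seen[i] <- TRUE
      i <- sigma[i]
    }
  }
  nc
}

# independent 1-D minimizer of the restricted flow: root of the central
# finite-difference derivative (bracketed; accuracy ~1e-12, well inside
# the 1e-8 comparison tolerance, unlike golden-section optimize())
numeric_flow_argmin <- function(k, z, h = 1e-6) {
  d <- function(x)
    (restricted_clique_flow(k, x + h, z) -
       restricted_clique_flow(k, x - h, z)) / (2 * h)
  uniroot(d, interval = c(1e-6, z), tol = 1e-12)$root
}
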