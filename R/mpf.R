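# Minimum probability flow (MPF) estimation for fully observable binary
# maximum-entropy (Lenz-Ising / Boltzmann) models, specialized to the
# Hopfield parameterization (symmetric W, zero diagonal, thresholds).
#
# The flow of a pattern set X is
#   (1/|X|) sum_{x in X} sum_e exp((E_x - E_{x^e}) / 2),
# where x^e flips bit e. Since E_x - E_{x^e} = (1 - 2 x_e)(I_e - theta_e)
# each term needs only the feedforward input, never two full energies;
# the naive two-energy route is kept in the tests as a cross-check.

flow_kernel <- function(X, W, theta) {
  I <- W %*% X                             # n x m feedforward inputs
  D <- (1 - 2 * X) * (I - theta)           # E_x - E_{x flipped at e}
  exp(D / 2)
}

#' Probability flow of a pattern set
#'
#' The convex MPF objective: a sum of exponentials of half the energy
#' differences to all single-bit-flip neighbors, averaged over patterns.
#' It can be driven arbitrarily close to zero iff every pattern is a
#' strict local energy minimum (an attractor), which is what makes
#' minimizing it a storage principle.
#'
#' @param X a 0/1 matrix with patterns as columns, or a list of patterns.
#' @param net a [hopfield_network()].
#' @param per_pattern also return the per-pattern breakdown.
#' @return the scalar flow, with attribute `per_pattern` when requested.
#' @examples
#' net <- hopfield_network(matrix(0, 6, 6), rep(0, 6))
#' probability_flow(clique_state(1:3, 4), net)  # zero net: exactly n = 6
#' @export
probability_flow <- function(X, net, per_pattern = FALSE) {
  stopifnot(inherits(net, "hopfield_network"))
  X <- as_state_matrix(X, net$n)
  K <- flow_kernel(X, net$W, net$theta)
  value <- sum(K) / ncol(X)
  if (per_pattern) attr(value, "per_pattern") <- colSums(K)
  value
}

#' Gradient of the probability flow
#'
#' Analytic partial derivatives with respect to the symmetric
#' off-diagonal weights and the thresholds. The weight gradient is
#' returned as a full symmetric zero-diagonal matrix in which entry
#' `(e, f)` is the derivative with respect to the single shared
#' parameter \eqn{W_{ef} = W_{fe}}.
#'
#' @inheritParams probability_flow
#' @return a list with `dW` (n-by-n symmetric, zero diagonal) and
#'   `dtheta` (length n).
#' @export
probability_flow_gradient <- function(X, net) {
  stopifnot(inherits(net, "hopfield_network"))
  X <- as_state_matrix(X, net$n)
  m <- ncol(X)
  K <- flow_kernel(X, net$W, net$theta)
  A <- K * (1 - 2 * X)
  dW <- (A %*% t(X) + X %*% t(A)) / (2 * m)
  diag(dW) <- 0
  dtheta <- -rowSums(A) / (2 * m)
  list(dW = dW, dtheta = dtheta)
}

pack_params <- function(W, theta) c(W[upper.tri(W)], theta)

unpack_params <- function(par, n) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- par[seq_len(n * (n - 1) / 2)]
  W <- W + t(W)
  list(W = W, theta = par[n * (n - 1) / 2 + seq_len(n)])
}

#' Fit a Hopfield network by minimizing probability flow
#'
#' Quasi-Newton (L-BFGS-B) descent of the convex flow over the free
#' parameters: the \eqn{n(n-1)/2} upper-triangle weights plus the
#' \eqn{n} thresholds (symmetry is enforced by the parameterization, so
#' no penalty is needed). With the default zero initialization the
#' starting objective equals `n` exactly -- a built-in self-check.
#'
#' @inheritParams probability_flow
#' @param init optional [hopfield_network()] supplying starting values;
#'   overrides `init_type`.
#' @param init_type `"zeros"` (default) or `"gauss"` (N(0, 0.01) entries,
#'   seeded by `seed`).
#' @param seed seed for the Gaussian initialization.
#' @param max_iter iteration cap for the optimizer.
#' @param grad_tol projected-gradient tolerance passed to L-BFGS-B.
#' @return an object of class `mpf_fit`: list with `network`,
#'   `final_flow`, `initial_flow`, `iterations`, `converged`, `message`.
#' @examples
#' X <- random_cliques(6, 3, 5, seed = 1)
#' fit <- fit_mpf(X)
#' all(is_fixed_point(X, fit$network))
#' @export
fit_mpf <- function(X, init = NULL, init_type = c("zeros", "gauss"),
                    seed = NULL, max_iter = 500, grad_tol = 1e-6) {
  X <- as_state_matrix(X)
  n <- nrow(X)
  init_type <- match.arg(init_type)
  if (!is.null(init)) {
    stopifnot(inherits(init, "hopfield_network"), init$n == n)
    par0 <- pack_params(init$W, init$theta)
  } else if (init_type == "gauss") {
    par0 <- seeded(seed, function() 0.1 * rnorm(n * (n - 1) / 2 + n))
  } else {
    par0 <- numeric(n * (n - 1) / 2 + n)
  }
  fn <- function(par) {
    p <- unpack_params(par, n)
    sum(flow_kernel(X, p$W, p$theta)) / ncol(X)
  }
  gr <- function(par) {
    p <- unpack_params(par, n)
    K <- flow_kernel(X, p$W, p$theta)
    A <- K * (1 - 2 * X)
    dW <- (A %*% t(X) + X %*% t(A)) / (2 * ncol(X))
    c(dW[upper.tri(dW)], -rowSums(A) / (2 * ncol(X)))
  }
  initial <- fn(par0)
  opt <- optim(par0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = as.integer(max_iter),
                              pgtol = grad_tol, factr = 0))
  p <- unpack_params(opt$par, n)
  net <- hopfield_network(p$W, p$theta)
  structure(list(network = net, final_flow = opt$value,
                 initial_flow = initial,
                 iterations = opt$counts[["function"]],
                 converged = opt$convergence == 0,
                 message = if (is.null(opt$message)) "" else opt$message),
            class = "mpf_fit")
}

#' @export
print.mpf_fit <- function(x, ...) {
  cat(sprintf("MPF fit: flow %.6g -> %.6g in %d evaluations (%s)\n",
              x$initial_flow, x$final_flow, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Local MPF learning rule
#'
#' One steepest-descent step of the flow of a single pattern, in the
#' local synaptic form
#' \eqn{\Delta W_{ef} \propto -x_f\, \Delta x_e\, e^{-\Delta E_e/2}},
#' \eqn{\Delta\theta_e \propto \Delta x_e\, e^{-\Delta E_e/2}}, where
#' \eqn{\Delta x_e} is the bit change the threshold dynamics would make
#' at `e` under the *current* network and
#' \eqn{\Delta E_e = -\Delta x_e (I_e - \theta_e)} the resulting energy
#' change. After the update the weights are symmetrized to
#' \eqn{\tfrac12(W_{ef} + W_{fe})} (energy-preserving) and the diagonal
#' forced to zero. A memorized pattern (\eqn{\Delta x = 0}) leaves the
#' network unchanged; when an update fires with both neurons active the
#' increment is Hebbian-positive.
#'
#' @param x a single 0/1 pattern of length `net$n`.
#' @param net a [hopfield_network()].
#' @param rate positive learning rate (the proportionality constant).
#' @return the updated `hopfield_network`.
#' @export
mpf_learning_step <- function(x, net, rate = 0.01) {
  stopifnot(inherits(net, "hopfield_network"))
  x <- check_state(x, net$n)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be positive")
  I <- drop(net$W %*% x)
  new_bits <- as.integer(I > net$theta)
  dx <- new_bits - x
  dE <- -dx * (I - net$theta)
  g <- dx * exp(-dE / 2)
  dW <- -outer(g, as.numeric(x))         # dW[e, f] = -x_f * dx_e * exp(.)
  W <- net$W + rate * dW
  W <- (W + t(W)) / 2
  diag(W) <- 0
  hopfield_network(W, net$theta + rate * g)
}
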