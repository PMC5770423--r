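#' Energy of a state
#'
#' \eqn{E_x = -\tfrac12 x^\top W x + \theta^\top x}. Attractors of the
#' asynchronous dynamics are exactly the strict local minima of the
#' energy under single-bit flips.
#'
#' @param state a 0/1 vector of length `net$n`.
#' @param net a [hopfield_network()] or [symmetric_params()].
#' @param ... passed to methods.
#' @return a scalar energy.
#' @export
energy <- function(state, net, ...) UseMethod("energy", net)

#' @export
energy.hopfield_network <- function(state, net, ...) {
  x <- check_state(state, net$n)
  drop(-0.5 * crossprod(x, net$W %*% x) + sum(net$theta * x))
}

#' Feedforward input to a neuron
#'
#' \eqn{I_e = \langle W_e, x \rangle}; because the diagonal of `W` is
#' zero this equals \eqn{\sum_{f \ne e} W_{ef} x_f}.
#'
#' @inheritParams energy
#' @param e neuron index in `1..n`.
#' @return a scalar input.
#' @export
feedforward_input <- function(state, net, e) {
  stopifnot(inherits(net, "hopfield_network"))
  x <- check_state(state, net$n)
  if (!is_count(e) || e > net$n) stop("`e` out of range")
  sum(net$W[e, ] * x)
}

#' Single-neuron update
#'
#' Applies the threshold rule at neuron `e`: the bit becomes 1 iff
#' \eqn{I_e > \theta_e} (strict; ties yield 0). The induced energy change
#' is \eqn{\Delta E_e = -\Delta x_e (I_e - \theta_e) \le 0}.
#'
#' @inheritParams feedforward_input
#' @return a list with `state` (updated vector) and `changed` (logical).
#' @export
update_neuron <- function(state, net, e) {
  stopifnot(inherits(net, "hopfield_network"))
  x <- check_state(state, net$n)
  if (!is_count(e) || e > net$n) stop("`e` out of range")
  new_bit <- as.integer(sum(net$W[e, ] * x) > net$theta[e])
  changed <- new_bit != x[e]
  x[e] <- new_bit
  list(state = x, changed = changed)
}

#' One asynchronous sweep through all neurons
#'
#' Updates every neuron once, in the given order, each update seeing the
#' effect of the previous ones.
#'
#' @inheritParams energy
#' @param order a permutation of `1..n` (default ascending).
#' @return the updated 0/1 integer vector.
#' @export
run_sweep <- function(state, net, order = seq_len(net$n)) {
  stopifnot(inherits(net, "hopfield_network"))
  x <- check_state(state, net$n)
  order <- as.integer(order)
  if (length(order) != net$n || anyNA(order) ||
      !identical(sort(order), seq_len(net$n)))
    stop("`order` must be a permutation of 1..n")
  cpp_sweep_dense(net$W, net$theta, x, order - 1L)
}

new_dynamics_result <- function(res, max_sweeps) {
  if (!res$converged)
    stop(sprintf(paste0("dynamics did not converge within %d sweeps; ",
                        "this should be unreachable for a symmetric ",
                        "zero-diagonal network"), max_sweeps))
  structure(list(fixed_point = res$state, sweeps = res$sweeps,
                 energy_trace = res$energy_trace,
                 converged = res$converged),
            class = "dynamics_result")
}

#' @export
print.dynamics_result <- function(x, ...) {
  cat(sprintf("dynamics_result: converged in %d sweep(s), final energy %.6g\n",
              x$sweeps, x$energy_trace[length(x$energy_trace)]))
  invisible(x)
}

#' Run the dynamics to its fixed point
#'
#' Sweeps repeatedly until one full pass changes no bit. The sweep count
#' includes the final idle pass, so a fixed-point input reports 1 sweep.
#' Energy descent (\eqn{\Delta E_e \le 0} per update) makes
#' non-convergence impossible for a valid network; exhausting
#' `max_sweeps` therefore raises an error rather than returning.
#'
#' @inheritParams energy
#' @param order_policy `"fixed"` visits neurons in ascending index every
#'   sweep; `"random"` draws a fresh uniformly random permutation per
#'   sweep from the current RNG stream (seed with [set.seed()]).
#' @param max_sweeps sweep budget; defaults to `n`.
#' @return an object of class `dynamics_result`: list with `fixed_point`,
#'   `sweeps`, `energy_trace` (energy after each sweep; non-increasing)
#'   and `converged`.
#' @examples
#' p <- symmetric_params(x = mpf_optimal_x(4), z = 1, v = 8)
#' net <- build_network(p)
#' cl <- clique_state(1:4, v = 8)
#' res <- converge(p_corrupt(cl, 0.1, seed = 7), net)
#' identical(res$fixed_point, cl)
#' @export
converge <- function(state, net, order_policy = c("fixed", "random"),
                     max_sweeps = NULL, ...) UseMethod("converge", net)

#' @rdname converge
#' @export
converge.hopfield_network <- function(state, net,
                                      order_policy = c("fixed", "random"),
                                      max_sweeps = NULL, ...) {
  x <- check_state(state, net$n)
  order_policy <- match.arg(order_policy)
  if (is.null(max_sweeps)) max_sweeps <- net$n
  if (!is_count(max_sweeps)) stop("`max_sweeps` must be a positive integer")
  res <- cpp_converge_dense(net$W, net$theta, x,
                            order_policy == "random",
                            as.integer(max_sweeps), TRUE)
  new_dynamics_result(res, max_sweeps)
}

#' @rdname converge
#' @export
converge.symmetric_params <- function(state, net,
                                      order_policy = c("fixed", "random"),
                                      max_sweeps = NULL, ...) {
  n <- net$v * (net$v - 1) / 2
  x <- check_state(state, n)
  order_policy <- match.arg(order_policy)
  if (is.null(max_sweeps)) max_sweeps <- n
  if (!is_count(max_sweeps)) stop("`max_sweeps` must be a positive integer")
  ends <- edge_endpoints(net$v)
  res <- cpp_converge_sym(net$v, net$x, net$y, net$z,
                          ends[1L, ] - 1L, ends[2L, ] - 1L, x,
                          order_policy == "random",
                          as.integer(max_sweeps), TRUE)
  new_dynamics_result(res, max_sweeps)
}

#' Test whether states are fixed points
#'
#' A state is a fixed point (memory) iff a single sweep changes no bit.
#'
#' @param X a 0/1 matrix with states as columns, or a list of states.
#' @param net a [hopfield_network()].
#' @return a logical vector, one entry per state.
#' @export
is_fixed_point <- function(X, net) {
  stopifnot(inherits(net, "hopfield_network"))
  X <- as_state_matrix(X, net$n)
  cpp_fixed_point_dense(net$W, net$theta, X)
}
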