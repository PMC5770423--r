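# The permutation-symmetric three-parameter network family on the edges
# of the complete graph K_v: weight x between edges sharing one vertex,
# y between disjoint edges, uniform threshold z. Averaging any
# clique-storing network over vertex relabelings lands in this family,
# so storage questions reduce to linear inequalities in (x, y, z).

#' Symmetric three-parameter network family
#'
#' @param x weight between edges sharing exactly one vertex.
#' @param y weight between vertex-disjoint edges (0 gives the sparse
#'   family: a vanishing fraction of connections at large `v`).
#' @param z uniform threshold; all storage results live in the `z > 0`
#'   component of the feasibility cone.
#' @param v vertex count (at least 4, so both overlap classes exist).
#' @param k optional target clique size carried along for bookkeeping.
#' @return an object of class `symmetric_params`.
#' @examples
#' symmetric_params(x = mpf_optimal_x(8), z = 1, v = 16, k = 8)
#' @export
symmetric_params <- function(x, y = 0, z = 1, v, k = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(z),
            length(x) == 1L, length(y) == 1L, length(z) == 1L)
  if (!is_count(v, 4)) stop("`v` must be an integer >= 4")
  if (!is.null(k) && (!is_count(k, 2) || k > v))
    stop("`k` must satisfy 2 <= k <= v")
  structure(list(x = x, y = y, z = z, v = as.integer(v),
                 k = if (is.null(k)) NULL else as.integer(k)),
            class = "symmetric_params")
}

#' @export
print.symmetric_params <- function(x, ...) {
  cat(sprintf("symmetric (x, y, z) = (%.6g, %.6g, %.6g) on v = %d%s\n",
              x$x, x$y, x$z, x$v,
              if (is.null(x$k)) "" else sprintf(" (k = %d)", x$k)))
  invisible(x)
}

#' Convenience constructors for the two design settings
#'
#' `params_flow_optimal()` uses the closed-form probability-flow
#' minimizer [mpf_optimal_x()] (derived on `v = 2k - 2`, and used
#' unchanged on `v = 2k` in the robustness experiments);
#' `params_large_deviation()` uses the large-deviation setting
#' [large_deviation_x()] (derived on `v = 2k`).
#'
#' @param k clique size.
#' @param p design corruption level in `[0, 1/2)`.
#' @param z threshold.
#' @param v vertex count; defaults follow the derivation conventions.
#' @return a [symmetric_params()].
#' @export
params_flow_optimal <- function(k, z = 1, v = 2 * k - 2) {
  symmetric_params(x = mpf_optimal_x(k, z), y = 0, z = z, v = v, k = k)
}

#' @rdname params_flow_optimal
#' @export
params_large_deviation <- function(k, p, z = 1, v = 2 * k) {
  symmetric_params(x = large_deviation_x(k, p, z), y = 0, z = z, v = v,
                   k = k)
}

#' Materialize the dense network of a symmetric parameter triple
#'
#' `W[e, f]` is `x` when edges `e`, `f` share exactly one vertex, `y`
#' when they are disjoint, 0 on the diagonal; all thresholds equal `z`.
#' The result is invariant under vertex-relabeling conjugation
#' \eqn{W \mapsto P W P^\top}. For large `v` prefer the sparse dynamics
#' in [converge()] (method for `symmetric_params`), which never builds
#' this matrix.
#'
#' @param params a [symmetric_params()].
#' @return a [hopfield_network()] on `n = v(v-1)/2` neurons.
#' @export
build_network <- function(params) {
  stopifnot(inherits(params, "symmetric_params"))
  v <- params$v
  ends <- edge_endpoints(v)
  n <- ncol(ends)
  shared <- (outer(ends[1L, ], ends[1L, ], "==") +
             outer(ends[1L, ], ends[2L, ], "==") +
             outer(ends[2L, ], ends[1L, ], "==") +
             outer(ends[2L, ], ends[2L, ], "=="))
  W <- matrix(params$y, n, n)
  W[shared == 1L] <- params$x
  diag(W) <- 0
  hopfield_network(W, rep(params$z, n))
}

#' Symmetric-family energy of a graph state
#'
#' \eqn{E_G(x, y, z) = -x\,S_1(G) - y\,S_0(G) + z\,\#E(G)}, evaluated
#' through [graph_stats()]; agrees with the dense quadratic energy of
#' [build_network()] to float tolerance.
#'
#' @param state a 0/1 vector of length `v(v-1)/2`.
#' @param net a [symmetric_params()].
#' @param ... unused.
#' @return a scalar energy.
#' @export
energy.symmetric_params <- function(state, net, ...) {
  gs <- graph_stats(state, net$v)
  -net$x * gs$s1 - net$y * gs$s0 + net$z * gs$edge_count
}

#' Closed-form restricted clique flow
#'
#' Per-clique probability flow of the training set of *all* `k`-cliques
#' on `v = 2k - 2` vertices under the sparse symmetric network
#' `(x, 0, z)`. The single-flip neighbors of a clique split into three
#' orbits -- delete an internal edge, add an edge from a clique vertex
#' to an outside vertex, add an edge between two outside vertices --
#' giving
#' \deqn{\binom{k}{2} e^{(z - 2(k-2)x)/2} + k(k-2)\, e^{((k-1)x - z)/2}
#'   + \binom{k-2}{2} e^{-z/2}.}
#' Enumerating the full flow over the clique set reproduces this value
#' exactly (asserted in the tests).
#'
#' @param k clique size, at least 4.
#' @param x shared-vertex weight.
#' @param z threshold.
#' @return the per-clique flow.
#' @export
restricted_clique_flow <- function(k, x, z = 1) {
  if (!is_count(k, 4)) stop("`k` must be an integer >= 4")
  choose(k, 2) * exp((z - 2 * (k - 2) * x) / 2) +
    k * (k - 2) * exp(((k - 1) * x - z) / 2) +
    choose(k - 2, 2) * exp(-z / 2)
}

#' Analytic minimizer of the restricted clique flow
#'
#' For fixed threshold `z > 0` the restricted flow is minimized uniquely
#' at \eqn{x = 2z/(3k - 5)} (set the derivative of the two `x`-dependent
#' orbit terms to zero; the exponents balance). Linear in `z` by the
#' homogeneity of the dynamics.
#'
#' @param k clique size, at least 4 (so `3k - 5 > 0` and the value lies
#'   inside the `r = 0` feasibility interval).
#' @param z threshold.
#' @return the optimal `x`.
#' @examples
#' round(mpf_optimal_x(64), 4)  # 0.0107
#' @export
mpf_optimal_x <- function(k, z = 1) {
  if (!is_count(k, 4)) stop("`k` must be an integer >= 4")
  if (!is.numeric(z) || z <= 0) stop("`z` must be positive")
  2 * z / (3 * k - 5)
}

#' Large-deviation robust weight setting
#'
#' Concentration of the corrupted neighbor counts pins the feasible `x`
#' between \eqn{z/(2k)} (clique edges must stay on) and
#' \eqn{z/(k(1+2p))} (edges leaving the clique must switch off), up to
#' \eqn{o(\sqrt k \ln k)} terms. The midpoint
#' \deqn{x = \frac12\Bigl[\frac{z}{2k} + \frac{z}{k(1+2p)}\Bigr]
#'   = \frac{z(3+2p)}{4k(1+2p)}}
#' satisfies both with probability approaching 1 for any fixed
#' `p < 1/2`, which is how the family attains the maximal robustness
#' index 1/2.
#'
#' @param k clique size.
#' @param p design corruption level, `0 <= p < 1/2`.
#' @param z threshold.
#' @return the robust `x`, always strictly inside
#'   `(z/(2k), z/(k(1+2p)))`.
#' @examples
#' round(large_deviation_x(64, 1/4), 4)  # 0.0091
#' @export
large_deviation_x <- function(k, p, z = 1) {
  if (!is_count(k, 2)) stop("`k` must be an integer >= 2")
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p >= 0.5)
    stop("`p` must lie in [0, 1/2)")
  z * (3 + 2 * p) / (4 * k * (1 + 2 * p))
}

stability_matrix <- function(k, r) {
  matrix(c(4 * (2 - k) + 2 * r, (2 - k) * (k - 3),
           4 * (2 - k),         (2 - k) * (k - 3) - 2 * r,
           2 * (k - 1) + 2 * r, (k - 1) * (k - 2),
           2 * (k - 1),         (k - 1) * (k - 2) - 2 * r),
         nrow = 4, byrow = TRUE)
}

#' Exact r-stability certificate
#'
#' A state is `r`-stable when the dynamics returns it from every state
#' within Hamming distance `r`. The symmetric network stores all
#' `k`-cliques as `r`-stable states iff the four strict linear
#' inequalities \eqn{M (x, y)^\top < (-2, -2, 2, 2)^\top z} hold, where
#' `M` collects the two extreme perturbations (`r` internal edges
#' removed at one vertex; `r` spurious edges attached to one outside
#' vertex); every other perturbation is a convex combination. When the
#' certificate holds, recovery takes a single sweep. Satisfaction is
#' invariant under \eqn{(x,y,z) \mapsto (cx, cy, cz)}, `c > 0`.
#'
#' The certificate is validated against exhaustive enumeration
#' ([exhaustive_r_stability()]) in the test-suite; enumeration is the
#' ground truth wherever printed formulas disagree (see
#' [feasible_x_interval()]).
#'
#' @param k clique size, `k > 3`.
#' @param r stability radius, `0 <= r < k`.
#' @param params a [symmetric_params()].
#' @param marginal_tol slacks below this are flagged marginal rather
#'   than decided.
#' @return an object of class `stability_certificate`: list with `k`,
#'   `r`, `M`, `slack` (rhs minus lhs, positive when satisfied),
#'   `satisfied`, `marginal`.
#' @export
stability_certificate <- function(k, r, params, marginal_tol = 1e-12) {
  stopifnot(inherits(params, "symmetric_params"))
  if (!is_count(k, 4)) stop("`k` must be an integer > 3")
  if (!is_count(r, 0) || r >= k) stop("`r` must satisfy 0 <= r < k")
  M <- stability_matrix(k, r)
  lhs <- drop(M %*% c(params$x, params$y))
  rhs <- c(-2, -2, 2, 2) * params$z
  slack <- rhs - lhs
  structure(list(k = as.integer(k), r = as.integer(r), M = M,
                 slack = slack, satisfied = all(slack > 0),
                 marginal = any(abs(slack) < marginal_tol)),
            class = "stability_certificate")
}

#' @export
print.stability_certificate <- function(x, ...) {
  cat(sprintf("r-stability certificate (k = %d, r = %d): %s%s\n",
              x$k, x$r, if (x$satisfied) "SATISFIED" else "violated",
              if (x$marginal) " [marginal]" else ""))
  cat("  slacks:", paste(sprintf("%.4g", x$slack), collapse = ", "), "\n")
  invisible(x)
}

#' Candidate feasible x-intervals for sparse r-stable storage
#'
#' With `y = 0`, only the first and third certificate rows bind, giving
#' the interval \eqn{z/(2(k-2)-r) < x < z/(k-1+r)} (the
#' `"matrix"`-derived form). A companion displayed derivation states
#' \eqn{z/(2(k-1)-r) < x < z/(k-1+r)} instead -- the lower bounds differ
#' by a constant in `k`. Both are returned, labeled; the exhaustive
#' oracle in the test-suite records which one matches simulation (the
#' matrix form does).
#'
#' @param k clique size, `k > 3`.
#' @param r stability radius.
#' @param z threshold.
#' @return a list with numeric `matrix_interval` and `printed_interval`
#'   (each `c(lo, hi)`) and logical `matrix_nonempty`,
#'   `printed_nonempty`.
#' @export
feasible_x_interval <- function(k, r = 0, z = 1) {
  if (!is_count(k, 4)) stop("`k` must be an integer > 3")
  if (!is_count(r, 0)) stop("`r` must be a nonnegative integer")
  m_int <- c(lo = z / (2 * (k - 2) - r), hi = z / (k - 1 + r))
  p_int <- c(lo = z / (2 * (k - 1) - r), hi = z / (k - 1 + r))
  list(matrix_interval = m_int, printed_interval = p_int,
       matrix_nonempty = m_int[["lo"]] < m_int[["hi"]],
       printed_nonempty = p_int[["lo"]] < p_int[["hi"]])
}

states_within_hamming <- function(state, r) {
  n <- length(state)
  cols <- list(matrix(state, ncol = 1L))
  for (d in seq_len(r)) {
    idx <- combn(n, d)
    block <- matrix(state, n, ncol(idx))
    for (c in seq_len(ncol(idx))) {
      block[idx[, c], c] <- 1L - block[idx[, c], c]
    }
    cols[[d + 1L]] <- block
  }
  do.call(cbind, cols)
}

#' Exhaustive r-stability check by enumeration
#'
#' Ground-truth oracle: for every `k`-clique on `v` vertices and every
#' state within Hamming distance at most `r` of it, run the dynamics and
#' require the clique back. Refuses (with an error, never silent
#' sampling) when the enumeration exceeds `sample_cap` dynamics runs.
#'
#' @param k clique size.
#' @param v vertex count.
#' @param r stability radius.
#' @param params a [symmetric_params()].
#' @param sample_cap maximum number of dynamics runs.
#' @param max_sweeps sweep budget per run.
#' @return a list with `stable` (logical), `checked` (number of runs)
#'   and `counterexample` (`NULL`, or a list with the failing clique's
#'   vertices and the start state).
#' @export
exhaustive_r_stability <- function(k, v, r, params, sample_cap = 5e6,
                                   max_sweeps = NULL) {
  stopifnot(inherits(params, "symmetric_params"), params$v == v)
  n <- v * (v - 1) / 2
  n_cliques <- count_cliques(v, k)
  per <- sum(choose(n, 0:r))
  total <- n_cliques * per
  if (total > sample_cap)
    stop(sprintf(paste0("enumeration needs %.3g dynamics runs, above the ",
                        "cap of %.3g; raise `sample_cap` explicitly"),
                 total, sample_cap))
  if (is.null(max_sweeps)) max_sweeps <- n
  ends <- edge_endpoints(v)
  sets <- combn(v, k)
  for (c in seq_len(ncol(sets))) {
    cl <- clique_state(sets[, c], v)
    starts <- states_within_hamming(cl, r)
    res <- cpp_recover_sym_batch(v, params$x, params$y, params$z,
                                 ends[1L, ] - 1L, ends[2L, ] - 1L,
                                 starts,
                                 matrix(cl, n, ncol(starts)),
                                 FALSE, as.integer(max_sweeps))
    if (!all(res$recovered)) {
      bad <- which(!res$recovered)[1L]
      return(list(stable = FALSE, checked = (c - 1L) * per + bad,
                  counterexample = list(clique = sets[, c],
                                        state = starts[, bad])))
    }
  }
  list(stable = TRUE, checked = total, counterexample = NULL)
}

#' Feasibility of storing a range of clique sizes
#'
#' Whether one symmetric network (with `y` free, `z = 1/2`, `r = 0`) can
#' store all `k`-cliques for every `k` in `[m, M]`. The feasible region
#' is the intersection of the per-`k` certificate polyhedra; it is
#' nonempty iff \eqn{x_M < x_m} for
#' \deqn{x_m = \frac{-(4m - \sqrt{12m^2 - 52m + 57} - 7)}{2(m^2-m-2)},
#' \quad
#' x_M = \frac{-(4M + \sqrt{12M^2 - 52M + 57} - 7)}{2(M^2-M-2)},}
#' the abscissae where the binding constraint lines for sizes `m` and
#' `M` meet the envelope curve of the upper-bound family.
#'
#' @param m,M clique-size range, `3 <= m <= M`.
#' @return an object of class `range_feasibility`: list with `m`, `M`,
#'   `x_m`, `x_M`, `feasible`.
#' @examples
#' range_bounds(5, 15)$feasible  # TRUE
#' @export
range_bounds <- function(m, M) {
  if (!is_count(m, 3) || !is_count(M, 3) || M < m)
    stop("need 3 <= m <= M")
  disc_m <- 12 * m^2 - 52 * m + 57
  disc_M <- 12 * M^2 - 52 * M + 57
  stopifnot(disc_m >= 0, disc_M >= 0)  # holds for all m >= 3
  x_m <- -(4 * m - sqrt(disc_m) - 7) / (2 * (m^2 - m - 2))
  x_M <- -(4 * M + sqrt(disc_M) - 7) / (2 * (M^2 - M - 2))
  structure(list(m = as.integer(m), M = as.integer(M), x_m = x_m,
                 x_M = x_M, feasible = x_M - x_m < 0),
            class = "range_feasibility")
}

#' @export
print.range_feasibility <- function(x, ...) {
  cat(sprintf("clique range [%d, %d]: %s (x_M = %.5g %s x_m = %.5g)\n",
              x$m, x$M, if (x$feasible) "storable" else "not storable",
              x$x_M, if (x$feasible) "<" else ">=", x$x_m))
  invisible(x)
}

#' Grid cross-check of range feasibility
#'
#' Direct search for a point `(x, y)` (with `z = 1/2`, `r = 0`)
#' satisfying every certificate inequality for all `k` in `[m, M]`, on a
#' rectangular grid around the analytic polytope. Used to validate
#' [range_bounds()].
#'
#' @inheritParams range_bounds
#' @param grid_n grid resolution per axis.
#' @return `TRUE` if some grid point is feasible.
#' @export
range_feasible_grid <- function(m, M, grid_n = 201) {
  xs <- seq(-1, 2, length.out = grid_n) / (m - 1)
  ys <- seq(-2, 1, length.out = grid_n) / ((m - 1) * (m - 2))
  ks <- m:M
  pts <- expand.grid(x = xs, y = ys)
  ok <- rep(TRUE, nrow(pts))
  for (k in ks) {
    M4 <- stability_matrix(k, 0)
    lhs <- as.matrix(pts) %*% t(M4)
    rhs <- matrix(c(-2, -2, 2, 2) * 0.5, nrow(pts), 4, byrow = TRUE)
    ok <- ok & rowSums(lhs < rhs) == 4L
    if (!any(ok)) break
  }
  any(ok)
}

#' Asymptotic range-storage constants
#'
#' For large sizes the range `[m, M]` is storable iff `M/m` stays below
#' \eqn{D = (2+\sqrt3)/(2-\sqrt3) \approx 13.93}; choosing the range
#' optimally, the stored cliques are a fraction
#' \eqn{1 - e^{-Cv}} of all \eqn{2^v} cliques, with
#' \eqn{C = (D-1)^2/(2D^2) \approx 0.43}.
#'
#' @return a list with `C` and `D` (exact closed forms as doubles).
#' @export
range_constants <- function() {
  D <- (2 + sqrt(3)) / (2 - sqrt(3))
  list(C = (D - 1)^2 / (2 * D^2), D = D)
}

#' Storable fraction of cliques at vertex count v
#'
#' The fraction of all cliques whose size falls in the optimal storable
#' range: a Binomial(v, 1/2) size is storable when at most
#' \eqn{(D-1)/D \sqrt v} standard units above the mean, giving the
#' normal-approximation expression \eqn{\Phi((D-1)/D\,\sqrt v)}; the
#' upper tail is bounded via the Mill's ratio by roughly
#' \eqn{e^{-Cv}}.
#'
#' @param v vertex count(s).
#' @return a list with `normal` (the CDF expression), `approx`
#'   (`1 - exp(-Cv)`) and `gap` (`normal - approx`).
#' @export
storable_fraction <- function(v) {
  stopifnot(is.numeric(v), all(v >= 1))
  con <- range_constants()
  t <- (con$D - 1) / con$D * sqrt(v)
  normal <- pnorm(t)
  approx <- 1 - exp(-con$C * v)
  list(normal = normal, approx = approx, gap = normal - approx)
}
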