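# Seeded experiment drivers: error-correction (robustness) curves,
# training-set-size curves for MPF fitting, learned-parameter group
# statistics, hidden-clique recovery, neighbor-count concentration and
# the finite-scale robustness-index estimator. All drivers are
# deterministic functions of their configuration plus `seed`.

trial_table <- function(df, meta) {
  attr(df, "meta") <- meta
  class(df) <- c("trial_table", class(df))
  df
}

#' @export
print.trial_table <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("trial_table: %d rows (%s)\n", nrow(x),
              paste(sprintf("%s=%s", names(meta),
                            vapply(meta, function(v)
                              paste(format(v), collapse = ","),
                              character(1))),
                    collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Write a trial table as TSV with a JSON metadata sidecar
#'
#' @param tab a `trial_table`.
#' @param path TSV output path; metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- attr(tab, "meta")
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

recover_sym_batch <- function(params, starts, targets, random_order,
                              max_sweeps = NULL) {
  v <- params$v
  n <- v * (v - 1) / 2
  if (is.null(max_sweeps)) max_sweeps <- n
  ends <- edge_endpoints(v)
  cpp_recover_sym_batch(v, params$x, params$y, params$z,
                        ends[1L, ] - 1L, ends[2L, ] - 1L,
                        starts, targets, random_order,
                        as.integer(max_sweeps))
}

#' Error-correction (robustness) curve
#'
#' For each corruption level `p`: draw `n_patterns` random `k`-cliques,
#' corrupt each `trials` times, converge the dynamics and record exact
#' recovery plus the fraction of correct bits. Corruptions across `p`
#' values reuse common random numbers (one uniform draw per bit,
#' thresholded at each `p`), so the recovery fraction is monotone
#' non-increasing in `p` path-by-path.
#'
#' @param v,k vertex count and clique size.
#' @param params a [symmetric_params()] with `params$v == v`.
#' @param p_grid corruption levels in `[0, 1/2]`.
#' @param n_patterns cliques per level.
#' @param trials corruptions per clique.
#' @param seed integer seed.
#' @param order_policy sweep order: `"random"` (a fresh permutation per
#'   sweep; the default for experiments) or `"fixed"`.
#' @return a `trial_table` with one row per `(p, pattern, trial)`:
#'   columns `p`, `pattern`, `trial`, `recovered`, `bit_acc`.
#' @export
robustness_curve <- function(v, k, params, p_grid, n_patterns = 100,
                             trials = 1, seed = 1,
                             order_policy = c("random", "fixed")) {
  stopifnot(inherits(params, "symmetric_params"), params$v == v)
  order_policy <- match.arg(order_policy)
  stopifnot(all(p_grid >= 0 & p_grid <= 0.5))
  n <- v * (v - 1) / 2
  seeded(seed, function() {
    cliques <- random_cliques(v, k, n_patterns)
    U <- array(runif(n * n_patterns * trials), c(n, n_patterns, trials))
    rows <- vector("list", length(p_grid))
    for (ip in seq_along(p_grid)) {
      p <- p_grid[ip]
      starts <- matrix(0L, n, n_patterns * trials)
      targets <- matrix(0L, n, n_patterns * trials)
      c0 <- 0L
      for (t in seq_len(trials)) {
        flips <- U[, , t, drop = FALSE] < p
        dim(flips) <- c(n, n_patterns)
        starts[, c0 + seq_len(n_patterns)] <-
          as.integer(xor(cliques == 1L, flips))
        targets[, c0 + seq_len(n_patterns)] <- cliques
        c0 <- c0 + n_patterns
      }
      res <- recover_sym_batch(params, starts, targets,
                               order_policy == "random")
      rows[[ip]] <- data.frame(
        p = p,
        pattern = rep(seq_len(n_patterns), times = trials),
        trial = rep(seq_len(trials), each = n_patterns),
        recovered = res$recovered, bit_acc = res$bit_acc)
    }
    trial_table(do.call(rbind, rows),
                list(experiment = "robustness_curve", v = v, k = k,
                     x = params$x, y = params$y, z = params$z,
                     p_grid = p_grid, n_patterns = n_patterns,
                     trials = trials, seed = seed,
                     order_policy = order_policy))
  })
}

#' Aggregate a robustness curve per corruption level
#'
#' @param tab output of [robustness_curve()].
#' @return a data.frame with `p`, `recovery_rate`, `recovery_sd`,
#'   `mean_bit_acc`.
#' @export
summarize_robustness <- function(tab) {
  sp <- split(as.data.frame(tab), tab$p)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    p = d$p[1L], recovery_rate = mean(d$recovered),
    recovery_sd = sd(d$recovered), mean_bit_acc = mean(d$bit_acc))))
  rownames(out) <- NULL
  out[order(out$p), ]
}

#' Training-set-size curve for MPF fitting
#'
#' For each training-set size: fit a full `(W, theta)` network on
#' freshly drawn random `k`-cliques by [fit_mpf()], then measure on
#' `test_count` held-out random cliques (i) the fraction that are fixed
#' points and (ii) the mean fraction of bits correct after converging
#' the dynamics initialized at each held-out clique.
#'
#' @param v,k vertex count and clique size.
#' @param sample_sizes training-set sizes (positive integers).
#' @param test_count held-out cliques per cell.
#' @param trials independent repetitions per size.
#' @param seed integer seed.
#' @param fit_options list passed on to [fit_mpf()] (`max_iter`,
#'   `grad_tol`, `init_type`).
#' @return a `trial_table` with one row per `(size, trial)`: columns
#'   `size`, `trial`, `fixation`, `mean_bit_acc`, `final_flow`,
#'   `converged`.
#' @export
training_curve <- function(v, k, sample_sizes, test_count = 200,
                           trials = 1, seed = 1, fit_options = list()) {
  stopifnot(all(sample_sizes >= 1))
  seeded(seed, function() {
    rows <- list()
    for (size in sample_sizes) {
      for (t in seq_len(trials)) {
        train <- random_cliques(v, k, size)
        test <- random_cliques(v, k, test_count)
        fit <- do.call(fit_mpf, c(list(X = train), fit_options))
        net <- fit$network
        fixed <- is_fixed_point(test, net)
        conv <- cpp_converge_dense_batch(net$W, net$theta, test, test,
                                         FALSE, net$n)
        rows[[length(rows) + 1L]] <- data.frame(
          size = size, trial = t, fixation = mean(fixed),
          mean_bit_acc = mean(conv$bit_acc),
          final_flow = fit$final_flow, converged = fit$converged)
      }
    }
    trial_table(do.call(rbind, rows),
                list(experiment = "training_curve", v = v, k = k,
                     sample_sizes = sample_sizes, test_count = test_count,
                     trials = trials, seed = seed,
                     total_cliques = count_cliques(v, k)))
  })
}

#' Group statistics of learned weights and thresholds
#'
#' Partitions the off-diagonal weights of a network on edge-neurons by
#' overlap class (`|e cap f| = 1` vs `0`), rescales everything so the
#' thresholds have mean 1 (a pure gauge choice: dynamics are invariant
#' under positive rescaling) and reports group means and spreads. For a
#' well-trained network the three groups concentrate on the symmetric
#' family's `(x, y, z)`.
#'
#' @param net a [hopfield_network()] with `n = v(v-1)/2`.
#' @param v vertex count.
#' @return a list with `x_mean`, `x_sd`, `y_mean`, `y_sd`, `theta_mean`
#'   (post-scaling, equal to 1), `theta_sd`, `scale` (the mean threshold
#'   divided out) and `empirical` (a [symmetric_params()] from the group
#'   means).
#' @export
weight_group_stats <- function(net, v) {
  stopifnot(inherits(net, "hopfield_network"))
  n <- v * (v - 1) / 2
  if (net$n != n) stop(sprintf("network size %d != v(v-1)/2 = %d", net$n, n))
  scale <- mean(net$theta)
  if (abs(scale) < 1e-300) stop("mean threshold is zero; cannot normalize")
  ends <- edge_endpoints(v)
  shared <- (outer(ends[1L, ], ends[1L, ], "==") +
             outer(ends[1L, ], ends[2L, ], "==") +
             outer(ends[2L, ], ends[1L, ], "==") +
             outer(ends[2L, ], ends[2L, ], "=="))
  off <- upper.tri(shared)
  w <- net$W[off] / scale
  cls <- shared[off]
  xg <- w[cls == 1L]
  yg <- w[cls == 0L]
  th <- net$theta / scale
  list(x_mean = mean(xg), x_sd = sd(xg),
       y_mean = mean(yg), y_sd = sd(yg),
       theta_mean = mean(th), theta_sd = sd(th), scale = scale,
       empirical = symmetric_params(x = mean(xg), y = mean(yg), z = 1,
                                    v = v))
}

#' Named parameter presets for hidden-clique recovery
#'
#' `"mpf-theory"` is the closed-form flow minimizer
#' ([mpf_optimal_x()]); `"large-deviation"` the robust setting
#' ([large_deviation_x()] at design level `p_design`); `"mpf-fit"`
#' fits a full network by MPF on `fit_samples` random cliques and
#' projects it onto the symmetric family via [weight_group_stats()].
#'
#' @param preset preset name.
#' @param v,k vertex count and clique size.
#' @param p_design design corruption level for `"large-deviation"`.
#' @param fit_samples,seed training-set size and seed for `"mpf-fit"`.
#' @return a [symmetric_params()].
#' @export
clique_preset <- function(preset = c("mpf-theory", "large-deviation",
                                     "mpf-fit"),
                          v, k, p_design = 1 / 4, fit_samples = 500,
                          seed = 1) {
  preset <- match.arg(preset)
  switch(preset,
    "mpf-theory" = symmetric_params(x = mpf_optimal_x(k), y = 0, z = 1,
                                    v = v, k = k),
    "large-deviation" = symmetric_params(x = large_deviation_x(k, p_design),
                                         y = 0, z = 1, v = v, k = k),
    "mpf-fit" = {
      X <- random_cliques(v, k, fit_samples, seed = seed)
      fit <- fit_mpf(X)
      gs <- weight_group_stats(fit$network, v)
      symmetric_params(x = gs$x_mean, y = gs$y_mean, z = 1, v = v, k = k)
    })
}

#' Denoise a graph by converging the clique-storing dynamics
#'
#' Runs the symmetric-family dynamics from an arbitrary graph state (a
#' noisy/hidden clique instance) and reports the fixed point reached,
#' whether it is a clique and of what size. Non-clique fixed points
#' (e.g. star-like graphs) are possible and simply reported.
#'
#' @param state a 0/1 graph state of length `v(v-1)/2` (or a `v`-by-`v`
#'   adjacency matrix).
#' @param params a [symmetric_params()].
#' @param order_policy sweep order policy, see [converge()].
#' @return a list with `state` (the fixed point), `is_clique`,
#'   `clique_size` (`NA` when not a clique) and `sweeps`.
#' @export
hidden_clique_solve <- function(state, params,
                                order_policy = c("random", "fixed")) {
  stopifnot(inherits(params, "symmetric_params"))
  order_policy <- match.arg(order_policy)
  if (is.matrix(state)) state <- state_from_adjacency(state)
  res <- converge(state, params, order_policy = order_policy)
  icl <- is_clique_state(res$fixed_point, params$v)
  list(state = res$fixed_point, is_clique = as.logical(icl),
       clique_size = if (isTRUE(as.logical(icl))) attr(icl, "k")
                     else NA_integer_,
       sweeps = res$sweeps)
}

#' Neighbor-count extrema of corrupted cliques
#'
#' Simulates p-corruptions of the canonical `k`-clique on `v = 2k`
#' vertices and records, per trial, the five extrema of the vertex edge
#' counts: `M_in`/`m_in` (max/min edges from a clique vertex to other
#' clique vertices), `M_out`/`m_out` (max/min edges from an outside
#' vertex to other outside vertices) and `M_between` (max edges from an
#' outside vertex into the clique). Concentration makes
#' `M_in - k(1-p)`, `m_in - k(1-p)`, `M_out - kp`, `m_out - kp` and
#' `M_between - kp` all \eqn{o(\sqrt k \ln k)}.
#'
#' @param k clique size (`v = 2k`).
#' @param p corruption level.
#' @param trials number of simulated corruptions.
#' @param seed integer seed.
#' @return a `trial_table` with columns `trial`, `M_in`, `m_in`,
#'   `M_out`, `m_out`, `M_between`.
#' @export
neighbor_stats <- function(k, p, trials = 100, seed = 1) {
  v <- 2 * k
  cl <- clique_state(seq_len(k), v)
  ends <- edge_endpoints(v)
  in_cl <- ends <= k
  seeded(seed, function() {
    rows <- vector("list", trials)
    for (t in seq_len(trials)) {
      st <- as.integer(xor(cl == 1L, runif(length(cl)) < p))
      act <- st == 1L
      both_in <- act & in_cl[1L, ] & in_cl[2L, ]
      both_out <- act & !in_cl[1L, ] & !in_cl[2L, ]
      between <- act & xor(in_cl[1L, ], in_cl[2L, ])
      d_in <- tabulate(as.integer(ends[, both_in]), nbins = v)[seq_len(k)]
      d_out <- tabulate(as.integer(ends[, both_out]), nbins = v)[k + seq_len(k)]
      d_btw <- tabulate(as.integer(ends[, between]), nbins = v)
      d_btw_out <- d_btw[k + seq_len(k)]   # edges into the clique
      rows[[t]] <- data.frame(trial = t, M_in = max(d_in), m_in = min(d_in),
                              M_out = max(d_out), m_out = min(d_out),
                              M_between = max(d_btw_out))
    }
    trial_table(do.call(rbind, rows),
                list(experiment = "neighbor_stats", k = k, v = v, p = p,
                     trials = trials, seed = seed))
  })
}

#' Finite-scale estimate of the robustness index
#'
#' Grid search for the largest corruption level `p` (in steps of
#' `p_step` up to 1/2) at which the sampled recovery rate of random
#' `k`-cliques stays at least `1 - epsilon`. A finite-`k` proxy for the
#' asymptotic robustness index, which is at most 1/2 by definition.
#'
#' @param v,k vertex count and clique size.
#' @param params a [symmetric_params()].
#' @param epsilon tolerated failure rate in `(0, 1)`.
#' @param p_step grid resolution.
#' @param trials corrupted cliques per grid point.
#' @param seed integer seed.
#' @return the estimate (0 when even the smallest positive `p` fails),
#'   with attribute `rates` holding the full grid.
#' @export
estimate_alpha <- function(v, k, params, epsilon = 0.1, p_step = 0.05,
                           trials = 100, seed = 1) {
  stopifnot(epsilon > 0, epsilon < 1)
  p_grid <- seq(p_step, 0.5, by = p_step)
  tab <- robustness_curve(v, k, params, p_grid, n_patterns = trials,
                          trials = 1, seed = seed)
  sm <- summarize_robustness(tab)
  pass <- sm$recovery_rate >= 1 - epsilon
  est <- if (any(pass)) max(sm$p[pass]) else 0
  attr(est, "rates") <- sm
  est
}
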