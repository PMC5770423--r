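# Limits of permutation-storing (Hopfield-Platt) networks: states are
# length k(k-1) binary vectors over ordered pairs (i, j), i != j, with
# bit (i, j) = 1 meaning sigma(i) = j. Derangements admit critical
# two-bit-flip patterns lying exactly between two stored permutations,
# so no such network -- whatever its weights -- can error-correct them
# reliably; only the combinatorial machinery is built here.

#' Position of an ordered pair in the off-diagonal row-major layout
#'
#' @param i,j letters with `i != j`, in `1..k`.
#' @param k number of letters.
#' @return integer position(s) in `1..k(k-1)`.
#' @export
pair_position <- function(i, j, k) {
  stopifnot(all(i >= 1 & i <= k), all(j >= 1 & j <= k))
  if (any(i == j)) stop("diagonal pairs (i, i) have no slot")
  as.integer((i - 1) * (k - 1) + j - (j > i))
}

#' @rdname pair_position
#' @param pos position in `1..k(k-1)`.
#' @export
position_pair <- function(pos, k) {
  stopifnot(all(pos >= 1 & pos <= k * (k - 1)))
  i <- (pos - 1) %/% (k - 1) + 1
  rank <- pos - (i - 1) * (k - 1)
  j <- rank + (rank >= i)
  rbind(i = as.integer(i), j = as.integer(j))
}

check_permutation <- function(sigma) {
  sigma <- as.integer(sigma)
  k <- length(sigma)
  if (k < 2L || anyNA(sigma) || !identical(sort(sigma), seq_len(k)))
    stop("`sigma` must be a bijection given as a length-k image vector")
  sigma
}

#' Encode a permutation as a binary state
#'
#' Sets bit `(i, sigma(i))` for every letter. The representation has no
#' diagonal slots, so any permutation with a fixed point (in particular
#' the identity) is not encodable and raises an error.
#'
#' @param sigma an integer image vector: `sigma[i]` is the image of `i`.
#' @return a 0/1 integer vector of length `k(k-1)` with exactly one 1
#'   per source letter and one per target letter.
#' @export
encode_permutation <- function(sigma) {
  sigma <- check_permutation(sigma)
  k <- length(sigma)
  if (any(sigma == seq_len(k)))
    stop("permutations with fixed points have no off-diagonal encoding")
  bits <- integer(k * (k - 1))
  bits[pair_position(seq_len(k), sigma, k)] <- 1L
  bits
}

#' @rdname encode_permutation
#' @param bits a 0/1 vector of length `k(k-1)`.
#' @param k number of letters.
#' @export
decode_permutation <- function(bits, k) {
  bits <- check_state(bits, k * (k - 1))
  pairs <- position_pair(which(bits == 1L), k)
  if (ncol(pairs) != k || anyDuplicated(pairs["i", ]) ||
      anyDuplicated(pairs["j", ]))
    stop("state does not encode a permutation")
  sigma <- integer(k)
  sigma[pairs["i", ]] <- pairs["j", ]
  check_permutation(sigma)
}

#' Derangement utilities
#'
#' A derangement is a permutation without fixed points; among all
#' permutations their fraction tends to \eqn{e^{-1} \approx 0.37}.
#'
#' @param sigma an image vector.
#' @return `is_derangement()` a logical.
#' @export
is_derangement <- function(sigma) {
  sigma <- check_permutation(sigma)
  all(sigma != seq_along(sigma))
}

#' @rdname is_derangement
#' @param k number of letters.
#' @param seed optional seed (caller's RNG untouched when given).
#' @export
random_derangement <- function(k, seed = NULL) {
  if (!is_count(k, 2)) stop("`k` must be an integer >= 2")
  seeded(seed, function() {
    repeat {
      sigma <- sample.int(k)
      if (all(sigma != seq_len(k))) return(sigma)
    }
  })
}

cycle_count <- function(sigma) {
  sigma <- check_permutation(sigma)
  seen <- logical(length(sigma))
  cycles <- 0L
  for (s in seq_along(sigma)) {
    if (seen[s]) next
    cycles <- cycles + 1L
    i <- s
    while (!seen[i]) {
      seen[i] <- TRUE
      i <- sigma[i]
    }
  }
  cycles
}

#' Critical two-bit-flip pattern of a derangement
#'
#' For a derangement \eqn{\sigma} and letters `i`, `j` with `i != j`,
#' `j != sigma(i)`, flip two bits of the encoded state (add edge `i j`,
#' remove edge `i sigma(i)`) to obtain the pattern `y`; two further
#' flips (remove `sigma^{-1}(j) j`, add `sigma^{-1}(j) sigma(i)`) land
#' on the encoding of a second permutation `x_alt`. `y` is then at
#' Hamming distance 2 from *both* stored permutations, so no network
#' storing all permutations can decide which one it came from.
#'
#' The construction degenerates when `j == sigma(sigma(i))`: the fourth
#' flip would need the diagonal slot `(sigma(i), sigma(i))`, so `x_alt`
#' is not encodable and an error is raised. Derangements whose cycles
#' all have length 2 (perfect matchings, even `k`) have no degenerate
#' pairs and realize the full count of `k(k-2)` critical pairs.
#'
#' @param sigma a derangement image vector.
#' @param i,j letters with `i != j`, `j != sigma(i)`,
#'   `j != sigma(sigma(i))`.
#' @return an object of class `critical_pair`: list with `i`, `j`,
#'   `y_pattern`, `x_alt` (image vector), `x_alt_state`,
#'   `stage1`/`stage2` (position pairs: one edge added, one removed per
#'   stage) and `critical` (all four positions).
#' @export
critical_pair <- function(sigma, i, j) {
  sigma <- check_permutation(sigma)
  if (!is_derangement(sigma)) stop("`sigma` must be a derangement")
  k <- length(sigma)
  if (!is_count(i) || !is_count(j) || i > k || j > k) stop("letter out of range")
  if (i == j || j == sigma[i]) stop("need i != j and j != sigma(i)")
  if (j == sigma[sigma[i]])
    stop("degenerate pair: j = sigma(sigma(i)) has no encodable x_alt")
  si <- sigma[i]
  pre_j <- which(sigma == j)
  x <- encode_permutation(sigma)
  stage1 <- c(add = pair_position(i, j, k), drop = pair_position(i, si, k))
  stage2 <- c(drop = pair_position(pre_j, j, k),
              add = pair_position(pre_j, si, k))
  y <- x
  y[stage1] <- 1L - y[stage1]
  alt <- sigma
  alt[i] <- j
  alt[pre_j] <- si
  alt_state <- encode_permutation(alt)
  stopifnot(sum(y != x) == 2L, sum(y != alt_state) == 2L)
  structure(list(i = as.integer(i), j = as.integer(j), y_pattern = y,
                 x_alt = alt, x_alt_state = alt_state,
                 stage1 = stage1, stage2 = stage2,
                 critical = unname(c(stage1, stage2))),
            class = "critical_pair")
}

#' All non-degenerate critical pairs of a derangement
#'
#' @param sigma a derangement image vector.
#' @return a list of [critical_pair()] objects; attribute `n_nominal`
#'   holds the nominal count `k(k-2)` (attained exactly when `sigma`
#'   has no degenerate pairs, e.g. a perfect matching).
#' @export
critical_pairs <- function(sigma) {
  sigma <- check_permutation(sigma)
  k <- length(sigma)
  out <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j == i || j == sigma[i] || j == sigma[sigma[i]]) next
      out[[length(out) + 1L]] <- critical_pair(sigma, i, j)
    }
  }
  attr(out, "n_nominal") <- k * (k - 2)
  out
}

#' Indistinguishability probability bounds
#'
#' Probability that the p-corruption of a stored derangement is an
#' indistinguishable realization (equally valid as a corruption of some
#' second stored permutation). Per critical pair the coupling event has
#' probability \eqn{q = 4(1-p)^2 p^2}; treating the `k(k-2)` pairs as
#' independent gives \eqn{1 - (1 - q)^{k(k-2)}}, which dominates the
#' looser printed bound \eqn{1 - (1 - 4p^2)^{n/2}} with
#' \eqn{n = k(k-1)} (the ordering is verified numerically in the tests,
#' not assumed).
#'
#' @param p corruption level in `(0, 1/2)`.
#' @param k number of letters.
#' @return a list with `exact_pair` and `lower_bound`.
#' @export
indistinguishability_bound <- function(p, k) {
  if (!is.numeric(p) || any(p <= 0 | p >= 0.5))
    stop("`p` must lie in (0, 1/2)")
  if (!is_count(k, 3)) stop("`k` must be an integer >= 3")
  q <- 4 * (1 - p)^2 * p^2
  n <- k * (k - 1)
  list(exact_pair = 1 - (1 - q)^(k * (k - 2)),
       lower_bound = 1 - (1 - 4 * p^2)^(n / 2))
}

#' Monte-Carlo frequency of indistinguishable corruptions
#'
#' Simulates p-corruptions of the encoded derangement and counts the
#' trials in which at least one critical pair exhibits the
#' indistinguishable flip combination: exactly one of its two stage-1
#' edges and exactly one of its two stage-2 edges flipped (2 x 2
#' combinations, each of probability \eqn{p^2(1-p)^2}, hence
#' \eqn{4(1-p)^2p^2} per pair). Every such combination leaves the
#' corrupted state at Hamming distance 2 from two distinct stored
#' permutations on the critical edges.
#'
#' @param sigma a derangement image vector.
#' @param p corruption level in `(0, 1/2)`.
#' @param trials number of Monte-Carlo draws.
#' @param seed optional seed.
#' @return the frequency, with attributes `se` (binomial standard
#'   error), `n_pairs` (critical pairs used) and `pair_freq` (the
#'   per-pair event frequencies, whose mean estimates the per-pair
#'   marginal \eqn{4(1-p)^2p^2}; the *union* frequency is well below
#'   the independent product form because pairs share critical edges).
#' @export
monte_carlo_indistinguishable <- function(sigma, p, trials, seed = NULL) {
  if (!is_count(trials)) stop("`trials` must be a positive integer")
  pairs <- critical_pairs(sigma)
  if (!length(pairs)) stop("`sigma` has no non-degenerate critical pairs")
  k <- length(sigma)
  n <- k * (k - 1)
  s1 <- vapply(pairs, function(cp) unname(cp$stage1), integer(2))
  s2 <- vapply(pairs, function(cp) unname(cp$stage2), integer(2))
  seeded(seed, function() {
    hit <- 0L
    pair_hits <- numeric(length(pairs))
    block <- 5000L
    done <- 0L
    while (done < trials) {
      m <- min(block, trials - done)
      F <- matrix(runif(n * m) < p, n, m)
      ev <- matrix(FALSE, length(pairs), m)
      for (q in seq_along(pairs)) {
        ev[q, ] <- (F[s1[1L, q], ] + F[s1[2L, q], ] == 1L) &
          (F[s2[1L, q], ] + F[s2[2L, q], ] == 1L)
      }
      hit <- hit + sum(colSums(ev) > 0L)
      pair_hits <- pair_hits + rowSums(ev)
      done <- done + m
    }
    freq <- hit / trials
    attr(freq, "se") <- sqrt(freq * (1 - freq) / trials)
    attr(freq, "n_pairs") <- length(pairs)
    attr(freq, "pair_freq") <- pair_hits / trials
    freq
  })
}

#' Read and write permutations as one-line images
#'
#' Format: the single line `"sigma(1) sigma(2) ... sigma(k)"`, 1-based.
#'
#' @param sigma an image vector.
#' @param path file path.
#' @return `read_permutation()` returns an integer image vector.
#' @export
write_permutation <- function(sigma, path) {
  sigma <- check_permutation(sigma)
  writeLines(paste(sigma, collapse = " "), path)
  invisible(path)
}

#' @rdname write_permutation
#' @export
read_permutation <- function(path) {
  check_permutation(as.integer(
    strsplit(trimws(readLines(path, n = 1L)), "\\s+")[[1L]]))
}
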