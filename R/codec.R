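# Bijection between simple graphs on v vertices and binary states of
# length n = v(v-1)/2, plus clique generation and graph statistics.
# Vertices are 1-based in the R API; serialized edge lists are 0-based.

#' Edge endpoint table
#'
#' Lexicographic enumeration of the unordered vertex pairs of the
#' complete graph on `v` vertices: column `e` holds the endpoints
#' `(i, j)`, `i < j`, of edge index `e`; `(1,2) -> 1`, `(1,3) -> 2`, ...,
#' `(v-1, v) -> n`.
#'
#' @param v vertex count (at least 2).
#' @return a 2-by-`n` integer matrix, `n = v(v-1)/2`.
#' @export
edge_endpoints <- function(v) {
  if (!is_count(v, min = 2)) stop("`v` must be an integer >= 2")
  key <- as.character(v)
  hit <- .cliquenet_cache[[key]]
  if (!is.null(hit)) return(hit)
  ends <- combn(as.integer(v), 2L)
  .cliquenet_cache[[key]] <- ends
  ends
}

#' Edge indexing
#'
#' `edge_index()` maps a vertex pair `i < j` to its lexicographic rank in
#' `1..n`; `index_edge()` is the inverse.
#'
#' @param i,j vertex indices with `1 <= i < j <= v`.
#' @param e edge index in `1..n`.
#' @param v vertex count.
#' @return `edge_index()` an integer index; `index_edge()` an integer
#'   vector `c(i, j)`.
#' @examples
#' edge_index(1, 2, v = 8)   # 1
#' index_edge(28, v = 8)     # c(7, 8)
#' @export
edge_index <- function(i, j, v) {
  if (!is_count(v, 2)) stop("`v` must be an integer >= 2")
  if (!all(i >= 1 & j <= v & i < j)) stop("need 1 <= i < j <= v")
  as.integer((i - 1) * v - i * (i + 1) / 2 + j)
}

#' @rdname edge_index
#' @export
index_edge <- function(e, v) {
  n <- v * (v - 1) / 2
  if (!all(e >= 1 & e <= n)) stop("edge index out of range")
  ends <- edge_endpoints(v)
  ends[, e]
}

#' Encode a clique as a binary state
#'
#' Returns the length-`n` state of the graph whose edges are exactly the
#' \eqn{\binom{k}{2}} pairs internal to `vertices` (a `k`-clique plus
#' `v - k` isolated vertices).
#'
#' @param vertices distinct vertex indices (at least 2 of them).
#' @param v vertex count.
#' @return a 0/1 integer vector of length `v(v-1)/2`.
#' @export
clique_state <- function(vertices, v) {
  vertices <- as.integer(vertices)
  if (length(vertices) < 2L) stop("a clique needs at least 2 vertices")
  if (anyDuplicated(vertices)) stop("duplicate vertices")
  if (any(vertices < 1L | vertices > v)) stop("vertex out of range")
  state <- integer(v * (v - 1) / 2)
  pairs <- combn(sort(vertices), 2L)
  state[edge_index(pairs[1L, ], pairs[2L, ], v)] <- 1L
  state
}

#' Vertices incident to at least one edge of a state
#'
#' For a clique state this decodes the clique's vertex set.
#'
#' @param state a 0/1 vector of length `v(v-1)/2`.
#' @param v vertex count.
#' @return an integer vector of vertex indices.
#' @export
support_vertices <- function(state, v) {
  state <- check_state(state, v * (v - 1) / 2)
  ends <- edge_endpoints(v)
  sort(unique(as.integer(ends[, state == 1L])))
}

#' Does a state encode a clique?
#'
#' @inheritParams support_vertices
#' @return `TRUE` iff the edges present are exactly all pairs among the
#'   supported vertices (a `k`-clique for some `k >= 2`), with attribute
#'   `k` giving the clique size when `TRUE`.
#' @export
is_clique_state <- function(state, v) {
  state <- check_state(state, v * (v - 1) / 2)
  if (sum(state) == 0L) return(FALSE)
  verts <- support_vertices(state, v)
  k <- length(verts)
  ok <- sum(state) == k * (k - 1) / 2 &&
    identical(state, clique_state(verts, v))
  if (ok) attr(ok, "k") <- k
  ok
}

#' Graph statistics entering the symmetric energy
#'
#' Counts the edges `#E`, the edge pairs sharing exactly one vertex
#' (`s1`) and the disjoint edge pairs (`s0`) of the graph encoded by
#' `state`. The symmetric-family energy is
#' \eqn{E_G = -x\,S_1(G) - y\,S_0(G) + z\,\#E(G)}.
#'
#' Two routes are provided: the degree formula
#' \eqn{S_1 = \sum_i \binom{\deg i}{2}} with
#' \eqn{S_0 = \binom{\#E}{2} - S_1} (default), and direct enumeration of
#' all edge pairs; they must agree and the test-suite asserts it.
#'
#' @inheritParams support_vertices
#' @param method `"degree"` (O(v + n)) or `"pairs"` (O(#E^2)).
#' @return a list with `edge_count`, `s1`, `s0`.
#' @examples
#' graph_stats(clique_state(1:4, 6), v = 6)  # edges 6, s1 = 12, s0 = 3
#' @export
graph_stats <- function(state, v, method = c("degree", "pairs")) {
  state <- check_state(state, v * (v - 1) / 2)
  method <- match.arg(method)
  ends <- edge_endpoints(v)
  act <- ends[, state == 1L, drop = FALSE]
  ec <- ncol(act)
  if (method == "degree") {
    deg <- tabulate(as.integer(act), nbins = v)
    s1 <- sum(choose(deg, 2))
    s0 <- choose(ec, 2) - s1
  } else {
    s1 <- 0
    if (ec >= 2L) {
      for (a in seq_len(ec - 1L)) {
        shared <- (act[1L, a] == act[1L, -(1:a)]) +
          (act[1L, a] == act[2L, -(1:a)]) +
          (act[2L, a] == act[1L, -(1:a)]) +
          (act[2L, a] == act[2L, -(1:a)])
        s1 <- s1 + sum(shared == 1L)
      }
    }
    s0 <- choose(ec, 2) - s1
  }
  list(edge_count = ec, s1 = as.numeric(s1), s0 = as.numeric(s0))
}

#' Clique counts
#'
#' `count_cliques()` is the exact binomial \eqn{\binom{v}{k}};
#' `asymptotic_clique_count()` evaluates the Stirling asymptotic
#' \eqn{2^{\sqrt{2n}+1/4} / (n^{1/4}\sqrt{\pi})} for the number
#' \eqn{\binom{2k}{k}} of `k`-cliques on `2k` vertices as a function of
#' the neuron count \eqn{n = \binom{2k}{2}}.
#'
#' @param v,k vertex count and clique size, `2 <= k <= v`.
#' @param n neuron count.
#' @param log if `TRUE` return the natural log (needed once the count
#'   overflows doubles).
#' @param corrected the published constant `+1/4` in the exponent is a
#'   factor \eqn{\sqrt 2} short of the Stirling limit of
#'   \eqn{\binom{2k}{k}} (substituting \eqn{k \approx \sqrt{n/2}+1/4}
#'   into \eqn{4^k/\sqrt{\pi k}} gives `+3/4`); `corrected = TRUE` uses
#'   `+3/4` so the ratio to the exact count tends to 1.
#' @return a numeric count (or log-count).
#' @export
count_cliques <- function(v, k) {
  if (!is_count(v, 2) || !is_count(k, 2) || k > v)
    stop("need 2 <= k <= v")
  choose(v, k)
}

#' @rdname count_cliques
#' @export
asymptotic_clique_count <- function(n, log = FALSE, corrected = FALSE) {
  stopifnot(is.numeric(n), all(n > 0))
  shift <- if (corrected) 0.75 else 0.25
  lg <- (sqrt(2 * n) + shift) * base::log(2) - 0.25 * base::log(n) -
    0.5 * base::log(pi)
  if (log) lg else exp(lg)
}

#' Sample random k-cliques
#'
#' Draws `count` uniformly random `k`-subsets of the vertices and encodes
#' each as a clique state. With `distinct = TRUE` duplicates are rejected
#' (falling back to explicit enumeration of all subsets when `count` is
#' close to \eqn{\binom{v}{k}} and the total is at most `1e6`).
#'
#' @inheritParams count_cliques
#' @param count number of cliques to draw.
#' @param seed optional integer seed (caller's RNG untouched when given).
#' @param distinct require pairwise-distinct cliques.
#' @return an `n`-by-`count` integer matrix, one clique state per column.
#' @export
random_cliques <- function(v, k, count, seed = NULL, distinct = FALSE) {
  if (!is_count(count)) stop("`count` must be a positive integer")
  total <- count_cliques(v, k)
  if (distinct && count > total)
    stop(sprintf("cannot draw %d distinct %d-cliques on %d vertices", count,
                 k, v))
  seeded(seed, function() {
    n <- v * (v - 1) / 2
    out <- matrix(0L, n, count)
    if (distinct && count > total / 2 && total <= 1e6) {
      sets <- combn(v, k)
      pick <- sample.int(ncol(sets), count)
      for (c in seq_len(count)) out[, c] <- clique_state(sets[, pick[c]], v)
      return(out)
    }
    seen <- if (distinct) new.env(parent = emptyenv()) else NULL
    c <- 1L
    while (c <= count) {
      verts <- sort(sample.int(v, k))
      if (distinct) {
        key <- paste(verts, collapse = ",")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
      }
      out[, c] <- clique_state(verts, v)
      c <- c + 1L
    }
    out
  })
}

#' Graph text input/output
#'
#' Graphs are exchanged either as edge-list text (one `"i j"` pair per
#' line, 0-based vertex ids) or as a dense 0/1 adjacency matrix (one row
#' of `v` space-separated entries per line).
#'
#' @inheritParams support_vertices
#' @param path file path.
#' @return readers return a 0/1 integer state vector; writers return
#'   `path` invisibly.
#' @export
write_edgelist <- function(state, v, path) {
  state <- check_state(state, v * (v - 1) / 2)
  ends <- edge_endpoints(v)
  act <- ends[, state == 1L, drop = FALSE]
  writeLines(sprintf("%d %d", act[1L, ] - 1L, act[2L, ] - 1L), path)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path, v) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  state <- integer(v * (v - 1) / 2)
  if (length(lines)) {
    parts <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"),
                                   as.integer))
    i <- pmin(parts[, 1L], parts[, 2L]) + 1L
    j <- pmax(parts[, 1L], parts[, 2L]) + 1L
    if (any(i == j)) stop("self-loops are not representable")
    state[edge_index(i, j, v)] <- 1L
  }
  state
}

#' @rdname write_edgelist
#' @export
write_adjacency <- function(state, v, path) {
  state <- check_state(state, v * (v - 1) / 2)
  A <- adjacency_from_state(state, v)
  writeLines(apply(A, 1L, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_adjacency <- function(path) {
  rows <- lapply(strsplit(trimws(readLines(path)), "\\s+"), as.integer)
  rows <- rows[lengths(rows) > 0L]
  A <- do.call(rbind, rows)
  v <- nrow(A)
  if (ncol(A) != v || any(A != t(A)) || any(diag(A) != 0L))
    stop("adjacency matrix must be square, symmetric, zero-diagonal")
  state_from_adjacency(A)
}

#' Convert between states and adjacency matrices
#'
#' @inheritParams support_vertices
#' @param A a symmetric 0/1 adjacency matrix with zero diagonal.
#' @return `adjacency_from_state()` a `v`-by-`v` 0/1 matrix;
#'   `state_from_adjacency()` a 0/1 state vector.
#' @export
adjacency_from_state <- function(state, v) {
  state <- check_state(state, v * (v - 1) / 2)
  A <- matrix(0L, v, v)
  A[lower.tri(A)] <- 0L
  ends <- edge_endpoints(v)
  act <- ends[, state == 1L, drop = FALSE]
  A[cbind(act[1L, ], act[2L, ])] <- 1L
  A[cbind(act[2L, ], act[1L, ])] <- 1L
  A
}

#' @rdname adjacency_from_state
#' @export
state_from_adjacency <- function(A) {
  v <- nrow(A)
  ends <- edge_endpoints(v)
  as.integer(A[cbind(ends[1L, ], ends[2L, ])])
}
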