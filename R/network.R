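#' Construct a binary Hopfield network
#'
#' A Hopfield network over `n` binary threshold neurons is a pair
#' \eqn{(W, \theta)}: an `n`-by-`n` real symmetric weight matrix with zero
#' diagonal and a length-`n` threshold vector. Symmetry plus the zero
#' diagonal guarantee that the asynchronous dynamics ([converge()])
#' descends the energy \eqn{E_x = -\tfrac12 x^\top W x + \theta^\top x}
#' and terminates in a fixed point.
#'
#' @param W numeric `n`-by-`n` symmetric matrix with zero diagonal.
#' @param theta numeric threshold vector of length `n`.
#' @param tol tolerance used when validating symmetry / zero diagonal.
#' @return an object of class `hopfield_network`: a list with elements
#'   `W`, `theta` and `n`.
#' @examples
#' net <- hopfield_network(matrix(0, 3, 3), rep(1, 3))
#' energy(c(1, 1, 0), net)
#' @export
hopfield_network <- function(W, theta, tol = 1e-8) {
  if (!is.matrix(W) || !is.numeric(W) || nrow(W) != ncol(W))
    stop("`W` must be a square numeric matrix")
  n <- nrow(W)
  if (!is.numeric(theta) || length(theta) != n)
    stop(sprintf("`theta` must be a numeric vector of length %d", n))
  if (any(abs(diag(W)) > tol))
    stop("`W` must have a zero diagonal")
  if (max(abs(W - t(W))) > tol)
    stop("`W` must be symmetric")
  W <- (W + t(W)) / 2          # remove round-off asymmetry
  diag(W) <- 0
  structure(list(W = W, theta = as.numeric(theta), n = n),
            class = "hopfield_network")
}

#' @export
print.hopfield_network <- function(x, ...) {
  cat(sprintf("Hopfield network: %d neurons (%d free parameters)\n",
              x$n, x$n * (x$n - 1) / 2 + x$n))
  cat(sprintf("  weight range [%.4g, %.4g], threshold range [%.4g, %.4g]\n",
              min(x$W), max(x$W), min(x$theta), max(x$theta)))
  invisible(x)
}

#' Read and write Hopfield networks as plain text
#'
#' Format: line 1 holds `n`; the next `n` lines hold the rows of `W`
#' (whitespace-delimited, full precision); the final line holds
#' \eqn{\theta}.
#'
#' @param net a [hopfield_network()].
#' @param path file path.
#' @return `read_network()` returns a `hopfield_network`;
#'   `write_network()` returns `path` invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "hopfield_network"))
  rows <- apply(net$W, 1L, function(r) paste(sprintf("%.17g", r),
                                             collapse = " "))
  lines <- c(as.character(net$n), rows,
             paste(sprintf("%.17g", net$theta), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[[1L]])
  if (length(lines) != n + 2L) stop("malformed network file")
  W <- do.call(rbind, lapply(lines[2:(n + 1L)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
  theta <- as.numeric(strsplit(trimws(lines[[n + 2L]]), "\\s+")[[1L]])
  hopfield_network(W, theta)
}

#' Read and write binary states as plain text
#'
#' A state is serialized as a single line of `'0'`/`'1'` characters with
#' no separators.
#'
#' @param state a 0/1 vector.
#' @param path file path.
#' @return `read_state()` returns an integer 0/1 vector.
#' @export
write_state <- function(state, path) {
  state <- check_state(state)
  writeLines(paste(state, collapse = ""), path)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  line <- trimws(readLines(path, n = 1L))
  state <- as.integer(strsplit(line, "")[[1L]])
  check_state(state)
}

#' Corrupt a state through a binary symmetric channel
#'
#' Flips each bit independently with probability `p` (the *p*-corruption
#' of the state). `p = 1/2` destroys all information: the output is then
#' uniform on \eqn{\{0,1\}^n} regardless of the input.
#'
#' @param state a 0/1 vector.
#' @param p flip probability in `[0, 1/2]`.
#' @param seed optional integer seed; when given, the caller's RNG state
#'   is left untouched and the result is a deterministic function of
#'   `(state, p, seed)`.
#' @return the corrupted 0/1 integer vector.
#' @examples
#' set.seed(1)
#' x <- clique_state(1:4, v = 8)
#' sum(p_corrupt(x, 0.2) != x)
#' @export
p_corrupt <- function(state, p, seed = NULL) {
  state <- check_state(state)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 0.5)
    stop("`p` must lie in [0, 1/2]")
  if (p == 0) return(state)
  seeded(seed, function() {
    flips <- runif(length(state)) < p
    as.integer(xor(state == 1L, flips))
  })
}
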