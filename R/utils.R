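# Internal helpers shared across modules.

# Evaluate fun() under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL uses the current stream.
seeded <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  fun()
}

# Validate a binary state vector, optionally against an expected length.
check_state <- function(state, n = NULL, arg = "state") {
  if (!is.numeric(state) && !is.logical(state))
    stop(sprintf("`%s` must be a numeric or logical 0/1 vector", arg))
  state <- as.integer(state)
  if (anyNA(state) || any(state != 0L & state != 1L))
    stop(sprintf("`%s` must contain only 0s and 1s", arg))
  if (!is.null(n) && length(state) != n)
    stop(sprintf("`%s` has length %d, expected %d", arg, length(state), n))
  state
}

# Coerce a list of states or a matrix (states as columns) to an integer
# matrix with one state per column, validating entries and a uniform length.
as_state_matrix <- function(X, n = NULL) {
  if (is.list(X)) {
    if (length(X) == 0L) stop("empty pattern set")
    lens <- lengths(X)
    if (length(unique(lens)) != 1L) stop("patterns have differing lengths")
    X <- vapply(X, check_state, integer(lens[[1L]]), n = lens[[1L]])
    if (!is.matrix(X)) X <- matrix(X, nrow = lens[[1L]])
  } else if (is.numeric(X) || is.logical(X)) {
    if (!is.matrix(X)) X <- matrix(as.integer(X), ncol = 1L)
    storage.mode(X) <- "integer"
    if (anyNA(X) || any(X != 0L & X != 1L))
      stop("pattern matrix must contain only 0s and 1s")
  } else {
    stop("`X` must be a 0/1 matrix (states as columns) or a list of states")
  }
  if (ncol(X) == 0L) stop("empty pattern set")
  if (!is.null(n) && nrow(X) != n)
    stop(sprintf("patterns have length %d, expected %d", nrow(X), n))
  X
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == floor(x)
}
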