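# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# `seed = NULL` leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation: one user-facing --seed fans out to the
# stochastic stages (subsampling, center choice, per-center estimation)
# through this affine map modulo the Mersenne prime 2^31 - 1, so every
# derived seed is a valid 32-bit integer.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(k)
  as.integer(s %% 2147483647)
}

check_sample_matrix <- function(X, min_rows = 2L) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("sample matrix must be numeric", call. = FALSE)
  if (nrow(X) < min_rows) {
    stop(sprintf("need at least %d samples (rows), got %d", min_rows, nrow(X)),
         call. = FALSE)
  }
  if (!all(is.finite(X))) stop("sample matrix contains non-finite entries", call. = FALSE)
  X
}

# All N(N-1)/2 unordered pairwise Euclidean distances. For wide matrices the
# Gram-matrix route hands the O(N^2 D) work to BLAS; stats::dist is kept for
# narrow data where its exact accumulation is just as fast.
pair_distances <- function(X) {
  if (ncol(X) <= 64L || nrow(X) > 5000L) {
    return(as.vector(stats::dist(X)))
  }
  G <- tcrossprod(X)
  sq <- diag(G)
  d2 <- outer(sq, sq, "+") - 2 * G
  sqrt(pmax(d2[lower.tri(d2)], 0))
}

# Distances from one row to all rows (including itself, distance 0).
dist_to_row <- function(X, i) {
  delta <- sweep(X, 2L, X[i, ], "-")
  sqrt(rowSums(delta * delta))
}
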