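# Seeded generators for the synthetic benchmark manifolds used to validate
# the estimator: flat families (binary cube, Gaussian cloud, hypercube)
# linearly embedded by a Haar-random rotation, curved families (cyclic
# polar-pair embedding, Swiss roll), unions of hypercubes, and
# high-contrast blob bitmap images.

# Haar-uniform rotation matrix in SO(D): QR of a Gaussian matrix with the
# sign of diag(R) fixed (gives O(D) Haar), then determinant corrected to +1.
random_rotation <- function(D) {
  qr_ <- qr(matrix(stats::rnorm(D * D), D, D))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))), D)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Linearly embed a d-dimensional sample matrix in D dimensions
#'
#' Appends `D - d` zero columns and applies one rotation matrix drawn
#' uniformly (Haar measure) from SO(D). An exact isometry: all pairwise
#' distances are preserved.
#'
#' @param X Numeric N x d matrix.
#' @param D Ambient dimension, `D >= ncol(X)`.
#' @param seed Integer seed for the rotation draw; `NULL` uses the current
#'   RNG stream.
#' @return N x D matrix.
#' @export
linear_embed <- function(X, D, seed = NULL) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (D < d) stop("ambient dimension D must be >= ncol(X)", call. = FALSE)
  Xz <- cbind(X, matrix(0, nrow(X), D - d))
  R <- with_seed(seed, random_rotation(D))
  Xz %*% R
}

#' @rdname generators
#' @export
gen_binary_cube <- function(N, d, D = d, seed = NULL) {
  with_seed(seed, {
    X <- matrix(sample(c(0, 1), N * d, replace = TRUE), N, d)
    linear_embed(X, D)
  })
}

#' Synthetic benchmark manifold generators
#'
#' Seeded generators for the benchmark dataset families, each returning an
#' N-row sample matrix:
#' \describe{
#'   \item{`gen_binary_cube(N, d, D)`}{uniform on the vertex set
#'     \eqn{\{0,1\}^d}, linearly embedded in D dimensions.}
#'   \item{`gen_gaussian(N, d, D)`}{standard multivariate Gaussian (identity
#'     covariance, zero mean) in d dimensions, linearly embedded.}
#'   \item{`gen_hypercube(N, d, D)`}{uniform on \eqn{[0,1]^d}, linearly
#'     embedded.}
#'   \item{`gen_curved(N, d)`}{uniform on \eqn{[0,2\pi]^d} mapped to 2d
#'     ambient coordinates by the cyclic polar pairs
#'     \eqn{(x_{i+1}\cos x_i,\; x_{i+1}\sin x_i)} for \eqn{i = 1 \dots d}
#'     with \eqn{x_{d+1} \equiv x_1} — a highly curved d-manifold in
#'     \eqn{R^{2d}} that defeats global estimators.}
#'   \item{`gen_swiss_roll(N)`}{\eqn{(x,y)} uniform on \eqn{[0,1]^2} mapped
#'     to \eqn{(x\cos(2\pi y),\, y,\, x\sin(2\pi y))}: the classic rolled-up
#'     surface in 3 dimensions.}
#'   \item{`gen_two_cubes(N1, N2, d1, d2, D)`}{union of two independently
#'     rotated, linearly embedded hypercubes of dimensions d1 and d2, each
#'     centered at the ambient origin so the components intersect. The
#'     component label of each row is returned in attribute `component`.}
#' }
#' All generators are deterministic under a fixed `seed`, which governs both
#' the sampling and the embedding rotation.
#'
#' @param N,N1,N2 Number of samples.
#' @param d,d1,d2 Intrinsic (pre-embedding) dimension.
#' @param D Ambient dimension (`>= d`).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Numeric sample matrix with N (or N1 + N2) rows.
#' @name generators
#' @examples
#' X <- gen_gaussian(200, d = 3, D = 10, seed = 1)
#' dim(X)
NULL

#' @rdname generators
#' @export
gen_gaussian <- function(N, d, D = d, seed = NULL) {
  with_seed(seed, {
    X <- matrix(stats::rnorm(N * d), N, d)
    linear_embed(X, D)
  })
}

#' @rdname generators
#' @export
gen_hypercube <- function(N, d, D = d, seed = NULL) {
  with_seed(seed, {
    X <- matrix(stats::runif(N * d), N, d)
    linear_embed(X, D)
  })
}

#' @rdname generators
#' @export
gen_curved <- function(N, d, seed = NULL) {
  if (d < 2) stop("curved family needs d >= 2", call. = FALSE)
  X <- with_seed(seed, matrix(stats::runif(N * d, 0, 2 * pi), N, d))
  out <- matrix(0, N, 2 * d)
  for (i in seq_len(d)) {
    nxt <- if (i == d) 1L else i + 1L
    out[, 2 * i - 1] <- X[, nxt] * cos(X[, i])
    out[, 2 * i]     <- X[, nxt] * sin(X[, i])
  }
  out
}

#' @rdname generators
#' @export
gen_swiss_roll <- function(N, seed = NULL) {
  U <- with_seed(seed, matrix(stats::runif(2 * N), N, 2))
  x <- U[, 1]; y <- U[, 2]
  cbind(x * cos(2 * pi * y), y, x * sin(2 * pi * y))
}

#' @rdname generators
#' @export
gen_two_cubes <- function(N1, N2, d1, d2, D, seed = NULL) {
  with_seed(seed, {
    # Center each cube pre-embedding so both components sit at the origin
    # and therefore intersect.
    A <- linear_embed(matrix(stats::runif(N1 * d1) - 0.5, N1, d1), D)
    B <- linear_embed(matrix(stats::runif(N2 * d2) - 0.5, N2, d2), D)
    out <- rbind(A, B)
    attr(out, "component") <- rep(c(1L, 2L), c(N1, N2))
    out
  })
}

#' Add isotropic Gaussian noise to a sample matrix
#'
#' Adds i.i.d. centered Gaussian noise of standard deviation `sigma` to
#' every ambient coordinate. Used to probe the noise robustness of the
#' estimator: weak noise leaves the ID estimate at the manifold dimension,
#' strong noise drives it to the ambient dimension.
#'
#' @param X Numeric sample matrix.
#' @param sigma Noise standard deviation (0 returns `X` unchanged).
#' @param seed Integer seed.
#' @return Matrix of the same shape as `X`.
#' @export
add_noise <- function(X, sigma, seed = NULL) {
  X <- as.matrix(X)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(X)
  X + with_seed(seed, matrix(stats::rnorm(length(X), sd = sigma),
                             nrow(X), ncol(X)))
}

#' Render one high-contrast elliptic blob bitmap
#'
#' Produces an `l` x `l` grayscale image of one elliptic blob with five
#' degrees of freedom: translations `dx`, `dy`, size `s`, eccentricity `e`,
#' and major-axis angle `theta`. On the centered pixel lattice
#' \eqn{i, j \in \{-(l-1)/2, \dots, (l-1)/2\}} the pixel value is
#' \deqn{a = \cos\theta\,(j - dx) + \sin\theta\,(i + dy),\quad
#'       b = -\sin\theta\,(j - dx) + \cos\theta\,(i + dy),}
#' \deqn{v = 1 - \sqrt{(a^2 + e^2 b^2) / ((1 + e^2) s^2)},}
#' and every pixel below 0.01 (including all negative values) is set to 0,
#' giving a high-contrast image. The lattice must be centered (odd `l`):
#' with translations up to 20 pixels and sizes up to 3, a corner-origin
#' lattice would push blobs off the bitmap.
#'
#' @param l Odd bitmap side length (pixels).
#' @param dx,dy Horizontal/vertical translation (pixels).
#' @param s Size (> 0).
#' @param e Eccentricity (> 0).
#' @param theta Major-axis angle (radians).
#' @return `l` x `l` numeric matrix with values in \[0, 1\]; rows index the
#'   vertical coordinate i, columns the horizontal coordinate j.
#' @export
render_blob <- function(l = 81L, dx = 0, dy = 0, s = 1, e = 5, theta = 0) {
  if (l < 3 || l %% 2 == 0) stop("bitmap side l must be odd and >= 3", call. = FALSE)
  if (s <= 0 || e <= 0) stop("size s and eccentricity e must be > 0", call. = FALSE)
  half <- (l - 1) / 2
  coords <- seq(-half, half)
  jj <- matrix(coords, l, l, byrow = TRUE)  # horizontal pixel coordinate j
  ii <- matrix(coords, l, l)                # vertical pixel coordinate i
  a <- cos(theta) * (jj - dx) + sin(theta) * (ii + dy)
  b <- -sin(theta) * (jj - dx) + cos(theta) * (ii + dy)
  v <- 1 - sqrt((a^2 + e^2 * b^2) / ((1 + e^2) * s^2))
  v[v < 0.01] <- 0
  v
}

#' Generate a dataset of multi-blob bitmap images
#'
#' Each sample is the sum of `n_blobs` independent blob images
#' ([render_blob()]) with parameters drawn uniformly from fixed ranges
#' (`dx, dy ~ U(-20, 20)`, `s ~ U(1, 3)`, `e ~ U(5, 10)`,
#' `theta ~ U(-pi/2, pi/2)`), flattened row-major to a vector of `l^2`
#' pixels. With 5 degrees of freedom per blob the dataset is a (highly
#' curved) `5 * n_blobs`-dimensional manifold of images — a synthetic proxy
#' for the transformation manifolds of high-contrast images arising in
#' invariant object recognition.
#'
#' @param N Number of images.
#' @param n_blobs Blobs per image (intrinsic dimension `5 * n_blobs`).
#' @param l Odd bitmap side length; the default 81 gives 6561 pixels.
#' @param seed Integer seed.
#' @return N x `l^2` matrix; attribute `blob_params` holds the N x
#'   `(5 n_blobs)` matrix of drawn parameters.
#' @export
gen_blob_images <- function(N, n_blobs = 1L, l = 81L, seed = NULL) {
  with_seed(seed, {
    pars <- matrix(0, N, 5 * n_blobs)
    out <- matrix(0, N, l * l)
    for (mu in seq_len(N)) {
      img <- matrix(0, l, l)
      for (b in seq_len(n_blobs)) {
        p <- c(dx = stats::runif(1, -20, 20), dy = stats::runif(1, -20, 20),
               s = stats::runif(1, 1, 3), e = stats::runif(1, 5, 10),
               theta = stats::runif(1, -pi / 2, pi / 2))
        pars[mu, (5 * b - 4):(5 * b)] <- p
        img <- img + render_blob(l, p[1], p[2], p[3], p[4], p[5])
      }
      out[mu, ] <- as.vector(t(img))  # row-major flattening
    }
    attr(out, "blob_params") <- pars
    out
  })
}
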