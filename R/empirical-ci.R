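#' Empirical correlation integral (pairwise-distance CDF)
#'
#' Computes the empirical density of neighbours of a sample matrix: all
#' \eqn{M = N(N-1)/2} unordered pairwise Euclidean distances, sorted
#' ascending, with the k-th smallest distance carrying cumulative value
#' \eqn{(k-1)/M}.
#'
#' The \eqn{(k-1)/M} convention (the CDF is left-continuous: the smallest
#' distance has value 0, and no point reaches 1) is deliberate and is the
#' default everywhere in this package; set `convention = "k_over_m"` for the
#' textbook right-continuous \eqn{k/M} variant. Ties among distances are kept
#' in stable sort order and assigned cumulative values by sort rank.
#'
#' @param X Numeric matrix, rows = samples, columns = features; at least 2
#'   rows, finite entries.
#' @param convention `"k_minus_1_over_m"` (default) or `"k_over_m"`.
#' @return An object of class `fci_ecdf`: a list with `radii` (ascending
#'   distances), `cdf` (cumulative fractions), and `n_pairs`.
#' @examples
#' e <- empirical_cdf(matrix(c(0, 1, 2), ncol = 1))
#' cbind(e$radii, e$cdf) # distances 1, 1, 2 with values 0, 1/3, 2/3
#' @export
empirical_cdf <- function(X, convention = c("k_minus_1_over_m", "k_over_m")) {
  convention <- match.arg(convention)
  X <- check_sample_matrix(X, min_rows = 2L)
  radii <- sort(pair_distances(X), method = "radix")
  M <- length(radii)
  k <- seq_len(M)
  cdf <- if (convention == "k_minus_1_over_m") (k - 1) / M else k / M
  new_fci_ecdf(radii, cdf)
}

new_fci_ecdf <- function(radii, cdf) {
  structure(list(radii = radii, cdf = cdf, n_pairs = length(radii)),
            class = "fci_ecdf")
}

#' @export
print.fci_ecdf <- function(x, ...) {
  cat(sprintf("Empirical correlation integral: %d pair distances in [%.4g, %.4g]\n",
              x$n_pairs, min(x$radii), max(x$radii)))
  invisible(x)
}

#' Subsample an empirical correlation integral
#'
#' Keeps a uniform random subset of at most `max_points` (radius, cdf) points
#' (without replacement, ascending order preserved). Used before nonlinear
#' fitting to bound the cost of the regression; the default 1000 points is
#' ample for a two-parameter fit.
#'
#' @param ecdf An `fci_ecdf` object.
#' @param max_points Maximum number of points to keep (>= 2).
#' @param seed Integer seed making the subsample reproducible; `NULL` uses
#'   the current RNG stream.
#' @return An `fci_ecdf` with `min(max_points, n_pairs)` points.
#' @export
subsample_cdf <- function(ecdf, max_points = 1000L, seed = NULL) {
  stopifnot(inherits(ecdf, "fci_ecdf"))
  if (max_points < 2) stop("max_points must be >= 2", call. = FALSE)
  M <- ecdf$n_pairs
  if (M <= max_points) return(ecdf)
  idx <- with_seed(seed, sort(sample.int(M, max_points)))
  new_fci_ecdf(ecdf$radii[idx], ecdf$cdf[idx])
}

#' Correlation-dimension (Grassberger-Procaccia) baseline estimate
#'
#' Classical geometric ID estimator: the correlation integral scales as
#' \eqn{\rho(r) \sim r^d} for small r, so the slope of \eqn{\log\rho} versus
#' \eqn{\log r} over the small-radius regime estimates the dimension. Included
#' as the in-package baseline; it is accurate for low dimension (d of order
#' 10 or less) but systematically underestimates for larger d, where the
#' small-radius region of the pair-distance distribution is undersampled.
#'
#' @param X Numeric sample matrix (rows = samples).
#' @param cdf_ceiling Upper bound on the cumulative fraction defining the
#'   "small radius" fitting window (default 0.1).
#' @param min_points Minimum number of CDF points required inside the window.
#' @return The fitted slope, a scalar dimension estimate.
#' @examples
#' X <- matrix(runif(400), ncol = 2)   # uniform unit square
#' corr_dim(X)                          # close to 2
#' @export
corr_dim <- function(X, cdf_ceiling = 0.1, min_points = 10L) {
  ecdf <- empirical_cdf(X)
  keep <- ecdf$cdf > 0 & ecdf$cdf <= cdf_ceiling & ecdf$radii > 0
  if (sum(keep) < min_points) {
    stop(sprintf(paste0("only %d pair distances with 0 < cdf <= %g; ",
                        "increase cdf_ceiling or provide more samples"),
                 sum(keep), cdf_ceiling), call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, log(ecdf$radii[keep])), log(ecdf$cdf[keep]))
  unname(fit$coefficients[2])
}
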