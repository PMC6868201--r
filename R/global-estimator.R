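#' Center and project samples onto the unit sphere
#'
#' First step of the full-correlation-integral (FCI) estimation protocol:
#' subtract the center of mass \eqn{b = N^{-1}\sum_\mu x^\mu} from every
#' sample, then rescale each sample to unit Euclidean norm. For data drawn
#' from a rotationally invariant distribution on a d-dimensional linear
#' subspace, the result is (approximately) uniform on the unit sphere
#' \eqn{S^{d-1}}, which is exactly the regime the analytic model [fci_cdf()]
#' describes. The normalization removes the radial degree of freedom, which
#' is why [estimate_id()] adds one to the fitted sphere dimension.
#'
#' @param X Numeric sample matrix (rows = samples), at least 3 rows.
#' @param zero_tol Rows whose post-centering norm is at most this value
#'   cannot be projected and are dropped with a warning.
#' @return The projected matrix with an attribute `n_dropped` counting
#'   removed rows.
#' @export
preprocess <- function(X, zero_tol = 1e-12) {
  X <- check_sample_matrix(X, min_rows = 3L)
  X <- sweep(X, 2L, colMeans(X), "-")
  norms <- sqrt(rowSums(X * X))
  keep <- norms > zero_tol
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warning(sprintf("dropped %d sample(s) with vanishing norm after centering",
                    n_dropped), call. = FALSE)
  }
  if (!any(keep)) {
    stop("degenerate data: all samples coincide with the center of mass",
         call. = FALSE)
  }
  out <- X[keep, , drop = FALSE] / norms[keep]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Fit the hypersphere chord-length model to an empirical CDF
#'
#' Second step of the FCI protocol: unweighted least-squares fit of
#' \eqn{\bar\rho(r / r_s; m)} (see [fci_cdf()]) to an empirical
#' pair-distance CDF, with the sphere dimension m and the sphere radius
#' \eqn{r_s} as free continuous parameters.
#'
#' Initialization exploits \eqn{\bar\rho(\sqrt2) = 1/2}: the starting scale
#' is the median pair distance divided by \eqn{\sqrt2}; the starting
#' dimension is the best integer on a grid (1 to `min(m_max, 200)`, extended
#' geometrically beyond 200 when `m_max` allows) at that scale. Both
#' parameters are then refined jointly by bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]).
#'
#' @param ecdf An `fci_ecdf` object (typically already reduced by
#'   [subsample_cdf()]).
#' @param m_bounds Length-2 vector: lower and upper bounds for the sphere
#'   dimension m (lower bound at least 1).
#' @return An object of class `fci_fit`: list with `m_hat`, `r_s_hat`, `sse`
#'   (sum of squared residuals), `n_points`, and optimizer diagnostics.
#' @export
fit_fci <- function(ecdf, m_bounds = c(1, 200)) {
  stopifnot(inherits(ecdf, "fci_ecdf"))
  r <- ecdf$radii
  y <- ecdf$cdf
  if (length(r) < 2) stop("need at least 2 CDF points to fit", call. = FALSE)
  if (max(r) - min(r) <= 0) {
    stop("degenerate empirical CDF: all pair distances equal", call. = FALSE)
  }
  if (m_bounds[1] < 1 || m_bounds[2] < m_bounds[1]) {
    stop("m_bounds must satisfy 1 <= lower <= upper", call. = FALSE)
  }

  r_s0 <- stats::median(r) / sqrt(2)
  if (r_s0 <= 0) r_s0 <- max(r) / 2

  # Integer grid scan for the starting dimension at the fixed initial scale.
  m_hi <- m_bounds[2]
  grid <- seq(max(1, ceiling(m_bounds[1])), min(floor(m_hi), 200))
  if (m_hi > 200) {
    ext <- unique(round(200 * 1.1^seq_len(60)))
    grid <- c(grid, ext[ext <= m_hi])
  }
  grid <- grid[grid >= m_bounds[1] & grid <= m_hi]
  if (length(grid) == 0) grid <- mean(m_bounds)
  sse_grid <- vapply(grid, function(m) {
    sum((fci_model_curve(r, r_s0, m) - y)^2)
  }, numeric(1))
  m0 <- grid[which.min(sse_grid)]

  fit <- minpack.lm::nls.lm(
    par = c(m = m0, r_s = r_s0),
    lower = c(m_bounds[1], 1e-12),
    upper = c(m_bounds[2], Inf),
    fn = function(p) fci_model_curve(r, p[2], p[1]) - y,
    control = minpack.lm::nls.lm.control(maxiter = 400)
  )
  if (fit$info < 1 || fit$info > 4) {
    stop(sprintf(paste0("FCI fit did not converge (%s); best grid point: ",
                        "m = %d, sse = %.4g"),
                 fit$message, m0, min(sse_grid)), call. = FALSE)
  }
  structure(list(
    m_hat = unname(fit$par["m"]),
    r_s_hat = unname(fit$par["r_s"]),
    sse = sum(fit$fvec^2),
    n_points = length(r),
    m_init = m0,
    niter = fit$niter,
    message = fit$message
  ), class = "fci_fit")
}

#' @export
print.fci_fit <- function(x, ...) {
  cat(sprintf("FCI fit: m = %.4f, r_s = %.4f (sse %.4g over %d points)\n",
              x$m_hat, x$r_s_hat, x$sse, x$n_points))
  invisible(x)
}

#' Estimate the intrinsic dimension of a dataset (global FCI estimator)
#'
#' Full pipeline of the FCI intrinsic-dimension estimator:
#' center and project the samples onto the unit sphere ([preprocess()]),
#' compute the empirical pair-distance CDF ([empirical_cdf()]), subsample it
#' ([subsample_cdf()]), fit the hypersphere chord-length model
#' ([fit_fci()]), and report \eqn{\hat d = \hat m + 1} — the +1 restores the
#' radial degree of freedom removed by the projection. The estimate uses the
#' whole sigmoidal shape of the correlation integral rather than its
#' small-radius tail, so it remains reliable even when N < d (a regime where
#' slope-based estimators such as [corr_dim()] fail).
#'
#' Note the +1 is applied unconditionally: if the input already lies on a
#' sphere centered at its center of mass, the returned `d_est` is the
#' sphere's dimension plus one (the dimension of the ball it bounds).
#'
#' @param X Numeric sample matrix (rows = samples, columns = features).
#' @param seed Integer seed controlling the CDF subsample; the pipeline is
#'   deterministic given `X` and `seed`.
#' @param max_cdf_points CDF points retained for the fit (default 1000).
#' @param m_max Upper bound for the fitted sphere dimension; defaults to
#'   `ncol(X) + 1`.
#' @param zero_tol Passed to [preprocess()].
#' @return An object of class `fci_id`: list with `d_est` (= `m_hat + 1`),
#'   `d_est_rounded`, `fit` (the `fci_fit`), `n_samples_used`, `n_dropped`.
#' @examples
#' X <- gen_hypercube(500, d = 5, D = 10, seed = 1)
#' estimate_id(X, seed = 1)   # d_est close to 5
#' @export
estimate_id <- function(X, seed = NULL, max_cdf_points = 1000L,
                        m_max = NULL, zero_tol = 1e-12) {
  X <- check_sample_matrix(X, min_rows = 3L)
  if (is.null(m_max)) m_max <- ncol(X) + 1
  P <- preprocess(X, zero_tol = zero_tol)
  ecdf <- empirical_cdf(P)
  ecdf <- subsample_cdf(ecdf, max_points = max_cdf_points, seed = seed)
  fit <- fit_fci(ecdf, m_bounds = c(1, m_max))
  structure(list(
    d_est = fit$m_hat + 1,
    d_est_rounded = as.integer(round(fit$m_hat + 1)),
    fit = fit,
    n_samples_used = nrow(P),
    n_dropped = attr(P, "n_dropped"),
    seed = seed
  ), class = "fci_id")
}

#' @export
print.fci_id <- function(x, ...) {
  cat(sprintf("FCI intrinsic dimension estimate: d = %.3f (rounded: %d)\n",
              x$d_est, x$d_est_rounded))
  cat(sprintf("  m_hat = %.3f, r_s_hat = %.3f, sse = %.4g, samples used = %d\n",
              x$fit$m_hat, x$fit$r_s_hat, x$fit$sse, x$n_samples_used))
  invisible(x)
}
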