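#' Neighborhood of one sample within a cutoff radius
#'
#' Rows of `X` at Euclidean distance strictly less than `r_c` from the
#' sample at `center_index`. The center itself is excluded: including it
#' would bias the neighborhood's center of mass toward the center point
#' during the subsequent projection step.
#'
#' @param X Numeric sample matrix.
#' @param center_index Row index of the neighborhood center.
#' @param r_c Positive cutoff radius.
#' @return Matrix of neighborhood rows (possibly 0 rows).
#' @export
local_subset <- function(X, center_index, r_c) {
  X <- check_sample_matrix(X, min_rows = 2L)
  if (center_index < 1 || center_index > nrow(X)) {
    stop("center_index out of range", call. = FALSE)
  }
  d <- dist_to_row(X, center_index)
  keep <- d < r_c
  keep[center_index] <- FALSE
  X[keep, , drop = FALSE]
}

#' Local intrinsic-dimension curve across scales for one center
#'
#' Runs the global FCI estimator ([estimate_id()]) on the neighborhood of a
#' chosen center at each scale of a grid, yielding the local ID estimate
#' \eqn{d_{x_0}(r_c)} as a function of the cutoff radius (or, equivalently,
#' of the neighbor count). Scales whose neighborhoods hold fewer than
#' `n_min` points are recorded with `d_est = NA`: with so few neighbors the
#' local estimate is unreliable. At the largest scale the neighborhood is
#' the whole dataset and the local estimate converges to the global one.
#'
#' The default radius grid has 24 geometric steps from the `n_min`-th
#' nearest-neighbor distance of the center up to just beyond its farthest
#' neighbor; the default neighbor-count grid is geometric between `n_min`
#' and N - 1. Neighborhoods larger than `max_points` samples are randomly
#' thinned (seeded) before estimation — the FCI estimator is accurate from a
#' few hundred samples even at large dimension, so this caps the cost of the
#' scan without degrading the curve.
#'
#' @param X Numeric sample matrix.
#' @param center_index Row index of the scan center.
#' @param scales Numeric vector of scales: cutoff radii (`type = "radius"`)
#'   or neighbor counts (`type = "knn"`). `NULL` uses the default grid.
#' @param type `"radius"` or `"knn"` parameterization of the scan.
#' @param n_min Validity floor: minimum neighbors for a defined estimate.
#' @param n_scales Number of grid points when `scales` is `NULL`.
#' @param max_points Cap on neighborhood samples used per local fit.
#' @param seed Integer seed (thinning and CDF subsampling).
#' @return An object of class `fci_mscurve`: data frame with columns
#'   `scale`, `n` (neighbors), `d_est` (NA below the validity floor), plus
#'   attributes `center_index`, `type`, `n_min`.
#' @export
multiscale_curve <- function(X, center_index, scales = NULL,
                             type = c("radius", "knn"), n_min = 20L,
                             n_scales = 24L, max_points = 500L, seed = NULL) {
  type <- match.arg(type)
  X <- check_sample_matrix(X, min_rows = 3L)
  N <- nrow(X)
  if (center_index < 1 || center_index > N) {
    stop("center_index out of range", call. = FALSE)
  }
  d <- dist_to_row(X, center_index)
  d_others <- sort(d[-center_index])

  if (is.null(scales)) {
    scales <- if (type == "radius") {
      lo <- d_others[min(n_min, length(d_others))]
      hi <- max(d_others) * 1.0001
      if (lo <= 0) lo <- min(d_others[d_others > 0], hi / 100)
      exp(seq(log(lo), log(hi), length.out = n_scales))
    } else {
      unique(round(exp(seq(log(n_min), log(N - 1), length.out = n_scales))))
    }
  }
  if (length(scales) == 0) stop("empty scale grid", call. = FALSE)
  scales <- sort(scales)

  rows <- lapply(seq_along(scales), function(i) {
    s <- scales[i]
    if (type == "radius") {
      keep <- which(d < s)
      keep <- keep[keep != center_index]
    } else {
      k <- min(as.integer(s), N - 1)
      ord <- order(d)
      ord <- ord[ord != center_index]
      keep <- ord[seq_len(k)]
    }
    n <- length(keep)
    d_est <- NA_real_
    if (n >= max(n_min, 3)) {
      sub_seed <- derive_seed(seed, i)
      if (n > max_points) {
        keep <- with_seed(derive_seed(seed, 1000L + i),
                          keep[sort(sample.int(n, max_points))])
      }
      est <- tryCatch(
        estimate_id(X[keep, , drop = FALSE], seed = sub_seed),
        error = function(e) NULL)
      if (!is.null(est)) d_est <- est$d_est
    }
    data.frame(scale = s, n = n, d_est = d_est)
  })
  out <- do.call(rbind, rows)
  structure(out, center_index = center_index, type = type, n_min = n_min,
            class = c("fci_mscurve", "data.frame"))
}

#' Multiscale FCI analysis over several centers
#'
#' Driver for the multiscale estimator: draws `n_centers` random centers
#' (or takes explicit `centers`), computes one [multiscale_curve()] per
#' center, and summarizes the family with the minimum valid local estimate
#' ([minimum_plateau_estimate()]) and the plateau modes ([plateau_modes()]).
#'
#' @param X Numeric sample matrix.
#' @param n_centers Number of random centers when `centers` is `NULL`.
#' @param centers Optional integer vector of explicit center row indices.
#' @param seed Integer seed; governs the center draw and every downstream
#'   stochastic stage.
#' @param ... Passed to [multiscale_curve()] (`type`, `n_min`, `scales`,
#'   `n_scales`, `max_points`).
#' @return Object of class `fci_multiscale`: list with `curves`,
#'   `minimum` (minimum valid local ID), `modes` (plateau modes), `centers`.
#' @examples
#' X <- gen_swiss_roll(1000, seed = 1)
#' ms <- multiscale_id(X, n_centers = 4, seed = 1)
#' round(ms$minimum)  # 2: the roll is a surface
#' @export
multiscale_id <- function(X, n_centers = 10L, centers = NULL, seed = NULL, ...) {
  X <- check_sample_matrix(X, min_rows = 3L)
  if (is.null(centers)) {
    centers <- with_seed(derive_seed(seed, 0L),
                         sample.int(nrow(X), min(n_centers, nrow(X))))
  }
  curves <- lapply(seq_along(centers), function(j) {
    multiscale_curve(X, centers[j], seed = derive_seed(seed, j * 10000L), ...)
  })
  minimum <- tryCatch(minimum_plateau_estimate(curves), error = function(e) NA_real_)
  structure(list(
    curves = curves,
    minimum = minimum,
    modes = plateau_modes(curves),
    centers = centers,
    seed = seed
  ), class = "fci_multiscale")
}

#' @export
print.fci_multiscale <- function(x, ...) {
  cat(sprintf("Multiscale FCI analysis over %d centers\n", length(x$curves)))
  cat(sprintf("  minimum valid local ID: %.3f (rounded: %d)\n",
              x$minimum, as.integer(round(x$minimum))))
  if (length(x$modes)) {
    cat("  plateau modes:", paste(sprintf("%.2f", x$modes), collapse = ", "), "\n")
  } else {
    cat("  plateau modes: none detected\n")
  }
  invisible(x)
}

#' Minimum valid local estimate across multiscale curves
#'
#' The headline multiscale heuristic: local estimates at centers in curved
#' regions overshoot toward the embedding dimension, while flat regions
#' plateau at the true ID, so the minimum defined local estimate over all
#' centers and valid scales estimates the manifold dimension.
#'
#' @param curves A list of `fci_mscurve` objects (or one such object).
#' @return Scalar: the minimum defined local ID.
#' @export
minimum_plateau_estimate <- function(curves) {
  vals <- valid_estimates(curves)
  if (length(vals) == 0) {
    stop(paste("no valid local estimate: use a denser scale grid,",
               "more samples, or a smaller n_min"), call. = FALSE)
  }
  min(vals)
}

valid_estimates <- function(curves) {
  if (inherits(curves, "fci_mscurve")) curves <- list(curves)
  unlist(lapply(curves, function(cv) cv$d_est[!is.na(cv$d_est)]))
}

#' Plateau modes of a family of multiscale curves
#'
#' Detects, per curve, maximal runs of at least `min_run` consecutive valid
#' scales whose local estimates vary by at most `flatness_tol` (relative
#' spread), then pools the estimates belonging to those flat runs across all
#' centers and reads off the modes of their distribution: local maxima of a
#' kernel density on the log scale (bandwidth `flatness_tol / 2`), keeping
#' maxima supported by at least `min_run` pooled points within
#' `flatness_tol` of the mode. Pooling run points rather than whole curves
#' means slowly drifting curve sections contribute little mass, while true
#' plateaux — where many scales and centers agree — pile up into peaks.
#' Multiple modes reveal multidimensional data, e.g. the union of two
#' manifolds of different dimension yields one plateau per component.
#'
#' @param curves A list of `fci_mscurve` objects (or one such object).
#' @param flatness_tol Relative spread tolerated within a plateau (default
#'   0.1, i.e. 10%).
#' @param min_run Minimum number of consecutive scales in a plateau.
#' @return Numeric vector of plateau modes (possibly empty), ascending.
#' @export
plateau_modes <- function(curves, flatness_tol = 0.1, min_run = 3L) {
  if (inherits(curves, "fci_mscurve")) curves <- list(curves)
  if (length(curves) == 0) stop("no curves supplied", call. = FALSE)
  pool <- unlist(lapply(curves, function(cv) {
    run_points(cv$d_est, flatness_tol, min_run)
  }))
  if (length(pool) == 0) return(numeric(0))
  # Degenerate pool (essentially one value): a single mode.
  if (max(pool) / min(pool) - 1 < flatness_tol / 4) {
    return(stats::median(pool))
  }
  dens <- stats::density(log(pool), bw = flatness_tol / 2)
  y <- dens$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (y[1] > y[2]) peaks <- c(1L, peaks)
  ny <- length(y)
  if (y[ny] > y[ny - 1]) peaks <- c(peaks, ny)
  modes <- exp(dens$x[peaks])
  support <- vapply(modes, function(m) {
    sum(abs(pool / m - 1) <= flatness_tol)
  }, numeric(1))
  sort(modes[support >= min_run])
}

# Estimates belonging to maximal flat runs of one curve: greedy
# left-to-right scan over the valid (non-NA) stretches; a window is flat
# while (max - min) / median <= tol. Runs shorter than min_run are dropped.
run_points <- function(d_est, tol, min_run) {
  out <- numeric(0)
  n <- length(d_est)
  i <- 1L
  while (i <= n) {
    if (is.na(d_est[i])) { i <- i + 1L; next }
    j <- i
    lo <- hi <- d_est[i]
    while (j < n && !is.na(d_est[j + 1L])) {
      lo2 <- min(lo, d_est[j + 1L]); hi2 <- max(hi, d_est[j + 1L])
      if ((hi2 - lo2) / stats::median(d_est[i:(j + 1L)]) > tol) break
      lo <- lo2; hi <- hi2; j <- j + 1L
    }
    if (j - i + 1L >= min_run) out <- c(out, d_est[i:j])
    i <- j + 1L
  }
  out
}
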