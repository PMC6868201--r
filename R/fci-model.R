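#' Total solid angle of the unit m-sphere
#'
#' Surface measure of the unit sphere \eqn{S^m \subset R^{m+1}}:
#' \eqn{\Omega_m = 2 \pi^{(m+1)/2} / \Gamma((m+1)/2)}. Evaluated through
#' log-gamma so that very large dimensions (m ~ 1000) neither overflow nor
#' lose precision.
#'
#' @param m Sphere dimension, integer-valued and \eqn{\ge 0} (vectorized).
#'   `m = 0` gives 2 (two points), `m = 1` gives \eqn{2\pi} (circle
#'   circumference), `m = 2` gives \eqn{4\pi} (sphere area).
#' @return Positive numeric vector of solid angles.
#' @examples
#' total_solid_angle(0:2) # 2, 2*pi, 4*pi
#' @export
total_solid_angle <- function(m) {
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("sphere dimension m must be >= 0", call. = FALSE)
  }
  exp(log(2) + (m + 1) / 2 * log(pi) - lgamma((m + 1) / 2))
}

#' Chord-length CDF of the uniform unit m-sphere (full correlation integral)
#'
#' Cumulative fraction of point pairs, both drawn uniformly from the unit
#' m-sphere, whose Euclidean (chord) distance is at most `rbar`. This is the
#' average full correlation integral of spherical data and the nonlinear
#' model fitted by [estimate_id()].
#'
#' Analytically, with \eqn{t = (\bar r^2 - 2)/2},
#' \deqn{\bar\rho(\bar r) = 1/2 + \frac{\Omega_{m-1}}{2\,\Omega_m}
#'   (\bar r^2 - 2)\; {}_2F_1\!\left(1/2,\ 1 - m/2;\ 3/2;\ t^2\right).}
#' Note the hypergeometric argument \eqn{t^2 = ((\bar r^2-2)/2)^2}: only this
#' normalization satisfies the boundary conditions \eqn{\bar\rho(0)=0},
#' \eqn{\bar\rho(2)=1} and agrees with the defining integral (see
#' [fci_cdf_oracle()]); the variant with argument \eqn{(\bar r^2-2)^2} does
#' not. Internally the series is evaluated exactly through Euler's integral
#' identity \eqn{t\,{}_2F_1(1/2, 1-m/2; 3/2; t^2) = \int_0^t (1-u^2)^{m/2-1}
#' du}, i.e. a regularized incomplete beta function:
#' \deqn{\bar\rho(\bar r) = 1/2 + \mathrm{sign}(t)\, I_{t^2}(1/2,\ m/2)/2,}
#' which is numerically stable for any real \eqn{m \ge 1}, including very
#' large m.
#'
#' @param rbar Dimensionless chord radius in \[0, 2\] (distance divided by the
#'   sphere radius). Values straying outside by at most `1e-9` (floating-point
#'   noise) are clamped; larger excursions are an error.
#' @param m Sphere dimension, real \eqn{\ge 1}; need not be an integer (the
#'   fitting protocol treats it as continuous).
#' @return Numeric vector of CDF values in \[0, 1\]. `fci_cdf(sqrt(2), m)` is
#'   exactly 1/2 for every m.
#' @seealso [fci_cdf_oracle()] for the independent quadrature evaluation,
#'   [fit_fci()] for the regression that uses this model.
#' @examples
#' fci_cdf(1, 2)      # 0.25: on S^2 the squared chord length is uniform
#' fci_cdf(sqrt(2), 7) # exactly 0.5 regardless of m
#' @export
fci_cdf <- function(rbar, m) {
  if (length(m) != 1 || !is.finite(m) || m < 1) {
    stop("model dimension m must be a single real >= 1", call. = FALSE)
  }
  rbar <- clamp_rbar(rbar)
  t <- (rbar^2 - 2) / 2
  # snap float noise at the midpoint so rho(sqrt(2)) is exactly 1/2
  # (the induced error is O(|t|), far below evaluation accuracy)
  t[abs(t) < 1e-12] <- 0
  0.5 + sign(t) * stats::pbeta(t^2, 0.5, m / 2) / 2
}

# Clamp policy: |excess| <= 1e-9 outside [0, 2] is floating-point noise and is
# clamped; anything larger indicates a caller bug.
clamp_rbar <- function(rbar, tol = 1e-9) {
  if (any(!is.finite(rbar))) stop("rbar must be finite", call. = FALSE)
  if (any(rbar < -tol | rbar > 2 + tol)) {
    stop("rbar outside [0, 2] beyond floating-point tolerance", call. = FALSE)
  }
  pmin(pmax(rbar, 0), 2)
}

# Model CDF with radius saturation, used inside the nonlinear fit where the
# scale parameter r_s is free: distances beyond the sphere diameter 2*r_s
# have model value exactly 1 (and the model is 0 at 0).
fci_model_curve <- function(r, r_s, m) {
  fci_cdf(pmin(pmax(r / r_s, 0), 2), m)
}

#' Quadrature oracle for the sphere chord-length CDF
#'
#' Evaluates the defining integral of the uniform-sphere chord CDF,
#' \deqn{\bar\rho(\bar r) = \frac{\Omega_{m-1}}{\Omega_m}
#'   \int_0^{\arccos(1 - \bar r^2/2)} \sin^{m-1}\beta \, d\beta,}
#' by adaptive numerical quadrature. This form is the unambiguous ground
#' truth against which the closed-form [fci_cdf()] is validated; it is slower
#' and only supports integer m.
#'
#' @param rbar Dimensionless chord radius in \[0, 2\] (scalar or vector).
#' @param m Integer sphere dimension \eqn{\ge 1}.
#' @param rel_tol Relative tolerance passed to [stats::integrate()].
#' @return Numeric vector of CDF values in \[0, 1\].
#' @export
fci_cdf_oracle <- function(rbar, m, rel_tol = 1e-12) {
  if (length(m) != 1 || !is.finite(m) || m < 1 || m != round(m)) {
    stop("oracle requires a single integer m >= 1", call. = FALSE)
  }
  rbar <- clamp_rbar(rbar)
  norm <- total_solid_angle(m - 1) / total_solid_angle(m)
  vapply(rbar, function(rb) {
    phi <- acos(1 - rb^2 / 2)
    if (phi == 0) return(0)
    q <- stats::integrate(function(b) sin(b)^(m - 1), 0, phi,
                          rel.tol = rel_tol, subdivisions = 500L)
    if (q$message != "OK") {
      stop("quadrature failed: ", q$message, " (rbar = ", rb, ", m = ", m, ")",
           call. = FALSE)
    }
    min(norm * q$value, 1)
  }, numeric(1))
}
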