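# Shared fixtures built in code.

# Uniform sample from the unit m-sphere in R^(m+1): normalized Gaussians.
sample_sphere <- function(N, m, seed = NULL) {
  G <- fcidim:::with_seed(seed, matrix(stats::rnorm(N * (m + 1)), N, m + 1))
  G / sqrt(rowSums(G * G))
}

# Exact model curve tabulated as an fci_ecdf, for self-fit tests.
model_ecdf <- function(m, r_s = 1, n = 200) {
  r <- seq(0.01, 1.99, length.out = n) * r_s
  fcidim:::new_fci_ecdf(r, fci_cdf(r / r_s, m))
}

# Haar rotation for equivariance tests (independent of the package's
# internal generator: built from a fixed QR decomposition).
fixed_rotation <- function(D, seed) {
  M <- fcidim:::with_seed(seed, matrix(stats::rnorm(D * D), D, D))
  q <- qr.Q(qr(M))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Run the CLI quietly, returning its exit status.
capture_cli <- function(args) {
  status <- NULL
  out <- capture.output(
    suppressWarnings(suppressMessages(status <- run_cli(args))))
  status
}

# Bare multiscale curve object for plateau-detection unit tests.
fake_curve <- function(d_est) {
  structure(data.frame(scale = seq_along(d_est), n = seq_along(d_est),
                       d_est = d_est),
            center_index = 1L, type = "radius", n_min = 20L,
            class = c("fci_mscurve", "data.frame"))
}
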