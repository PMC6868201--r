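# Synthetic manifold generators: isometry, determinism, geometry.

test_that("linear embedding is an exact isometry", {
  X <- matrix(rnorm(50 * 4), 50, 4)
  for (D in c(4, 10, 40)) {
    Y <- linear_embed(X, D, seed = 1)
    expect_equal(dim(Y), c(50, D))
    d0 <- dist(X); d1 <- dist(Y)
    expect_lt(max(abs(d1 - d0) / pmax(d0, 1e-300)), 1e-10)
  }
  expect_equal(sqrt(sum(linear_embed(matrix(1), 7, seed = 2)^2)), 1,
               tolerance = 1e-12)
  expect_error(linear_embed(X, 3), "must be >=")
})

test_that("every generator is deterministic under a fixed seed", {
  gens <- list(
    function(s) gen_binary_cube(40, 6, 12, seed = s),
    function(s) gen_gaussian(40, 6, 12, seed = s),
    function(s) gen_hypercube(40, 6, 12, seed = s),
    function(s) gen_curved(40, 3, seed = s),
    function(s) gen_swiss_roll(40, seed = s),
    function(s) gen_two_cubes(20, 20, 3, 5, 8, seed = s),
    function(s) gen_blob_images(3, 1, seed = s),
    function(s) add_noise(matrix(0, 10, 4), 0.5, seed = s),
    function(s) linear_embed(matrix(seq_len(12), 4, 3), 6, seed = s)
  )
  for (g in gens) {
    expect_identical(g(7L), g(7L))
    expect_false(identical(g(7L), g(8L)))
  }
})

test_that("binary cube rows sit on embedded vertices", {
  X <- gen_binary_cube(100, 5, 20, seed = 11)
  expect_equal(dim(X), c(100, 20))
  # squared inter-vertex distances are integers (number of flipped bits)
  d2 <- as.vector(dist(X))^2
  expect_lt(max(abs(d2 - round(d2))), 1e-9)
  expect_true(all(round(d2) %in% 0:5))
})

test_that("gaussian and hypercube generators have the declared spread", {
  G <- gen_gaussian(4000, 6, 6, seed = 12)
  # rotation preserves total variance: sum of column variances ~ d
  expect_equal(sum(apply(G, 2, var)), 6, tolerance = 0.15)
  H <- gen_hypercube(1000, 4, 9, seed = 13)
  expect_equal(dim(H), c(1000, 9))
  # isometry bound: no pair can exceed the cube diagonal
  expect_lte(max(dist(H)), sqrt(4) + 1e-9)
})

test_that("curved family realizes the cyclic polar-pair map", {
  d <- 4
  X <- gen_curved(200, d, seed = 14)
  expect_equal(ncol(X), 2 * d)
  # each coordinate pair has squared norm equal to one angle squared,
  # and the multiset of pair norms is consistent across the cycle
  pair_norm <- sapply(seq_len(d), function(i) sqrt(X[, 2*i-1]^2 + X[, 2*i]^2))
  expect_true(all(pair_norm >= 0 & pair_norm <= 2 * pi + 1e-9))
  # row norm^2 = sum of all angles^2 (cos^2 + sin^2 collapses each pair)
  expect_equal(rowSums(X^2), rowSums(pair_norm^2), tolerance = 1e-10)
  # d = 2 printed pattern: (x2 cos x1, x2 sin x1, x1 cos x2, x1 sin x2)
  X2 <- gen_curved(50, 2, seed = 15)
  x1 <- sqrt(X2[, 3]^2 + X2[, 4]^2)   # pair 2 norm carries x1
  x2 <- sqrt(X2[, 1]^2 + X2[, 2]^2)   # pair 1 norm carries x2
  expect_equal(X2[, 1], x2 * cos(atan2(X2[, 2], X2[, 1])), tolerance = 1e-9)
  expect_equal(X2[, 3], x1 * cos(atan2(X2[, 4], X2[, 3])), tolerance = 1e-9)
})

test_that("swiss roll coordinates satisfy the rolled-surface identities", {
  X <- gen_swiss_roll(500, seed = 16)
  expect_equal(ncol(X), 3)
  expect_true(all(X[, 2] >= 0 & X[, 2] <= 1))
  r <- sqrt(X[, 1]^2 + X[, 3]^2)     # = x, the radial parameter
  expect_true(all(r >= 0 & r <= 1 + 1e-12))
  expect_equal(X[, 1], r * cos(2 * pi * X[, 2]), tolerance = 1e-9)
})

test_that("two-cube union stacks labeled, origin-centered components", {
  X <- gen_two_cubes(250, 350, 4, 7, 12, seed = 17)
  expect_equal(nrow(X), 600)
  comp <- attr(X, "component")
  expect_equal(as.vector(table(comp)), c(250, 350))
  # each component is centered near the ambient origin
  expect_lt(max(abs(colMeans(X[comp == 1, ]))), 0.05)
  expect_lt(max(abs(colMeans(X[comp == 2, ]))), 0.05)
  # each component alone recovers its own dimension
  expect_equal(estimate_id(X[comp == 1, ], seed = 1)$d_est_rounded, 4L)
  expect_equal(estimate_id(X[comp == 2, ], seed = 1)$d_est_rounded, 7L)
})

test_that("noise corruption has the declared amplitude", {
  X <- gen_hypercube(400, 3, 10, seed = 18)
  expect_identical(add_noise(X, 0), X)
  noisy <- add_noise(X, 0.25, seed = 18)
  expect_equal(sd(noisy - X), 0.25, tolerance = 0.02)
  expect_error(add_noise(X, -1), "sigma")
})

test_that("blob rendering matches the elliptic profile and threshold", {
  img <- render_blob(81, dx = 0, dy = 0, s = 2, e = 6, theta = 0.3)
  expect_equal(dim(img), c(81, 81))
  expect_true(all(img >= 0 & img <= 1))
  expect_equal(img[41, 41], 1)                   # lattice origin: a = b = 0
  expect_true(all(img[img != 0] >= 0.01))        # hard contrast threshold
  # pixels beyond the ellipse support are exactly zero
  expect_equal(img[1, 1], 0)
  # translation moves the peak accordingly: the maximum sits at the pixel
  # where (j - dx, i + dy) = (0, 0), i.e. column 41 + dx, row 41 - dy
  shifted <- render_blob(81, dx = 10, dy = -5, s = 2, e = 6, theta = 0)
  expect_equal(which(shifted == max(shifted), arr.ind = TRUE)[1, ],
               c(row = 41 + 5, col = 41 + 10))
  expect_error(render_blob(80), "odd")
  expect_error(render_blob(81, s = 0), "must be > 0")
})

test_that("blob image datasets flatten draws from the printed ranges", {
  B <- gen_blob_images(20, n_blobs = 2, seed = 19)
  expect_equal(dim(B), c(20, 81^2))
  expect_true(all(B >= 0))
  pars <- attr(B, "blob_params")
  expect_equal(dim(pars), c(20, 10))
  for (b in 0:1) {
    expect_true(all(abs(pars[, 5 * b + 1:2]) < 20))        # dx, dy
    expect_true(all(pars[, 5 * b + 3] > 1 & pars[, 5 * b + 3] < 3))  # s
    expect_true(all(pars[, 5 * b + 4] > 5 & pars[, 5 * b + 4] < 10)) # e
    expect_true(all(abs(pars[, 5 * b + 5]) < pi / 2))      # theta
  }
  # multi-blob images are sums of single-blob renders: peak can exceed 1
  expect_true(max(B) <= 2 + 1e-9)
})

test_that("global estimator recovers the dimension of every flat family", {
  # median over seeds: single draws at d = 40 sit within ~1.5% of d, which
  # can fall on either side of the rounding boundary
  median_d <- function(gen, d) {
    median(vapply(1:5, function(s) {
      estimate_id(gen(500, d, 60, seed = 20 * d + s), seed = s)$d_est
    }, numeric(1)))
  }
  for (d in c(5, 15, 40)) {
    expect_equal(round(median_d(gen_hypercube, d)), d)
    expect_equal(round(median_d(gen_gaussian, d)), d)
    # the binary cube is the strongly non-uniform family (vertex sampling,
    # step-patterned CDF): its estimates run ~1-5% high, so recovery is
    # asserted to within one integer step of the true dimension
    expect_lte(abs(round(median_d(gen_binary_cube, d)) - d), 1)
  }
})
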