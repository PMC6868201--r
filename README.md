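# fcidim — intrinsic dimension estimation via the full correlation integral

`fcidim` estimates the intrinsic dimension (ID) of a numeric dataset — the
number of parameters needed to describe it locally — from the *full
correlation integral*: the fraction of sample pairs at Euclidean distance
below a cutoff, used at **all** cutoffs instead of only the small-radius
limit. It is aimed at practitioners facing high-dimensional embeddings
(molecular-dynamics descriptors, single-cell latent spaces, image
manifolds) where classical estimators break down because small
neighborhoods are empty: the method keeps working even when the number of
samples is *smaller* than the dimension being estimated.

## The method in one paragraph

For samples drawn from a rotationally invariant distribution on a
d-dimensional linear subspace, centering at the empirical mean and
projecting every sample onto the unit sphere produces (approximately)
uniform points on S^(d−1). The pairwise chord-distance CDF of a uniform
m-sphere is known exactly: with r̄ = r/r_s and t = (r̄² − 2)/2,

    ρ̄(r̄) = 1/2 + (Ω_{m−1} / 2Ω_m) (r̄² − 2) ₂F₁(1/2, 1 − m/2; 3/2; t²)
          = 1/2 + sign(t) · I_{t²}(1/2, m/2) / 2,

a sigmoid through (√2, 1/2) whose steepness grows strictly with m (I is
the regularized incomplete beta function; Ω_m the total solid angle of the
m-sphere). Fitting this two-parameter curve (m, r_s) to the empirical
pair-distance CDF by least squares and reporting d̂ = m̂ + 1 gives the ID.
Because the whole sigmoid — not its undersampled tail — constrains the fit,
accuracy is retained at N ≪ d. A multiscale variant applies the same
estimator inside neighborhoods of growing radius around chosen centers,
yielding local ID curves whose plateaus expose curvature and
multidimensionality; the classical Grassberger–Procaccia slope estimator is
included as a baseline (`corr_dim()`).

## Worked example

```r
library(fcidim)

# a 15-dimensional hypercube, rotated into 60 ambient dimensions
X <- gen_hypercube(500, d = 15, D = 60, seed = 3)
estimate_id(X, seed = 3)
#> FCI intrinsic dimension estimate: d = 15.283 (rounded: 15)
#>   m_hat = 14.283, r_s_hat = 1.001, sse = 0.0006546, samples used = 500

# the same dimension from only 100 samples of a 200-dimensional cube
estimate_id(gen_hypercube(100, 200, 210, seed = 5), seed = 5)$d_est
#> [1] 203.2528

# curvature needs the multiscale analysis: a Swiss roll is locally 2-D
ms <- multiscale_id(gen_swiss_roll(2000, seed = 11), n_centers = 5, seed = 11)
round(ms$minimum)
#> [1] 2
```

The first call prints the fitted sphere dimension `m_hat` (the +1 rule
gives `d_est`), the fitted sphere radius `r_s_hat` (≈1 after projection),
and the residual sum of squares of the CDF fit. In the undersampled second
call the relative error is 1.6% with N half of d. In the third, the global
estimate would overshoot (the roll is curled up in 3-space); the minimum
over local plateau estimates recovers the surface dimension 2.

A command-line interface wraps the same functions
(`inst/cli/fci estimate|multiscale|corrdim|generate`); each subcommand
emits a JSON report echoing its configuration and seed.

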