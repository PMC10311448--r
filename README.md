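# gaussrf

Generalised Gaussian derivative models of visual receptive fields, the
natural image transformations they are covariant under, and a numerical
suite that verifies each covariance property as a commutative diagram.

## The scientific problem

The earliest linear stages of biological vision — retinal ganglion cells
and LGN neurons with centre-surround receptive fields, simple cells in V1
with oriented ones — face image data whose geometry is constantly deformed
by viewing conditions: perspective foreshortening (locally an affine map),
viewing distance (spatial scaling), relative motion (a Galilean space-time
shear), and events unfolding faster or slower (temporal scaling). A
receptive-field family can *absorb* these deformations if filtering a
transformed input equals transforming the filtered output under a matched
change of filter parameters — covariance (equivariance). This package
implements the receptive-field families for which this works, the
parameter-matching laws, and machinery that measures how well the
discretised theory realises each covariance.

The models:

* **Spatial simple-cell model** — scale-normalised directional derivatives
  of affine Gaussian kernels,
  `T(x) = s^(m/2) ∂_φd^m g(x; s Σ)`, where
  `g(x; Σ) = exp(-xᵀΣ⁻¹x/2) / (2π √det Σ)` and the 2×2 SPD matrix `Σ`
  (eigenvalues λ1 ≥ λ2, orientation φ) shapes the elliptical support.
* **Spatial LGN model** — the Laplacian of an isotropic Gaussian,
  `±s (∂x1x1 + ∂x2x2) g(x; s I)`.
* **Time-causal limit kernel** `ψ(t; τ, c)` — an infinite cascade of
  first-order temporal integrators with geometrically distributed time
  constants `μ_k = c^(-k) √(c²-1) √τ` (truncated at `K` stages;
  `Σ μ_k² = τ (1 - c^(-2K))`), the canonical temporal smoothing kernel
  that never accesses the future and is covariant under temporal scalings
  by integer powers of `c`.
* **Velocity-adapted spatio-temporal models** —
  `s^(m/2) τ^(n/2) ∂_φd^m ∂̄t^n [ g(x - v t; s Σ) ψ(t; τ, c) ]` with the
  transport derivative `∂̄t = v·∇ + ∂t`, tuned to image velocity `v`
  (space-time separable exactly when `v = 0`).

The matching laws verified by the suite: `Σ_R = A Σ_L Aᵀ` and `v_R = A v_L`
under a spatial affine map `A`; `s_R = S_x² s_L`, `v_R = S_x v_L` under
uniform scaling; `v' = v + u` under a Galilean shear `u`; `τ' = S_t² τ`,
`v' = v / S_t` under temporal scaling `S_t = c^i`. Two negative results are
demonstrated as well: rotationally symmetric (LGN) smoothing admits *no*
affine matching, and the space-time separable LGN model is *not* Galilean
covariant while its velocity-adapted variant is.

## Worked example

```r
library(gaussrf)

Sigma <- covariance_from_eigen(64, 16, pi / 6)
Sigma
#> spatial covariance: lam1 = 64, lam2 = 16, phi = 0.523599 rad
eccentricity(Sigma)
#> [1] 0.5

# an oriented first-derivative receptive field; derivative kernels carry
# an exactly vanishing zeroth moment
k <- spatial_rf_kernel(spatial_rf_spec(s = 1, Sigma = Sigma, m = 1))
dim(k); attr(k, "mass")
#> [1] 81 81
#> [1] -5.76e-21

# shape recovery from the sampled kernel (moment inversion)
estimate_rf_params(k, m = 1)[c("phi", "eccentricity")]
#> $phi           0.5235988   # = pi/6
#> $eccentricity  0.5

# limit-kernel time constants for c = sqrt(2), tau = 1
limit_kernel_time_constants(1, sqrt(2), 4)
#> [1] 0.7071068 0.5000000 0.3535534 0.2500000

# commutative diagram: filter-then-warp vs warp-then-filter under
# A = diag(1.5, 1) with the matched Sigma_R = A Sigma t(A)
img <- make_test_image(fixture_spec("band_limited_noise", size = 129, seed = 0))
covariance_residual(img, spatial_rf_spec(s = 4), affine_map(1.5, 0, 0, 1))
#> [1] 0.000414

# negative control: refuse to match the covariance and the diagram breaks
covariance_residual(img, spatial_rf_spec(s = 4), affine_map(1.5, 0, 0, 1),
                    right_spec = spatial_rf_spec(s = 4))
#> [1] 0.113
```

The first residual says the two paths around the affine diagram agree to
0.04% relative L2 over the interior of the image — the covariance holds to
interpolation accuracy. The unmatched control is ~300× worse, so a passing
residual is informative, not vacuous.

`run_covariance_suite()` executes all six diagram families (spatial
affine, spatial scaling, Galilean, temporal scaling, and the joint
spatio-temporal affine/scaling cases with velocity matching) and returns a
report; `negative_controls()` runs the three mandatory failure cases;
`hypothesis_report()` computes the population statistics (eccentricity
`ε = √(λmin/λmax)`, speed, `σ_space = √s`, `σ_time = √τ`) used to phrase
testable hypotheses about biological receptive-field variability. A thin
CLI over these functions is in `inst/scripts/covariance-cli.R`.

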