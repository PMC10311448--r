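---
title: "Receptive-field models, covariance properties, and how they are verified numerically"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptive-field models, covariance properties, and how they are verified numerically}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaussrf)
```

## The model family

`gaussrf` implements linear receptive-field models for the earliest stages
of visual processing. Over the spatial domain, the oriented (simple-cell)
model is a scale-normalised directional derivative of an affine Gaussian,

$$T(x) = s^{m/2}\,\partial_{\varphi_d}^{\,m}\, g(x;\, s\Sigma),\qquad
  g(x;\Sigma) = \frac{e^{-x^{\top}\Sigma^{-1}x/2}}{2\pi\sqrt{\det\Sigma}},$$

parameterised by a spatial scale $s$, a $2\times 2$ SPD covariance matrix
$\Sigma$ (eigenvalues $\lambda_1 \ge \lambda_2$, orientation $\varphi$),
a derivative order $m \le 4$ and a derivative direction $\varphi_d$. The
centre-surround (LGN) model is the Laplacian of an isotropic Gaussian,
$\pm s \nabla^2 g(x; sI)$. Over time, the smoothing kernel is the
time-causal limit kernel $\psi(t; \tau, c)$: a cascade of first-order
integrators $\dot y = (x - y)/\mu_k$ with geometrically distributed time
constants $\mu_k = c^{-k}\sqrt{c^2-1}\sqrt{\tau}$, truncated at $K$
stages. Because $\sum_{k\ge 1}\mu_k^2 = \tau$ is a geometric series, the
$K$-stage cascade carries temporal variance $\tau(1 - c^{-2K})$ — with the
defaults $c=\sqrt 2$, $K=12$ the deficit is $2^{-12}\approx 2.4\times
10^{-4}$, negligible against every tolerance used here. Spatio-temporal
receptive fields combine the two with velocity adaptation,

$$T(x, t) = s^{m/2}\tau^{n/2}\,\partial_{\varphi_d}^{\,m}
  \bar\partial_t^{\,n}\,\bigl[g(x - v t;\, s\Sigma)\,\psi(t; \tau, c)\bigr],
  \qquad \bar\partial_t = v\cdot\nabla + \partial_t,$$

so the spatial kernel travels along the motion trajectory and the
transport derivative $\bar\partial_t$ differentiates along it. A useful
identity drives the implementation: applied to $g(x - vt)h(t)$, the
transport derivative reduces to $g(x - vt)\,h'(t)$ — the spatial motion
term cancels exactly — so spatial differentiation can be done analytically
while temporal differentiation acts on the temporal factor alone.

## Covariances and their matching laws

Each natural image transformation leaves the family closed under a
deterministic change of parameters:

| transformation | input relation | matched parameters |
|---|---|---|
| affine $A$ | $x_R = A x_L$ | $\Sigma_R = A\Sigma_L A^{\top}$, $v_R = A v_L$ |
| uniform scaling $S_x$ | $x_R = S_x x_L$ | $s_R = S_x^2 s_L$, $v_R = S_x v_L$ |
| Galilean $u$ | $x' = x + u t$ | $v' = v + u$ |
| temporal scaling $S_t = c^i$ | $t' = S_t t$ | $\tau' = S_t^2 \tau$, $v' = v / S_t$ |

Derivative responses additionally transform as tensors: spatial gradients
obey $\nabla_L = A^{\top}\nabla_R$, and the velocity-adapted temporal
derivative maps onto itself when $v$ is matched (substituting
$\nabla_L = A^\top \nabla_R$ or $v' = v+u$ into $\bar\partial_t$ shows the
correspondence directly). Scale normalisation by $s^{m/2}$ and
$\tau^{n/2}$ is what makes the *magnitudes* of derivative responses equal
across scales, not merely proportional.

Two covariances provably cannot hold and are kept as negative controls:
rotationally symmetric smoothing admits no matching under anisotropic
affine maps (`match_affine()` refuses; the measured residual stays ~0.4
and does not shrink under grid refinement), and the space-time separable
LGN model fails the Galilean diagram (residual ~1) while its
velocity-adapted variant passes.

Temporal scalings are restricted to integer powers of $c$. For the finite
$K$-stage cascade the kernel-level rescaling identity actually holds for
any $S_t>0$ (all time constants scale by $\sqrt{\tau}$), but matching
within a discrete ladder of temporal scale channels is only possible when
the rescaled constants coincide with an existing channel, i.e. for
$S_t = c^i$; the suite therefore only asserts $S_t \in \{c, c^2\}$.

## How a diagram is verified

`covariance_residual()` computes path A = warp(filter(input)) and path B =
filter(warp(input), matched parameters) and reports their relative $L_2$
distance over an interior crop. Key choices:

* **Crops.** The continuous identities hold on infinite domains. The crop
  margin removes everything a boundary can influence: kernel support,
  out-of-domain fill during warps (found exactly, per transformation, by
  mapping the crop corners through the inverse warp), the causal start-up
  frames, and — for Galilean shears — a parallelogram region that follows
  the sweep $u\,t$ frame by frame.
* **Comparison mode.** Under similarities (rotations, uniform scalings)
  and under Galilean/temporal scalings, scale-normalised scalar responses
  are directly comparable at any implemented order. Under anisotropic
  affine maps a directional derivative maps to a derivative along a
  sheared direction, so first-order responses are compared as gradient
  *vectors* transformed by $A^{\top}$; second and higher orders would
  need the full Hessian transport and are not offered under anisotropic
  maps.
* **Tolerances.** Residuals of interpolating diagrams are limited by the
  cubic interpolation and the discretisation of the kernels, not by the
  theory; the default tolerance is $10^{-2}$ and the measured residuals
  sit near $10^{-3}$ or below. Identity and 90°-rotation cases are exact
  grid permutations and are held to $10^{-12}$. A three-level refinement
  ladder (interpolation order 1 → 3, then grid and scale doubled) checks
  that residuals fall under refinement, which is what distinguishes a
  discretisation-limited residual from a structural failure.

## Numerical design

**Analytic sampling.** Kernels are produced by differentiating the
continuous Gaussian analytically (a Hermite-polynomial recursion in the
direction $\varphi_d$) and sampling at integer offsets — never by finite
differencing of sampled values — so derivative orders are exact and
90°-rotation equivariance is bit-exact on square grids. Support is cut at
`truncation_radius` (default 5) Mahalanobis units.

**Truncation and moments.** Smoothing kernels are *not* renormalised
after truncation; the mass deficit is reported in the `mass` attribute so
diagram residuals reflect truncation honestly. Derivative kernels are the
one exception: hard truncation leaves a DC flux of order $10^{-4}$ in
even-order kernels, which would leak a constant's response through what
should be a pure derivative operator. Each derivative kernel therefore has
the flux subtracted uniformly over its support (a vanishing-moment
correction). The correction offsets sampled values by $\sim 10^{-6}$
relative to the continuous closed form — the tests pin the analytic
evaluator to the closed forms exactly and the sampled centres to
$10^{-5}$ — and in exchange constants are annihilated to machine
precision, which is what makes responses on a logarithmic brightness scale
exactly invariant to multiplicative illumination changes.

**Temporal integrators.** Each cascade stage is discretised
ramp-invariantly: the pole is $e^{-\Delta t/\mu}$ and the input weights
are chosen so the update reproduces the continuous solution exactly for
piecewise-linear input. This keeps unit DC gain and a nonnegative impulse
response for any step size, and — unlike the plain zero-order-hold
exponential update — has no half-sample delay bias. That bias matters: at
frame-rate synthesis it accumulates to $K\,\Delta t/2 \approx 1.5$ frames
across the cascade, which cancels between the two paths of a Galilean
diagram but shifts the two paths of a temporal-scaling diagram against
each other by a sub-frame offset worth several percent of residual.

**Frame-rate kernels.** Spatio-temporal kernels are synthesised on a
temporal grid oversampled fourfold and then binned to frame rate with
4-tap Keys-cubic weights — the same interpolation model the warps use —
so that discrete temporal convolution acts as continuous convolution with
the cubically interpolated signal (third-order accurate; box binning is
zero-order and dominates residuals at the percent level). Taps falling
before the causal edge are folded onto the first slice to preserve the
partition of unity. Each slice's spatial kernel is recentred at the
slice's frame time, which makes the velocity-adapted kernel the exact
integer-shift shear of the separable kernel whenever $v$ is an integer
number of pixels per frame — and makes the Galilean diagram exact in that
case, a useful sanity anchor.

**Warps and convolution.** Image warps use inverse mapping about the
image centre with Keys bicubic interpolation (order 1 available);
out-of-domain samples are filled by mirror reflection, consistent with the
convolution boundary default. Convolutions run via FFT with explicit
boundary extension (reflect / replicate / circular / zero; the temporal
axis of causal kernels aligns strictly over past and present frames and is
extended by replication, with the start-up frames flagged).

## Synthetic data

All experiments run on generated inputs. Band-limited noise is seeded
white noise low-pass filtered with a hard radial mask at 1/6 of the
Nyquist frequency — band-limited so warp interpolation error is controlled
(cubic interpolation error scales as the fourth power of the band edge).
Because the FFT mask makes the field exactly periodic, translating-pattern
videos shift frames by FFT phase shifts: the exact continuous translation
of the periodic base, with integer displacements reducing to circular
rolls. The default suite video translates at (0.25, 0.125) px/frame; this
sets the temporal band edge of the content, and the temporal-derivative
diagrams are the first to feel it — at ~(0.5, 0.25) px/frame their
residuals rise to ~1.4%, which is a resolution limit of frame-sampled
video, not of the theory. The default problem sizes — 129×129 images,
65×65×64 videos, kernels sized automatically to their own support — keep
the full suite plus controls under a minute on one CPU.

What passing diagrams on these fixtures do *not* show: behaviour on
natural images (broadband spectra, occlusions, non-smooth content), on
real recordings of neurons, or under transformations outside the four
groups (no perspective warps — the affine map is their first-order
approximation).

## Shape estimation and the population machinery

`estimate_rf_params()` recovers the generating orientation and
eccentricity $\epsilon = \sqrt{\lambda_{\min}/\lambda_{\max}}$ from a
sampled kernel via second moments of the squared kernel. For a Gaussian
axis the squared kernel's moment is $\lambda/2$; along a derivative axis
it is $r_m \lambda$ with $r_1 = 3/2$, $r_2 = 7/6$ (computable in closed
form from Hermite-weighted Gaussian integrals), and these ratios are
inverted analytically. Near-isotropic derivative kernels put more energy
along the derivative axis than across it, so the energy principal axes can
swap relative to the generating axes; the derivative axis is identified by
its fourth standardised moment (5/3 for first derivatives — bimodal —
about 3.49 for second, exactly 3 for the Gaussian axis). Orientation is
flagged undefined when the recovered eccentricity is within $10^{-3}$
of 1.

The population generators cover the transformation groups: a hemisphere of
isotropic kernels orthographically projected to the image plane (slant
$\theta$ gives $\epsilon = \cos\theta$, azimuth gives orientation) and a
self-similar ladder of velocities ($\pm v_{base}\,\text{ratio}^k$).
`hypothesis_report()` computes $\epsilon$, speed, $\sigma_{space} =
\sqrt s$ and $\sigma_{time} = \sqrt\tau$ per member and issues three
verdicts: H1 (eccentricity spread beyond 0.2 — more of the affine group
than rotations), H2 (the $(\epsilon, v)$ occupancy grid extends in both
directions and $\epsilon$ is not confined to a narrow band), H3 (speeds
vary while the $\epsilon$ IQR stays below 0.05). The spread and
narrow-band thresholds are configurable defaults — nothing in the theory
fixes them — and H2/H3 are mutually exclusive by construction.
Orientations are histogrammed in double-angle representation, identifying
a derivative kernel with its sign-flipped copy.

## Known limitations

* Anisotropic-affine diagrams for derivative responses are implemented at
  first order only (gradient transport); higher orders would need full
  tensor transport.
* Down-scaling diagrams push content toward the Nyquist frequency; the
  suite keeps the matched kernel's standard deviation at or above one
  pixel, below which sampled derivative kernels alias visibly.
* The temporal axis of a causal convolution has a start-up region of one
  kernel length that is flagged, not computed around.
* Shape estimation inverts moments for $m \le 2$; higher orders would
  need the corresponding moment ratios.
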