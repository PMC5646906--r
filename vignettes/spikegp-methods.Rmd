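---
title: "Methods and numerical conventions in spikegp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and numerical conventions in spikegp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the modelling assumptions, parameter defaults and
numerical conventions behind `spikegp`, together with the limitations we are
aware of. It is the place to look when a number in the package (a default
grid, a tolerance, a window length) needs a justification.

## 1. The model

A recording is a set of spike sequences `y = (y_1 < … < y_N)` on a window
`[0, T]`, observed on a frame grid with interval `delta`. Each sequence is
modelled as an inhomogeneous renewal process driven by a non-negative
intensity `x(t)`: define the operational time

```
X(a, b) = integral of x(t) dt over (a, b],
```

and require that the rescaled intervals `tau_k = X(y_{k-1}, y_k)` are i.i.d.
draws from a fixed unit-mean-scale renewal density. Three families are
implemented:

| family | rescaled ISI law | hazard behaviour |
|--------|------------------|------------------|
| IP | Exponential(1) | memoryless |
| IG | Gamma(shape `gamma`, rate `gamma`) | refractory for `gamma > 1` |
| IIG | inverse Gaussian(mean `alpha`, shape 1) | refractory, heavy right tail |

The sequence log-density consists of the renewal terms for interior
intervals plus boundary corrections: the first spike and the censored tail
after the last spike are treated with inhomogeneous-Poisson forms (the
renewal state at the window edges is unobserved, and the IP boundary keeps
the likelihood proper for every family). For the IP family this reduces
exactly to the usual inhomogeneous Poisson likelihood.

The intensity is represented by its values on the frame grid,
`x = (x_0, …, x_n)` with `t_i = i * delta`, and given a squared-exponential
Gaussian-process prior with mean `mu`, marginal variance `sigma_f^2`,
inverse-squared length scale `kappa` and a fixed nugget `sigma_v2 = 1e-4`
(numerical conditioning only; it is excluded from the hyperparameter
search). The posterior mode under the non-negativity constraint
`x_i >= 0` is found by a projected Newton method; for each hyperparameter
grid point `theta = (shape, kappa, sigma_f)` the evidence is approximated by
a Laplace integral at the constrained mode, and the final estimate is the
evidence-weighted mixture

```
x* = sum_theta w(theta) x*_theta,   w ∝ exp(Laplace log evidence) * prior.
```

The pointwise 95% band combines the within-`theta` Laplace variances with
the between-`theta` spread of the modes and is clipped at zero.

## 2. Numerical conventions

**Left-rule quadrature.** `X(a, b)` is computed by the left rule on the
frame grid: `delta * sum of x_k` for nodes `k` with `a <= t_k < b`. The
rule is exactly additive (`X(a,c) = X(a,b) + X(b,c)` when all three points
are nodes), which the time-rescaling identities rely on, and makes the
likelihood an explicitly linear function of the `x_k` inside the
exponential terms, which keeps the Newton steps cheap.

**Frame-grid snapping.** Spike times and integration endpoints are snapped
to the nearest grid node (every real time is within `delta/2` of a node).
Snapping emits a warning rather than failing; consumers that simulate at
rates where the mean ISI approaches `delta` should expect distortion — see
Limitations.

**Projected Newton and boundary modes.** The constrained mode can have
coordinates clamped at zero (typically during long spikeless stretches with
a small prior mean). At such a mode the full Hessian-plus-prior-precision
matrix can be indefinite even though the block on the free coordinates is
positive definite. The Laplace evidence is therefore computed over the free
subspace only: log-determinant of the free block and one factor of
`sqrt(2*pi)` per free coordinate. Clamped coordinates carry zero Laplace
variance in the band. Interior modes are unaffected, and an independent
three-dimensional quadrature oracle in the test-suite pins the interior
constant to 0.05 nats.

**Prior mean anchoring.** When `mu` is not supplied, `fit_intensity`
anchors it at the empirical rate `N/T` pooled over sequences. For the IIG
family the rescaled-interval mean is `alpha` rather than 1, so the
consistent intensity level is `alpha * N/T`; the prior mean is scaled per
grid point accordingly.

## 3. Parameter defaults and rationale

`fit_config()` defaults:

- `gamma_grid`: 12 log-spaced points in `[1, 20]`. Shapes below 1
  (bursting) are excluded by default because the refractory regime is the
  empirically relevant one for calcium spikes; see Limitations.
- `alpha_grid = NULL`: the IIG family falls back to `gamma_grid`. The two
  shapes live on different scales (IG dispersion falls like `1/sqrt(gamma)`
  while IIG dispersion grows like `sqrt(alpha)`), so family comparisons
  should pass an explicit small-`alpha` grid, e.g.
  `alpha_grid = c(0.1, 0.2, 0.4, 0.8)`, to give IIG a fair refractory
  parameterisation.
- `kappa_grid`: 10 log-spaced points in `[1e-3, 10]`, covering length
  scales from ~0.3 s to ~30 s.
- `sigma_f_grid`: 8 log-spaced points in `[0.1, 5]` — from nearly flat to
  strongly modulated relative to a rate of order 1 event/s.
- `min_spikes = 10`: sequences at or below 10 spikes trigger a warning; the
  per-cell diagnostics below are meaningless at smaller counts.
- `tol_grad = 1e-6`, `tol_obj = 1e-8`, `max_iter = 200`: the Newton solve
  is quadratically convergent near the mode; these tolerances put the
  projected-gradient norm far below the statistical noise floor.

The prior over the hyperparameter grid is uniform; with 10–1000 grid points
the evidence dominates the prior after a few tens of spikes.

## 4. Goodness of fit and model selection

`rescale_isis` maps a sequence to `tau_k` (for `k >= 2`; the first interval
is excluded because its left edge is the window boundary, not a spike) and
`u_k = 1 - exp(-tau_k)`. Two diagnostic constructions are offered:

- **KS points**: sorted `u_k` against uniform plotting positions
  `s_n = (n - 0.5)/K`.
- **QQ points**: sorted `tau_k` against exponential quantiles
  `-log(1 - s_n)`.

Both are summarised by the zero-intercept least-squares slope
(`fit_slope`), which is 1 in expectation under a correctly specified model.

`select_isi_model` fits every candidate family to every cell, computes the
per-cell slope, and ranks families by the median absolute deviation of the
slopes from 1. Two design decisions deserve a record:

**QQ slopes by default.** The KS slope regresses bounded order statistics
on the uniform diagonal through the origin; a symmetric dispersion error
moves the low and high order statistics in opposite directions, which
largely cancels, so a badly misspecified family can still score a KS slope
near 1 (we observed an IP fit to Gamma(6) data with a median KS-slope
deviation of 0.004). The QQ slope responds directly to over- or
under-dispersion of the rescaled intervals — precisely what distinguishes
the renewal families — and is therefore the selection default. KS points
remain the better *calibration* diagnostic when the family is known, since
their slope has much lower sampling variance.

**Identifiability requires a slow intensity.** The protocol jointly
estimates the intensity and judges the residual ISI law. If the GP prior
admits length scales comparable to the mean ISI, the fitted intensity can
track individual spikes and absorb part of the ISI dispersion: in our
experiments the rescaled intervals then became under-dispersed for every
candidate family (QQ slopes 0.6–0.75 against 1.0 under the true intensity)
and selection degenerated. The protocol is meaningful only when the
underlying rate varies slowly relative to the ISIs — which is the premise
of the model — and the hyperparameter grid should include appropriately
slow `kappa` values; given the choice, the Laplace evidence does prefer the
slow length scale.

## 5. Surrogate generators and realism

Three samplers generate sequences from a given intensity and family:

- `"rescaling"`: draw unit renewal intervals and invert the operational
  time — exact up to grid resolution, and the reference method.
- `"inverse"`: per-interval inverse-CDF sampling by bisection on the grid.
- `"bernoulli"`: per-frame Bernoulli thinning with probability
  `min(q * delta, 1)` from the conditional intensity `q`; a warning is
  emitted when `q * delta` saturates, since the discretisation is only
  first-order accurate.

The three methods agree distributionally (pairwise two-sample KS tests on
pooled ISIs do not reject at 1% in the acceptance suite). All generators
snap spikes to the frame grid and enforce at least one empty frame between
spikes, which is the realism constraint of frame-based imaging: two events
within a frame are indistinguishable. Consequently simulation at rates
where the mean ISI approaches `delta` thins the sequences (at
`delta = 0.5`, rate 1, about 9% of the expected count is lost); choose
`delta` at least five times smaller than the mean ISI.

GP intensity draws (`sample_intensity`) are clipped at zero by default and
report the clipped fraction per draw; moment checks in the test-suite use
unclipped draws.

## 6. Problem sizes in the test-suite

Simulation studies in the tests use a deterministic two-cosine intensity
with periods `2*pi` and `4*pi` seconds on a window `T = 16*pi ≈ 50` s
(about 50 spikes per cell at mean rate 1). The window is four periods of
the slow component: long enough that the finite-window censoring bias of
the pooled rescaled-interval mean (order 1/spike-count) is ~0.003, well
inside Monte-Carlo error, and short enough that a full fit takes seconds.
Model-selection experiments instead use periods of ~25 and ~50 s against a
1 s mean ISI, for the identifiability reason of section 4.

## 7. Limitations

- **Shapes below 1** (bursting regimes) are supported by the densities and
  generators, but the default grids exclude them and the MAP solver is less
  well conditioned there (the log-density is unbounded as an interval
  length tends to zero for `gamma < 1`).
- **The credible band is pointwise.** Its calibration claim is aggregate
  coverage over nodes and cells; within one cell, misses are correlated —
  a rare long spikeless gap pulls the local posterior towards zero and all
  nodes in the gap miss together. The band makes no simultaneous-coverage
  claim.
- **Frame-grid snapping** biases every statistic when the mean ISI is not
  well above `delta` (see section 5).
- **Hyperparameter marginalisation is a grid sum**, not a continuous
  integral; with very concentrated evidence (the effective number of
  contributing grid points is reported by `summary`) the band can be
  slightly too narrow between grid points.
- **The nugget `sigma_v2` is fixed**, not inferred; it is a conditioning
  device, and results are insensitive to it over `1e-6`–`1e-3`.
- **The boundary intervals use IP forms** for every family; for very short
  windows (a few ISIs) this choice dominates the likelihood and family
  comparison is unreliable — hence `min_spikes`.
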