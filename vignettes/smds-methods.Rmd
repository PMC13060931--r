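---
title: "Drifting emission subspaces: the model and methods behind smds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drifting emission subspaces: the model and methods behind smds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Latent linear dynamical systems (LDS) are a workhorse for trial-structured
neural population recordings: high-dimensional activity `y_t` in `N` channels
is explained by a low-dimensional latent state `x_t` with linear-Gaussian
dynamics and a linear-Gaussian emission,

    x_{t+1} = A x_t + b + q_t,   q_t ~ N(0, Q)
    y_t     = C x_t + r_t,       r_t ~ N(0, R),

with `x_1 ~ N(mu1, Sigma1)`. The standard model assumes one emission matrix
`C` for the whole session. Representational drift — the gradual change of
single-neuron tuning while behaviour and, plausibly, the underlying
computation stay fixed — violates exactly that assumption, and it does so on
within-session timescales in several motor and sensory areas.

This package implements a dynamical system in which the latent dynamics
`{A, b, Q}` stay fixed but the emission matrix moves smoothly across trials
on the Stiefel manifold, the space of `N x D` matrices with orthonormal
columns. Orthonormality is what makes drift identifiable: an unconstrained
per-trial `C` could trade scale and shear against the latent states, whereas
a Stiefel-constrained emission leaves only within-subspace rotations
unresolved, and those are modelled explicitly.

## Parametrizing motion on the Stiefel manifold

A displacement vector `z` of length `D(2N-D-1)/2` splits into

* `w` — the `D(D-1)/2` strict upper-triangle entries (row-major) of a
  generator `W` that rotates the basis *within* its subspace, and
* `V` — a `D x (N-D)` block, stored column-stacked, that tilts the subspace
  into its orthogonal complement. Only `V` moves the point on the Grassmann
  manifold of subspaces.

The generator `B = [[W - W', V], [-V', 0]]` is skew-symmetric, and the Cayley
transform `f(B) = (I - B)(I + B)^{-1}` maps it to a rotation. The emission of
block `k` is

    C^(k) = U_base f(B(z^(k))) O_readout,

where `U_base` is a fixed orthonormal basis of the ambient space (set from
the principal axes of the training data when fitting) and
`O_readout = [I_D; 0]` selects the first `D` rotated axes. The matrix
exponential is available as an alternative retraction
(`smds_control(retraction = "expm")`); the Cayley map is the default because
it is cheaper and better behaved in optimization, and the two agree to first
order at the origin.

Displacements evolve across *blocks* (consecutive groups of trials sharing
one emission; block size 1 gives per-trial drift) as a Gaussian random walk

    z^(1) ~ N(m_z, S_z),   z^(k+1) = z^(k) + e^(k),  e^(k) ~ N(0, diag(tau2)),

with one drift rate `tau2_i` per coordinate, so each subspace axis may rotate
at its own speed. Each `tau2_i` carries an Inverse-gamma prior
(`ig_alpha = 2`, `ig_beta = 1e-3` by default) and is clipped elementwise
(`tau2_clip = 1e-2`) after every M-step; see the numerical notes below for
why the clip matters.

Drift is quantified through principal angles: for orthonormal `C1`, `C2`,
the angles are the arccosines of the singular values of `C1'C2` (clipped into
`[-1, 1]` before `acos`), and the Grassmann geodesic distance is the
root-sum-of-squares of the angles. Its normalized form divides by the
supremum `(pi/2) sqrt(D)`, so 1 means fully orthogonal subspaces.
Per-dimension drift is the angle between matching columns across blocks,
using the absolute inner product so sign flips do not count; columns keep
their identity across blocks because the within-subspace rotation is an
explicit latent, not a nuisance. Per-dimension *peak* drift is measured
against the first block by default — the natural reading of "drift over the
session" — with an all-pairs maximum available
(`drift_report(fit, peak = "all-pairs")`) for sessions where the largest
excursion happens mid-session.

## Inference: structured mean-field variational EM

The exact joint posterior over states `{x}` and displacements `{z}` is
intractable, so the fit alternates between two Gaussian factors:

1. **States given displacements.** With the emissions frozen at the current
   posterior means, `C^(k) = h(zhat^(k))`, each trial is an ordinary LDS and
   is smoothed exactly (Kalman filter + Rauch-Tung-Striebel pass, Joseph-form
   covariance updates, implemented in compiled code). Conditioning on the
   point estimate `zhat` rather than propagating the displacement
   uncertainty is a deliberate simplification; it keeps the state update
   exact and cheap.
2. **Displacements given states.** The expected log-likelihood of one block,
   as a function of `vec(C)`, collapses into a single Gaussian
   pseudo-observation `yhat ~ N(vec(h(z)), Rhat)` with precision
   `sum_t E[x_t x_t'] (x) R^{-1}` under the package's column-stacking vec
   convention, and mean `vec((sum_t y_t E[x_t]') (sum_t E[x_t x_t'])^{-1})` —
   the per-block least-squares emission estimate. A unit test verifies, by
   brute-force evaluation of the expected log-likelihood, that the two
   expressions differ only by a `z`-independent constant; that test is what
   pins the Kronecker ordering, since vec conventions silently differ across
   texts. The chain of pseudo-observations, with identity dynamics and
   process noise `diag(tau2)` per elapsed block, is then smoothed with an
   extended Kalman smoother that linearizes `vec(h(.))` at each predicted
   mean using the analytic Cayley differential
   `dF = -(I + F) dB (I + B)^{-1}` (finite differences serve as a test
   cross-check and as the fallback for the exponential retraction).
3. **M-step.** `{A, b, Q, mu1, Sigma1, R}` have the standard LDS closed
   forms, with the block-specific emissions entering the `R` update; `R` is
   diagonal by default (`r_mode = "full"` is available). The displacement
   prior `(m_z, S_z)` is refreshed from the first block's posterior, and each
   `tau2_i` is set to its Inverse-gamma posterior mode,

       tau2_i = (beta + S_i / 2) / (alpha + 1 + (K - 1) / 2),

   where `S_i` sums the expected squared increments
   `E[(z_i^(k+1) - z_i^(k))^2]` (using means, marginal variances, and the
   smoother's lag-one cross-covariances, divided by the block gap), then
   clipped to `tau2_clip`.

The traced objective is the exact state marginal log-likelihood at the
current emissions plus the log-density of the posterior-mean displacement
path under its random-walk prior — a MAP-style surrogate for the evidence
lower bound. It is not guaranteed monotone (the displacement update is
approximate), but the suite fails if it ever drops by more than 1% of its
magnitude in a fit.

### Numerical safeguards

* **Iterated, damped EKS update.** The Cayley rotation angle saturates as the
  displacement grows, so the Jacobian flattens and a single linearized
  measurement update can overshoot catastrophically (we observed exactly this
  failure mode on stationary data: the chain chased noise, `tau2` inflated to
  the clip, and the filter diverged). The measurement update is therefore a
  short Gauss-Newton iteration on the block's MAP objective with step
  halving — it relinearizes at the updated mean and only accepts steps that
  decrease the objective. For affine emissions this reduces exactly to the
  standard Kalman update, which the suite verifies.
* **`tau2` clipping** bounds the per-block drift the first-order
  linearization has to absorb; the per-iteration diagnostics record when the
  clip binds.
* Symmetrization after every covariance update, eigenvalue flooring when a
  nominally-PD matrix is reconstituted, and ridge-regularized solves (with a
  warning) for degenerate sufficient statistics.

### Initialization

`U_base` is the full eigenbasis of the pooled uncentered second moment of the
training data (uncentered because the emission model has no bias term, so a
nonzero mean direction belongs inside the subspace); displacements start at
zero, i.e. at the top-`D` principal subspace. Dynamics start at
`A = 0.99 I`, `b = 0`, `Q = I`, `R` at the channels' residual variances
after rank-`D` truncation — one closed-form M-step pulls these to sensible
scales immediately. The LDS baseline uses the same recipe with `C` the
top-`D` principal axes. Fits are deterministic given the data.

## Held-out evaluation and dimension selection

Model selection uses the exact marginal log-likelihood of held-out blocks.
For a held-out block inside the training range, the posterior-mean
displacement is linearly interpolated between the flanking training blocks —
under a Gaussian random walk the bridge mean *is* the linear interpolant of
the endpoints — and mapped through the retraction; outside the range the
nearest end is used (with a warning). `select_dimension()` fits a dimension
grid across block-level train/test splits and reports the smallest dimension
whose mean held-out log-likelihood is within one standard error (across
splits) of the best; the underlying saturation is qualitative, and the 1-SE
rule is the package's operational version of it.

## The simulator and what it does (not) emulate

`smds_sim_config()` provides two fully specified recipes: `"main"`
(`D = 2`, `N = 10`, 750 blocks of one 30-timestep trial each) and
`"highdim"` (`D = 8`, `N = 24`, same recipe scaled up). The generator-level
constants are package choices, fixed once: damped plane rotations for the
dynamics (`0.97 x` a 15-degree rotation for `"main"`; four planes at 15-45
degrees for `"highdim"`), `Q = 0.05 I`, `R = 0.1 I`, `m_z = 0`,
`S_z = 0.01 I`, and per-axis drift rates calibrated so each subspace axis
rotates out of plane by roughly 0.5-1 degree per block (0.25-1 for
`"highdim"`) — for a small generator the Cayley map rotates axis `d` by about
`2 ||row d of V||`, which gives the per-coordinate standard deviation
`rot_d / (2 sqrt(N - D))`. Per-block drift is thus small (the regime the
EKS linearization assumes) while drift accumulated over a session is large,
tens of degrees, comparable to what within-session recordings show.

The simulator emulates Gaussian observation noise, a shared stationary
latent process, and smooth random-walk subspace drift. It does not emulate
spiking statistics (Poisson counts, refractoriness), non-stationary firing
rates or gain changes, abrupt representational switches, electrode loss or
neuron turnover, or behavioural covariates. Passing the recovery tests
therefore demonstrates the estimator's correctness under its own model
class, not robustness to those realities.

Several checks run at reduced replicate sizes so the suite and the
acceptance script stay fast on one CPU: dimension-recovery experiments use
200-250 blocks (main recipe) and 100-120 blocks (`"highdim"`) with 2-3
splits and 15-20 variational iterations; recovery-quality checks use
60-150 blocks. These sizes are the package's choices and are stated here
rather than in the tests.

## Known limitations

* Axis-wise drift attribution requires the latent axes to be identifiable;
  with rotation-symmetric dynamics (e.g. an isotropic plane rotation with
  isotropic noise) the within-plane orientation of the latent basis is
  arbitrary, and per-dimension rates can only be compared after aligning
  bases, or by breaking the symmetry in the generator.
* On drift-free data the Inverse-gamma prior keeps `tau2` at a small floor
  (`~ ig_beta / (ig_alpha + 1 + (K-1)/2)`), so fitted emissions retain a
  degree-scale wiggle; apparent drift below a few degrees should not be
  over-interpreted.
* Conditioning the state update on the displacement point estimate slightly
  underestimates state uncertainty, and the traced objective is a surrogate,
  not a true bound.
* The drift prior is a homogeneous random walk: event-driven or switching
  drift, drift in the dynamics themselves, and non-Gaussian emissions are
  out of scope.
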