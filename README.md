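# smds: Stiefel manifold dynamical systems for tracking representational drift

Linear dynamical systems (LDS) explain high-dimensional neural population
activity `y_t ∈ R^N` with a low-dimensional latent state `x_t ∈ R^D`:

    x_{t+1} = A x_t + b + q_t,   q_t ~ N(0, Q)
    y_t     = C x_t + r_t,       r_t ~ N(0, R).

They assume a *stable* emission matrix `C` across a session — an assumption
broken by representational drift, the gradual within-session change of how
neurons map latent content to firing. **smds** implements a state-space model
in which the latent dynamics stay fixed while the emission matrix is
constrained to be orthonormal (a point on the Stiefel manifold) and evolves
smoothly across trial blocks:

    C^(k) = U_base f(B(z^(k))) O_readout,        f(B) = (I − B)(I + B)^{-1}
    z^(k+1) = z^(k) + e^(k),                     e^(k) ~ N(0, diag(τ²)),

where `z^(k)` is a displacement whose `w`-part rotates the basis within its
subspace and whose `V`-part tilts the subspace itself, `B(z)` is the induced
skew-symmetric generator, and `f` is the Cayley transform. Each coordinate's
drift rate `τ²_i` is learned (Inverse-gamma prior, clipped after each
M-step). Fitting uses structured mean-field variational EM: exact Kalman
smoothing over states (compiled core) alternating with extended Kalman
smoothing over the displacement chain via collapsed Gaussian
pseudo-observations, plus closed-form M-steps. Drift is then quantified with
principal angles and normalized Grassmann distances, overall and per latent
dimension (in degrees).

The package is intended for researchers analysing trial-structured
multichannel recordings (electrophysiology, calcium imaging) who want to ask
*whether*, *how fast*, and *along which latent dimensions* a population code
drifts within a session — and who want latent-dimensionality estimates that
are not inflated by that drift.

It also provides:

* an LDS baseline with exact EM (`lds()`), sharing the same held-out
  evaluation machinery;
* a simulator for drifting-subspace experiments (`smds_sim_config()`,
  `sample_smds()`), used throughout the tests;
* held-out-likelihood model selection with a one-standard-error saturation
  rule (`select_dimension()`);
* model-free sliding-window PCA drift diagnostics
  (`sliding_window_pca_drift()`), drift reports (`drift_report()`), and JSON
  serialization for datasets and reports;
* a thin command-line wrapper (`inst/cli/smds-cli.R`) with
  `simulate` / `fit` / `eval` / `drift` verbs.

## Worked example

Simulate a drifting session from the built-in `D = 2`, `N = 10` recipe
(one 30-timestep trial per block), fit the model, and summarise the drift:

```r
library(smds)
cfg <- smds_sim_config("main", n_blocks = 120)
sim <- sample_smds(cfg$params, cfg$n_blocks, cfg$trials_per_block, cfg$T,
                   seed = 1)
fit <- smds(sim$data, D = 2, control = smds_control(max_iter = 20))
summary(fit)
#> Stiefel manifold dynamical system fit: D = 2, N = 10, 120 blocks
#>   objective -4872.62 after 20 iterations (max iterations reached)
#>   drift rates tau2 in [6.96e-05, 1.45e-04]
#>   normalized Grassmann drift, first to last block: 0.103
#>   latent variance fractions: 0.51 0.49

drift_report(fit)
#> Drift report: 120 blocks, 2 latent dimensions
#>   normalized Grassmann distance: median 0.074, max 0.124
#>   peak drift per dimension (degrees): 11.4 13.3
#>   latent variance fraction per dimension: 0.51 0.49
```

The fitted drift rates sit at the order of magnitude the generator used; the
subspace rotates by about 10% of the maximal Grassmann distance over the
session, i.e. each latent axis turns by roughly 11-13 degrees — and the
recovered per-block subspaces track the simulated ones closely:

```r
d <- mapply(function(a, b) grassmann_distance(a, b, normalized = TRUE),
            fit$C_blocks, sim$path$C)
median(d)
#> [1] 0.032
```

Dimension selection on held-out blocks (`select_dimension(sim$data, 1:10)`)
saturates at the generator's `D = 2`, while an LDS fitted to the same data
keeps improving with extra dimensions it spends on absorbing the drift.

## Going further

The methods vignette (`vignettes/smds-methods.Rmd`) documents the model and
its assumptions, the variational EM derivation and its numerical safeguards
(iterated damped EKS updates, `τ²` clipping), the simulator's design
constants, the held-out interpolation rule, and known limitations.
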