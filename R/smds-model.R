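#' Parameters of a Stiefel manifold dynamical system
#'
#' An LDS whose emission matrix is block-specific: `y_t = C^(k) x_t + r_t`
#' with `C^(k) = U_base f(B(z^(k))) O_readout` on the Stiefel manifold. The
#' displacement `z` follows a Gaussian random walk across blocks,
#' `z^(k+1) = z^(k) + N(0, diag(tau2))`, `z^(1) ~ N(m_z, S_z)`, so each
#' subspace coordinate can drift at its own rate. Each entry of `tau2`
#' carries an Inverse-gamma prior and is clipped after every M-step.
#'
#' @param A,b,Q,mu1,Sigma1 Shared latent dynamics, as in [lds_params()].
#' @param R Observation noise covariance (matrix or diagonal vector).
#' @param frame An [emission_frame()].
#' @param m_z,S_z Initial displacement mean and covariance (defaults 0 and
#'   `0.01 I`).
#' @param tau2 Positive vector of per-coordinate drift rates, length
#'   `displacement_dim(D, N)` (scalars are recycled).
#' @param ig_alpha,ig_beta Inverse-gamma prior hyperparameters for `tau2`.
#' @param tau2_clip Elementwise upper clip applied to `tau2` after M-steps.
#' @return Object of class `smds_params`.
#' @export
smds_params <- function(A, b = NULL, Q, mu1 = NULL, Sigma1 = NULL, R, frame,
                        m_z = NULL, S_z = NULL, tau2 = 1e-4,
                        ig_alpha = 2, ig_beta = 1e-3, tau2_clip = 1e-2) {
  stopifnot(inherits(frame, "emission_frame"))
  D <- frame$D; N <- frame$N
  zd <- displacement_dim(D, N)
  base <- lds_params(A = A, b = b, Q = Q,
                     C = frame$U_base[, seq_len(D), drop = FALSE], R = R,
                     mu1 = mu1, Sigma1 = Sigma1)
  if (is.null(m_z)) m_z <- rep(0, zd)
  if (is.null(S_z)) S_z <- 0.01 * diag(zd)
  if (is.vector(S_z) && length(S_z) == 1) S_z <- S_z * diag(zd)
  tau2 <- rep_len(as.numeric(tau2), zd)
  if (any(tau2 < 0)) stop("tau2 must be nonnegative")
  structure(list(A = base$A, b = base$b, Q = base$Q, R = base$R,
                 mu1 = base$mu1, Sigma1 = base$Sigma1, frame = frame,
                 m_z = as.numeric(m_z), S_z = as.matrix(S_z), tau2 = tau2,
                 ig_alpha = ig_alpha, ig_beta = ig_beta, tau2_clip = tau2_clip,
                 D = as.integer(D), N = as.integer(N), zdim = zd),
            class = "smds_params")
}

#' @export
print.smds_params <- function(x, ...) {
  cat(sprintf("SMDS parameters: D = %d, N = %d, displacement dim = %d\n",
              x$D, x$N, x$zdim))
  cat(sprintf("  drift rates tau2 in [%.2e, %.2e], clip %.2e\n",
              min(x$tau2), max(x$tau2), x$tau2_clip))
  invisible(x)
}

# LDS view of an SMDS with the emission frozen at displacement z
lds_view <- function(params, z) {
  lds_params(A = params$A, b = params$b, Q = params$Q,
             C = displacement_to_emission(z, params$frame), R = params$R,
             mu1 = params$mu1, Sigma1 = params$Sigma1)
}

#' Sample a drift path of emission subspaces
#'
#' Draws the displacement random walk over blocks and maps each displacement
#' through the Cayley retraction to an orthonormal emission matrix.
#'
#' @param params An [smds_params()] object.
#' @param n_blocks Number of blocks in the chain.
#' @param seed Optional integer seed.
#' @return Object of class `drift_path`: `z` (`n_blocks x zdim` matrix) and
#'   `C` (list of `N x D` Stiefel points).
#' @export
sample_drift_path <- function(params, n_blocks, seed = NULL) {
  stopifnot(inherits(params, "smds_params"), n_blocks >= 1)
  if (!is.null(seed)) { old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(as.integer(seed)) }
  zd <- params$zdim
  z <- matrix(0, n_blocks, zd)
  z[1, ] <- rmvnorm_one(1, params$m_z, params$S_z)
  if (n_blocks > 1) for (k in 2:n_blocks) {
    z[k, ] <- z[k - 1, ] + stats::rnorm(zd, 0, sqrt(params$tau2))
  }
  Cs <- lapply(seq_len(n_blocks), function(k)
    displacement_to_emission(z[k, ], params$frame))
  structure(list(z = z, C = Cs), class = "drift_path")
}

#' @export
print.drift_path <- function(x, ...) {
  cat(sprintf("Drift path: %d blocks, emission %d x %d\n",
              nrow(x$z), nrow(x$C[[1]]), ncol(x$C[[1]])))
  invisible(x)
}

#' Simulate a trial dataset from an SMDS
#'
#' Samples a drift path over blocks, then draws every trial from the shared
#' latent dynamics with its block's emission matrix.
#'
#' @param params An [smds_params()] object.
#' @param n_blocks Number of drift blocks.
#' @param trials_per_block Trials sharing each emission matrix.
#' @param T Timesteps per trial.
#' @param seed Optional integer seed.
#' @return List with `data` (a [trial_data()]), `path` (the ground-truth
#'   `drift_path`), and `x` (list of latent-state matrices).
#' @export
sample_smds <- function(params, n_blocks, trials_per_block, T, seed = NULL) {
  stopifnot(inherits(params, "smds_params"))
  if (!is.null(seed)) { old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(as.integer(seed)) }
  path <- sample_drift_path(params, n_blocks)
  K <- n_blocks * trials_per_block
  block <- rep(seq_len(n_blocks), each = trials_per_block)
  xs <- vector("list", K); ys <- vector("list", K)
  for (k in seq_len(K)) {
    x <- matrix(0, T, params$D)
    x[1, ] <- rmvnorm_one(1, params$mu1, params$Sigma1)
    if (T > 1) for (t in 2:T) {
      x[t, ] <- params$A %*% x[t - 1, ] + params$b +
        t(rmvnorm_one(1, rep(0, params$D), params$Q))
    }
    Ck <- path$C[[block[k]]]
    ys[[k]] <- x %*% t(Ck) + rmvnorm_one(T, rep(0, params$N), params$R)
    xs[[k]] <- x
  }
  list(data = trial_data(ys, block = block), path = path, x = xs)
}

# damped block-rotation dynamics: planes rotating at different speeds
rotation_dynamics <- function(D, degrees, decay = 0.97) {
  A <- diag(D)
  n_planes <- floor(D / 2)
  degrees <- rep_len(degrees, max(n_planes, 1))
  for (j in seq_len(n_planes)) {
    th <- degrees[j] * pi / 180
    Rj <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    idx <- (2 * j - 1):(2 * j)
    A[idx, idx] <- Rj
  }
  decay * A
}

# per-coordinate drift rates giving roughly `rot_deg[d]` of out-of-subspace
# rotation of axis d per block, plus a slow within-subspace rotation. For a
# small skew generator the Cayley map rotates axis d by about 2 ||row d of V||,
# so each of the N-D entries of that row gets sd rot/(2 sqrt(N-D)).
drift_rates <- function(D, N, rot_deg, w_deg = 0.5) {
  rot <- rep_len(rot_deg, D) * pi / 180
  v_sd <- rot / (2 * sqrt(N - D))
  tau2_V <- matrix(rep(v_sd^2, N - D), nrow = D)   # D x (N-D), row d constant
  tau2_w <- rep((w_deg * pi / 180 / 2)^2, w_dim(D))
  c(tau2_w, as.vector(tau2_V))
}

#' Named synthetic-experiment generators
#'
#' Fully specified simulation recipes for the drifting-subspace recovery
#' experiments: `"main"` uses `D = 2` latent dimensions, `N = 10` channels,
#' and 750 trials of 30 timesteps with the emission subspace rotating
#' smoothly trial-to-trial; `"highdim"` scales the same recipe up to
#' `D = 8`, `N = 24`. Dynamics are damped plane rotations (`0.97 x` rotation
#' by 15 degrees per step for `"main"`; four planes at 15-45 degrees for
#' `"highdim"`), with `Q = 0.05 I`, `R = 0.1 I`, `m_z = 0`, `S_z = 0.01 I`,
#' and per-dimension drift rates of about 0.5-1 degree of subspace rotation
#' per block (0.25-1 for `"highdim"`), so drift accumulated over a session is
#' large while each per-block step stays small.
#'
#' @param name `"main"` or `"highdim"`.
#' @param n_blocks Optionally override the number of blocks (trial count
#'   scales with it); the full-size experiments use 750.
#' @return List with `params` (an [smds_params()]), `n_blocks`,
#'   `trials_per_block`, and `T`.
#' @export
smds_sim_config <- function(name = c("main", "highdim"), n_blocks = NULL) {
  name <- match.arg(name)
  if (name == "main") {
    D <- 2; N <- 10
    A <- rotation_dynamics(D, degrees = 15)
    rot <- c(0.5, 1)
    nb <- 750L
  } else {
    D <- 8; N <- 24
    A <- rotation_dynamics(D, degrees = c(15, 25, 35, 45))
    rot <- seq(0.25, 1, length.out = D)
    nb <- 750L
  }
  frame <- emission_frame(diag(N), D)
  params <- smds_params(A = A, Q = 0.05 * diag(D), R = 0.1 * diag(N),
                        frame = frame, S_z = 0.01 * diag(displacement_dim(D, N)),
                        tau2 = drift_rates(D, N, rot))
  if (!is.null(n_blocks)) nb <- as.integer(n_blocks)
  list(params = params, n_blocks = nb, trials_per_block = 1L, T = 30L)
}
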