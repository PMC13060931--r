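#' Control settings for SMDS variational EM
#'
#' @param max_iter Maximum coordinate-ascent iterations.
#' @param tol Relative change of the objective declaring convergence.
#' @param ig_alpha,ig_beta Inverse-gamma prior hyperparameters for the drift
#'   rates `tau2`.
#' @param tau2_clip Elementwise upper clip applied to `tau2` after each
#'   M-step; the first-order extended-Kalman approximation relies on small
#'   per-block drift, so the clip keeps updates inside that regime.
#' @param tau2_init Initial drift rate for every displacement coordinate.
#' @param S_z_init Initial displacement prior variance (scalar, times identity).
#' @param r_mode `"diagonal"` or `"full"` observation noise.
#' @param learn_b Learn the dynamics bias?
#' @param retraction `"cayley"` (default) or `"expm"` for the map from skew
#'   generators to rotations.
#' @param verbose Print one line per iteration?
#' @return List of class `smds_control`.
#' @export
smds_control <- function(max_iter = 100L, tol = 1e-5, ig_alpha = 2,
                         ig_beta = 1e-3, tau2_clip = 1e-2, tau2_init = 1e-4,
                         S_z_init = 0.01, r_mode = c("diagonal", "full"),
                         learn_b = TRUE, retraction = c("cayley", "expm"),
                         verbose = FALSE) {
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 ig_alpha = ig_alpha, ig_beta = ig_beta,
                 tau2_clip = tau2_clip, tau2_init = tau2_init,
                 S_z_init = S_z_init, r_mode = match.arg(r_mode),
                 learn_b = isTRUE(learn_b),
                 retraction = match.arg(retraction),
                 verbose = isTRUE(verbose)),
            class = "smds_control")
}

# vec of the emission matrix under the package's column-stacking convention
emission_vec <- function(z, frame, retraction = "cayley") {
  as.vector(displacement_to_emission(z, frame, retraction = retraction))
}

#' Jacobian of the vectorized emission map
#'
#' Analytic differential of `z -> vec(U_base f_Cayley(B(z)) O_readout)`,
#' using `dF = -(I + F) dB (I + B)^{-1}` for the Cayley map and the sparsity
#' of each coordinate's skew generator. For the matrix-exponential retraction
#' a central finite difference is used instead.
#'
#' @param z Displacement vector.
#' @param frame An [emission_frame()].
#' @param retraction Retraction in use.
#' @return `(N D) x length(z)` Jacobian matrix.
#' @export
emission_jacobian <- function(z, frame, retraction = "cayley") {
  if (retraction != "cayley") return(emission_jacobian_fd(z, frame, retraction))
  emission_g_jac(z, frame)$J
}

# fused emission value + Jacobian sharing one Cayley factorization; sits on
# the hot path of the displacement smoother
emission_g_jac <- function(z, frame) {
  D <- frame$D; N <- frame$N
  parts <- split_displacement(z, D, N)
  B <- build_skew(parts$w, parts$V, D, N)
  IpB_inv <- solve(diag(N) + B)
  Fm <- (diag(N) - B) %*% IpB_inv
  Cvec <- as.vector(frame$U_base %*% Fm[, seq_len(D), drop = FALSE])
  L <- frame$U_base %*% (diag(N) + Fm)
  Rm <- IpB_inv[, seq_len(D), drop = FALSE]
  zd <- length(z)
  J <- matrix(0, N * D, zd)
  i <- 1L
  if (D > 1) {
    idx <- triu_idx(D)
    for (r in seq_len(nrow(idx))) {
      a <- idx[r, 1]; b <- idx[r, 2]
      J[, i] <- -(tcrossprod(L[, a], Rm[b, ]) - tcrossprod(L[, b], Rm[a, ]))
      i <- i + 1L
    }
  }
  for (j in seq_len(N - D)) for (d in seq_len(D)) {
    J[, i] <- -(tcrossprod(L[, d], Rm[D + j, ]) -
                  tcrossprod(L[, D + j], Rm[d, ]))
    i <- i + 1L
  }
  list(g = Cvec, J = J)
}

#' @rdname emission_jacobian
#' @param h Finite-difference step.
#' @export
emission_jacobian_fd <- function(z, frame, retraction = "cayley", h = 1e-6) {
  zd <- length(z)
  J <- matrix(0, frame$N * frame$D, zd)
  for (i in seq_len(zd)) {
    zp <- z; zm <- z
    zp[i] <- zp[i] + h; zm[i] <- zm[i] - h
    J[, i] <- (emission_vec(zp, frame, retraction) -
                 emission_vec(zm, frame, retraction)) / (2 * h)
  }
  J
}

#' E-step over latent states: per-trial Kalman smoothing
#'
#' Freezes each block's emission matrix at the current posterior-mean
#' displacement, `C^(k) = h(zhat^(k))`, and runs exact Kalman smoothing on
#' every trial.
#'
#' @param params An [smds_params()] object.
#' @param data A [trial_data()] object.
#' @param zhat Matrix of posterior-mean displacements, one row per block
#'   (rows ordered as `blocks`), or a `displacement_posterior`.
#' @param blocks Sorted block labels corresponding to the rows of `zhat`
#'   (defaults to the sorted unique blocks of `data`).
#' @param retraction Retraction used by the emission map.
#' @return List with `posts` (one `state_posterior` per trial), `loglik`
#'   (sum of exact per-trial marginals given the frozen emissions), and
#'   `C_blocks` (the emissions used, in block order).
#' @export
estep_states <- function(params, data, zhat, blocks = NULL,
                         retraction = "cayley") {
  if (inherits(zhat, "displacement_posterior")) {
    blocks <- zhat$blocks; zhat <- zhat$mean
  }
  zhat <- matrix(zhat, ncol = params$zdim)
  if (is.null(blocks)) blocks <- sort(unique(data$block))
  if (nrow(zhat) != length(blocks)) stop("zhat must have one row per block")
  C_blocks <- lapply(seq_len(nrow(zhat)), function(j)
    displacement_to_emission(zhat[j, ], params$frame, retraction = retraction))
  views <- lapply(C_blocks, function(C)
    lds_params(A = params$A, b = params$b, Q = params$Q, C = C, R = params$R,
               mu1 = params$mu1, Sigma1 = params$Sigma1))
  idx <- match(data$block, blocks)
  if (anyNA(idx)) stop("data contains blocks absent from zhat")
  posts <- lapply(seq_len(data$K), function(k)
    kalman_smooth(views[[idx[k]]], data$y[[k]]))
  list(posts = posts,
       loglik = sum(vapply(posts, `[[`, numeric(1), "loglik")),
       C_blocks = C_blocks, block_of_trial = idx)
}

#' Collapse a block's expected likelihood into one Gaussian pseudo-observation
#'
#' Given the smoothed state moments of a block's trials, the expected
#' log-likelihood of the block as a function of the vectorized emission
#' matrix is, up to a constant, a Gaussian log-density
#' `log N(yhat; vec(C), Rhat)` with precision `sum_t E[x x'] (x) R^{-1}`
#' (column-stacking vec) and mean `Rhat vec(R^{-1} sum_t E[y x'])`. This is
#' the nonlinear-Gaussian observation the displacement smoother consumes.
#'
#' @param y_block List of the block's `T x N` trials.
#' @param R Observation noise covariance.
#' @param xpost_block List of matching `state_posterior` objects.
#' @return List of class `pseudo_obs`: `yhat` (length `N D`), `Rhat`
#'   (`N D x N D`), and the building blocks `Sxx` (`sum_t E[x x']`) and
#'   `Syx` (`sum_t y_t E[x_t]'`).
#' @export
build_pseudo_obs <- function(y_block, R, xpost_block) {
  D <- ncol(xpost_block[[1]]$mean)
  N <- ncol(y_block[[1]])
  Sxx <- matrix(0, D, D); Syx <- matrix(0, N, D)
  for (k in seq_along(y_block)) {
    po <- xpost_block[[k]]
    Sxx <- Sxx + apply(po$var, c(1, 2), sum) + crossprod(po$mean)
    Syx <- Syx + crossprod(y_block[[k]], po$mean)
  }
  Sxx <- (Sxx + t(Sxx)) / 2
  Sxx_inv <- tryCatch(solve(Sxx), error = function(e) {
    warning("singular state second moment; using ridge-regularized inverse")
    solve(Sxx + 1e-8 * mean(diag(Sxx)) * diag(D))
  })
  Rhat <- kronecker(Sxx_inv, R)
  Rhat <- (Rhat + t(Rhat)) / 2
  Lambda <- kronecker(Sxx, solve(R))      # precision, built without an
  Lambda <- (Lambda + t(Lambda)) / 2      # (N D)-sized inversion
  yhat <- as.vector(Syx %*% t(Sxx_inv))   # = vec(Syx Sxx^{-1})
  structure(list(yhat = yhat, Rhat = Rhat, Lambda = Lambda,
                 Sxx = Sxx, Syx = Syx),
            class = "pseudo_obs")
}

#' Extended Kalman smoothing over the displacement chain
#'
#' Runs a forward extended Kalman filter (linearizing the vectorized
#' emission map at each predicted mean) and a Rauch-Tung-Striebel backward
#' pass over the block chain, whose prior is a Gaussian random walk with
#' identity dynamics and process noise `diag(tau2)` per elapsed block (gaps
#' between non-adjacent training blocks scale the process noise).
#'
#' @param params An [smds_params()] object (supplies `m_z`, `S_z`, `tau2`).
#' @param pseudo List with one [build_pseudo_obs()] result per block, in
#'   chain order.
#' @param blocks Block labels (defaults to `1:length(pseudo)`); differences
#'   between consecutive labels set the process-noise multiplier.
#' @param emission Optional override of the emission map for testing: a list
#'   with functions `g(z)` and `jac(z)`. Defaults to the Cayley emission of
#'   `params$frame`.
#' @return Object of class `displacement_posterior`: `blocks`, smoothed
#'   `mean` (`B x zdim`), `var` (`zdim x zdim x B`), and `cross`
#'   (`Cov(z_k, z_{k+1})`, `zdim x zdim x (B-1)`).
#' @export
eks_displacements <- function(params, pseudo, blocks = NULL, emission = NULL) {
  B <- length(pseudo)
  if (B < 1) stop("no pseudo-observations supplied")
  if (is.null(blocks)) blocks <- seq_len(B)
  gaps <- if (B > 1) diff(blocks) else integer(0)
  if (any(gaps < 1)) stop("blocks must be strictly increasing")
  zd <- params$zdim
  if (is.null(emission)) {
    emission <- list(g = function(z) emission_vec(z, params$frame),
                     jac = function(z) emission_jacobian(z, params$frame),
                     gj = function(z) emission_g_jac(z, params$frame))
  }
  gj <- if (!is.null(emission$gj)) emission$gj else
    function(z) list(g = emission$g(z), J = emission$jac(z))
  Qz <- diag(pmax(params$tau2, 1e-12), zd)
  mf <- matrix(0, B, zd); mp <- matrix(0, B, zd)
  Pf <- array(0, c(zd, zd, B)); Pp <- array(0, c(zd, zd, B))
  m <- params$m_z; P <- params$S_z
  Izd <- diag(zd)
  for (j in seq_len(B)) {
    if (j > 1) P <- P + gaps[j - 1] * Qz           # identity dynamics
    mp[j, ] <- m; Pp[, , j] <- P
    yhat <- pseudo[[j]]$yhat; Rhat <- pseudo[[j]]$Rhat
    Lambda <- pseudo[[j]]$Lambda
    if (is.null(Lambda)) Lambda <- solve((Rhat + t(Rhat)) / 2)

    # Iterated, step-damped measurement update (Gauss-Newton on the block's
    # MAP objective). A single linearized step can overshoot badly where the
    # retraction saturates (the Cayley rotation angle is bounded, so the
    # Jacobian flattens for large displacements); relinearizing at the
    # updated mean with step halving keeps the update inside the region the
    # linearization describes. For affine emissions this reduces exactly to
    # the standard Kalman update.
    Pinv <- solve((P + t(P)) / 2 + 1e-12 * diag(zd))
    map_obj <- function(x, gx) {
      r <- yhat - gx; d <- x - m
      0.5 * sum(d * (Pinv %*% d)) + 0.5 * sum(r * (Lambda %*% r))
    }
    mi <- m
    ev <- gj(mi)
    g_mi <- ev$g; J <- ev$J
    f_cur <- map_obj(mi, g_mi)
    K <- NULL; K_stale <- TRUE
    for (gn in 1:3) {
      S <- J %*% P %*% t(J) + Rhat
      S <- (S + t(S)) / 2
      K <- tryCatch(t(solve(S, J %*% P)), error = function(e)
        stop(sprintf("non-positive-definite innovation covariance at block %d",
                     blocks[j])))
      K_stale <- FALSE
      cand <- m + as.vector(K %*% (yhat - g_mi + J %*% (mi - m)))
      step <- cand - mi
      alpha <- 1; accepted <- FALSE
      repeat {
        xt <- mi + alpha * step
        gt <- emission$g(xt)
        f_new <- map_obj(xt, gt)
        if (f_new <= f_cur + 1e-10 * abs(f_cur)) { accepted <- TRUE; break }
        alpha <- alpha / 2
        if (alpha < 1 / 32) break
      }
      if (!accepted) break
      moved <- alpha * sqrt(sum(step^2))
      mi <- xt; g_mi <- gt; f_cur <- f_new
      if (moved < 1e-6 * (1 + sqrt(sum(mi^2)))) break   # keep previous J, K
      ev <- gj(mi)
      g_mi <- ev$g; J <- ev$J
      K_stale <- TRUE
    }
    if (K_stale) {                      # refresh the gain for the final J
      S <- J %*% P %*% t(J) + Rhat
      S <- (S + t(S)) / 2
      K <- t(solve(S, J %*% P))
    }
    m <- mi
    IKJ <- Izd - K %*% J
    P <- IKJ %*% P %*% t(IKJ) + K %*% Rhat %*% t(K)
    P <- (P + t(P)) / 2
    mf[j, ] <- m; Pf[, , j] <- P
  }
  ms <- mf; Ps <- Pf
  cross <- array(0, c(zd, zd, max(B - 1, 0)))
  if (B > 1) for (j in (B - 1):1) {
    G <- t(solve(Pp[, , j + 1], Pf[, , j]))        # Pf G' form, A = I
    ms[j, ] <- mf[j, ] + as.vector(G %*% (ms[j + 1, ] - mp[j + 1, ]))
    Pj <- Pf[, , j] + G %*% (Ps[, , j + 1] - Pp[, , j + 1]) %*% t(G)
    Ps[, , j] <- (Pj + t(Pj)) / 2
    cross[, , j] <- G %*% Ps[, , j + 1]
  }
  structure(list(blocks = blocks, mean = ms, var = Ps, cross = cross),
            class = "displacement_posterior")
}

#' @export
print.displacement_posterior <- function(x, ...) {
  cat(sprintf("Displacement posterior: %d blocks, dimension %d\n",
              length(x$blocks), ncol(x$mean)))
  invisible(x)
}

#' M-step of SMDS variational EM
#'
#' Closed-form updates: dynamics and noise parameters as in a standard LDS
#' (with the per-block emissions frozen at `h(zhat)`), the displacement
#' prior `(m_z, S_z)` from the first block's posterior, and each drift rate
#' `tau2_i` set to its Inverse-gamma posterior mode given the expected
#' squared displacement increments, then clipped to `tau2_clip`.
#'
#' @param data A [trial_data()] object.
#' @param xpost Result of [estep_states()].
#' @param zpost A `displacement_posterior`.
#' @param params Current [smds_params()].
#' @param control An [smds_control()] list.
#' @return Updated [smds_params()]; attribute `"n_clipped"` records how many
#'   drift-rate coordinates the clip bound.
#' @export
smds_mstep <- function(data, xpost, zpost, params, control = smds_control()) {
  ss <- pool_suffstats(data, xpost$posts)
  dyn <- mstep_dynamics(ss, learn_b = control$learn_b)

  # observation noise with block-specific emissions
  N <- data$N
  Rsum <- matrix(0, N, N)
  for (k in seq_len(data$K)) {
    po <- xpost$posts[[k]]; y <- data$y[[k]]
    Ck <- xpost$C_blocks[[xpost$block_of_trial[k]]]
    Exx <- apply(po$var, c(1, 2), sum) + crossprod(po$mean)
    Syx_k <- crossprod(y, po$mean)
    Rsum <- Rsum + crossprod(y) - Syx_k %*% t(Ck) - Ck %*% t(Syx_k) +
      Ck %*% Exx %*% t(Ck)
  }
  Rnew <- Rsum / ss$n_obs
  Rnew <- if (control$r_mode == "diagonal") diag(pmax(diag(Rnew), 1e-8), N)
          else sym_pd(Rnew, floor = 1e-8)

  # drift-rate update: IG posterior mode from expected squared increments
  B <- length(zpost$blocks)
  tau2 <- params$tau2
  n_clipped <- 0L
  if (B > 1) {
    gaps <- diff(zpost$blocks)
    zd <- ncol(zpost$mean)
    dg <- function(x) if (is.matrix(x)) diag(x) else x   # zd = 1 drops dims
    Ssq <- rep(0, zd)
    for (j in seq_len(B - 1)) {
      dm <- zpost$mean[j + 1, ] - zpost$mean[j, ]
      ed2 <- dm^2 + dg(zpost$var[, , j + 1]) + dg(zpost$var[, , j]) -
        2 * dg(zpost$cross[, , j])
      Ssq <- Ssq + pmax(ed2, 0) / gaps[j]
    }
    tau2 <- (control$ig_beta + Ssq / 2) /
      (control$ig_alpha + 1 + (B - 1) / 2)
    n_clipped <- sum(tau2 > control$tau2_clip)
    tau2 <- pmin(tau2, control$tau2_clip)
  }

  out <- smds_params(A = dyn$A, b = dyn$b, Q = dyn$Q, mu1 = dyn$mu1,
                     Sigma1 = dyn$Sigma1, R = Rnew, frame = params$frame,
                     m_z = zpost$mean[1, ],
                     S_z = sym_pd(matrix(zpost$var[, , 1],
                                         ncol(zpost$mean), ncol(zpost$mean))),
                     tau2 = tau2, ig_alpha = control$ig_alpha,
                     ig_beta = control$ig_beta, tau2_clip = control$tau2_clip)
  attr(out, "n_clipped") <- n_clipped
  out
}

# log density of the posterior-mean displacement path under the random-walk
# prior; the objective traced by smds() adds this to the state marginals.
zpath_log_prior <- function(params, zpost) {
  B <- length(zpost$blocks)
  lp <- mvn_logdens(zpost$mean[1, ], params$m_z, params$S_z)
  if (B > 1) {
    gaps <- diff(zpost$blocks)
    for (j in seq_len(B - 1)) {
      dm <- zpost$mean[j + 1, ] - zpost$mean[j, ]
      v <- pmax(gaps[j] * params$tau2, 1e-12)
      lp <- lp + sum(stats::dnorm(dm, 0, sqrt(v), log = TRUE))
    }
  }
  lp
}

mvn_logdens <- function(x, mean, Sigma) {
  d <- length(x)
  L <- chol(sym_pd(Sigma))
  a <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(a^2)
}

#' Fit a Stiefel manifold dynamical system
#'
#' Structured mean-field variational EM: the posterior factorizes into a
#' per-trial Gaussian over latent states and a Gaussian chain over block
#' displacements. Each iteration alternates exact Kalman smoothing of the
#' states given point-estimate emissions, extended Kalman smoothing of the
#' displacements given collapsed Gaussian pseudo-observations, and
#' closed-form M-steps (with the Inverse-gamma drift-rate update and clip).
#' `U_base` is initialized from the principal axes of the pooled training
#' data, the displacements at zero, and the dynamics as in [lds()].
#'
#' @param data A [trial_data()] object.
#' @param D Latent state dimension.
#' @param control An [smds_control()] list.
#' @param init Optional [smds_params()] to start from (skips the PCA
#'   initialization).
#' @return Object of class `smds`: fitted `params`, displacement posterior
#'   `zpost`, per-block emissions `C_blocks`, state posteriors `xpost`,
#'   objective `trace` (state marginal log-likelihood plus displacement-path
#'   log prior), `loglik` (final state marginal term), iteration
#'   `diagnostics`, and convergence info.
#' @export
smds <- function(data, D, control = smds_control(), init = NULL) {
  stopifnot(inherits(data, "trial_data"), D >= 1, D <= data$N)
  blocks <- sort(unique(data$block))
  B <- length(blocks)
  if (is.null(init)) {
    pc <- pca_init(data, D)
    frame <- emission_frame(pc$U, D)
    zd <- displacement_dim(D, data$N)
    params <- smds_params(A = 0.99 * diag(D), Q = diag(D), R = pc$rvar,
                          frame = frame, S_z = control$S_z_init * diag(zd),
                          tau2 = control$tau2_init,
                          ig_alpha = control$ig_alpha,
                          ig_beta = control$ig_beta,
                          tau2_clip = control$tau2_clip)
  } else {
    params <- init
    if (params$N != data$N) stop("init has wrong channel count")
  }
  zd <- params$zdim
  zhat <- matrix(0, B, zd)
  y_by_block <- split(data$y, factor(data$block, levels = blocks))

  trace <- numeric(0)
  diag_log <- list()
  zpost <- NULL; xpost <- NULL
  for (it in seq_len(control$max_iter)) {
    xpost <- estep_states(params, data, zhat, blocks = blocks,
                          retraction = control$retraction)
    pseudo <- lapply(seq_len(B), function(j) {
      idx <- which(xpost$block_of_trial == j)
      build_pseudo_obs(y_by_block[[j]], params$R, xpost$posts[idx])
    })
    zpost <- eks_displacements(params, pseudo, blocks = blocks)
    step <- max(abs(zpost$mean - zhat))
    zhat <- zpost$mean
    params <- smds_mstep(data, xpost, zpost, params, control)
    obj <- xpost$loglik + zpath_log_prior(params, zpost)
    trace <- c(trace, obj)
    diag_log[[it]] <- c(iter = it, objective = obj, max_z_step = step,
                        tau2_min = min(params$tau2),
                        tau2_max = max(params$tau2),
                        n_clipped = attr(params, "n_clipped"))
    if (control$verbose) {
      message(sprintf("iter %3d  objective %.2f  max z step %.2e  tau2 [%.1e, %.1e]",
                      it, obj, step, min(params$tau2), max(params$tau2)))
    }
    if (!is.finite(obj)) stop("objective diverged (non-finite) at iteration ", it)
    if (it > 1 && abs(trace[it] - trace[it - 1]) <
          control$tol * (1 + abs(trace[it - 1]))) break
  }
  xpost <- estep_states(params, data, zhat, blocks = blocks,
                        retraction = control$retraction)
  structure(list(params = params, zpost = zpost, xpost = xpost,
                 C_blocks = xpost$C_blocks, blocks = blocks,
                 trace = trace, loglik = xpost$loglik,
                 niter = length(trace),
                 converged = length(trace) < control$max_iter,
                 diagnostics = do.call(rbind, diag_log),
                 D = as.integer(D), N = data$N, control = control,
                 call = match.call()),
            class = "smds")
}

#' @export
print.smds <- function(x, ...) {
  cat(sprintf("Stiefel manifold dynamical system fit: D = %d, N = %d, %d blocks\n",
              x$D, x$N, length(x$blocks)))
  cat(sprintf("  objective %.2f after %d iterations (%s)\n",
              x$trace[length(x$trace)], x$niter,
              if (x$converged) "converged" else "max iterations reached"))
  cat(sprintf("  drift rates tau2 in [%.2e, %.2e]\n",
              min(x$params$tau2), max(x$params$tau2)))
  invisible(x)
}

#' @export
summary.smds <- function(object, ...) {
  print(object)
  dmax <- grassmann_distance(object$C_blocks[[1]],
                             object$C_blocks[[length(object$C_blocks)]],
                             normalized = TRUE)
  cat(sprintf("  normalized Grassmann drift, first to last block: %.3f\n", dmax))
  vfrac <- variance_per_dimension(object)
  cat(sprintf("  latent variance fractions: %s\n",
              paste(sprintf("%.2f", vfrac), collapse = " ")))
  invisible(object)
}

#' @export
coef.smds <- function(object, ...) object$params

#' @export
logLik.smds <- function(object, newdata = NULL, ...) {
  ll <- if (is.null(newdata)) object$loglik
        else heldout_loglik(object, newdata)
  structure(ll, class = "logLik", df = NA_integer_)
}

#' @export
plot.smds <- function(x, which = c("objective", "drift"), ...) {
  which <- match.arg(which)
  if (which == "objective") {
    graphics::plot(seq_along(x$trace), x$trace, type = "b", pch = 16,
                   xlab = "iteration", ylab = "objective", ...)
  } else {
    M <- pairwise_drift_matrix(x$C_blocks)
    graphics::image(x$blocks, x$blocks, M, xlab = "block", ylab = "block",
                    main = "normalized Grassmann distance", ...)
  }
  invisible(x)
}

#' @export
simulate.smds <- function(object, nsim = 1, seed = NULL, T = 30, ...) {
  sample_smds(object$params, n_blocks = nsim, trials_per_block = 1,
              T = T, seed = seed)
}

#' Predicted emission matrix at an arbitrary block
#'
#' For a training block, returns the fitted emission `h(zhat)`. For a block
#' between two training blocks, the posterior-mean displacement is linearly
#' interpolated between the flanking training blocks (the bridge mean of the
#' random-walk prior) and mapped through the retraction; beyond the training
#' range the nearest end is used, with a warning.
#'
#' @param fit An [smds()] fit.
#' @param block Integer block label.
#' @return `N x D` emission matrix.
#' @export
predict_emission <- function(fit, block) {
  zb <- fit$zpost$blocks
  z <- if (block %in% zb) {
    fit$zpost$mean[match(block, zb), ]
  } else if (block < min(zb) || block > max(zb)) {
    warning(sprintf("block %d outside training range [%d, %d]; using nearest end",
                    block, min(zb), max(zb)))
    fit$zpost$mean[if (block < min(zb)) 1 else length(zb), ]
  } else {
    lo <- max(which(zb < block)); hi <- min(which(zb > block))
    wgt <- (block - zb[lo]) / (zb[hi] - zb[lo])
    (1 - wgt) * fit$zpost$mean[lo, ] + wgt * fit$zpost$mean[hi, ]
  }
  displacement_to_emission(z, fit$params$frame,
                           retraction = fit$control$retraction)
}

#' Held-out marginal log-likelihood of an SMDS fit
#'
#' For each held-out block, predicts its emission matrix from the drift
#' posterior ([predict_emission()]) and evaluates the exact LDS marginal
#' log-likelihood of the block's trials under the shared fitted dynamics.
#'
#' @param fit An [smds()] fit.
#' @param heldout A [trial_data()] whose block labels are interleaved with
#'   (or flank) the training blocks.
#' @return Scalar total log-likelihood over held-out trials.
#' @export
heldout_loglik <- function(fit, heldout) {
  stopifnot(inherits(fit, "smds"), inherits(heldout, "trial_data"))
  p <- fit$params
  total <- 0
  for (blk in sort(unique(heldout$block))) {
    C <- predict_emission(fit, blk)
    view <- lds_params(A = p$A, b = p$b, Q = p$Q, C = C, R = p$R,
                       mu1 = p$mu1, Sigma1 = p$Sigma1)
    for (k in which(heldout$block == blk)) {
      total <- total + kalman_loglik(view, heldout$y[[k]])
    }
  }
  total
}
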