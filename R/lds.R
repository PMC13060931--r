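#' Parameters of a linear dynamical system
#'
#' `x_{t+1} = A x_t + b + N(0, Q)`, `x_1 ~ N(mu1, Sigma1)`,
#' `y_t = C x_t + N(0, R)`.
#'
#' @param A `D x D` dynamics matrix.
#' @param b Length-`D` dynamics bias (default 0).
#' @param Q `D x D` dynamics noise covariance (SPD).
#' @param C `N x D` emission matrix.
#' @param R `N x N` observation noise covariance (SPD), or a length-`N`
#'   vector of diagonal variances.
#' @param mu1 Initial state mean (default 0).
#' @param Sigma1 Initial state covariance (default identity).
#' @return Object of class `lds_params`.
#' @export
lds_params <- function(A, b = NULL, Q, C, R, mu1 = NULL, Sigma1 = NULL) {
  A <- as.matrix(A); Q <- as.matrix(Q); C <- as.matrix(C)
  D <- nrow(A); N <- nrow(C)
  if (ncol(A) != D) stop("A must be square")
  if (ncol(C) != D) stop(sprintf("C must have %d columns", D))
  if (is.null(b)) b <- rep(0, D)
  if (is.null(mu1)) mu1 <- rep(0, D)
  if (is.null(Sigma1)) Sigma1 <- diag(D)
  if (is.vector(R) && length(R) == N) R <- diag(R, N)
  R <- as.matrix(R)
  Sigma1 <- as.matrix(Sigma1)
  check_spd(Q, "Q"); check_spd(R, "R"); check_spd(Sigma1, "Sigma1")
  structure(list(A = A, b = as.numeric(b), Q = Q, C = C, R = R,
                 mu1 = as.numeric(mu1), Sigma1 = Sigma1,
                 D = as.integer(D), N = as.integer(N)),
            class = "lds_params")
}

check_spd <- function(M, name, tol = 1e-8) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > tol * (1 + max(abs(M)))) {
    stop(name, " must be symmetric")
  }
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(ev))) stop(name, " must be positive semidefinite")
  invisible(TRUE)
}

#' @export
print.lds_params <- function(x, ...) {
  cat(sprintf("LDS parameters: D = %d latent dimensions, N = %d channels\n",
              x$D, x$N))
  invisible(x)
}

rmvnorm_one <- function(n, mean, Sigma) {
  D <- length(mean)
  if (all(Sigma == 0)) return(matrix(mean, n, D, byrow = TRUE))
  ev <- eigen(Sigma, symmetric = TRUE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  sweep(matrix(stats::rnorm(n * D), n, D) %*% rt, 2, mean, `+`)
}

#' Simulate trials from a linear dynamical system
#'
#' @param params An [lds_params()] object.
#' @param T Timesteps per trial (scalar or length-`K` vector for ragged trials).
#' @param K Number of trials.
#' @param seed Optional integer seed.
#' @param block Optional block assignment passed to [trial_data()].
#' @return List with `data` (a [trial_data()]) and `x` (list of `T x D`
#'   latent-state matrices, for testing recovery).
#' @export
sample_lds <- function(params, T, K, seed = NULL, block = NULL) {
  stopifnot(inherits(params, "lds_params"))
  if (!is.null(seed)) { old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(as.integer(seed)) }
  Ts <- rep_len(T, K)
  xs <- vector("list", K); ys <- vector("list", K)
  for (k in seq_len(K)) {
    x <- matrix(0, Ts[k], params$D)
    x[1, ] <- rmvnorm_one(1, params$mu1, params$Sigma1)
    if (Ts[k] > 1) for (t in 2:Ts[k]) {
      x[t, ] <- params$A %*% x[t - 1, ] + params$b +
        t(rmvnorm_one(1, rep(0, params$D), params$Q))
    }
    y <- x %*% t(params$C) + rmvnorm_one(Ts[k], rep(0, params$N), params$R)
    xs[[k]] <- x; ys[[k]] <- y
  }
  list(data = trial_data(ys, block = block), x = xs)
}

#' Exact Kalman smoothing of one trial
#'
#' Runs the Kalman filter and Rauch-Tung-Striebel smoother, returning the
#' Gaussian smoothed posterior over latent states together with the exact
#' marginal log-likelihood of the trial.
#'
#' @param params An [lds_params()] object.
#' @param y `T x N` observation matrix (one trial).
#' @return Object of class `state_posterior`: `mean` (`T x D`), `var`
#'   (`D x D x T`), `cross` (`D x D x (T-1)` lag-one covariances
#'   `Cov(x_t, x_{t+1})`), and `loglik`.
#' @export
kalman_smooth <- function(params, y) {
  y <- as.matrix(y)
  if (ncol(y) != params$N) stop("y has wrong number of channels")
  out <- kalman_smooth_cpp(y, params$A, params$b, params$Q, params$C,
                           params$R, params$mu1, params$Sigma1, TRUE)
  structure(out, class = "state_posterior")
}

kalman_loglik <- function(params, y) {
  kalman_smooth_cpp(as.matrix(y), params$A, params$b, params$Q, params$C,
                    params$R, params$mu1, params$Sigma1, FALSE)$loglik
}

#' Exact marginal log-likelihood of a dataset under an LDS
#'
#' Sum over trials of the exact Gaussian marginal `log p(y_1:T)`; invariant
#' under similarity transforms of the parameters.
#'
#' @param params An [lds_params()] object.
#' @param data A [trial_data()] object.
#' @return Scalar log-likelihood.
#' @export
lds_loglik <- function(params, data) {
  stopifnot(inherits(data, "trial_data"))
  sum(vapply(data$y, function(y) kalman_loglik(params, y), numeric(1)))
}

# sufficient statistics for the closed-form M-steps, pooled over trials
pool_suffstats <- function(data, posts) {
  D <- ncol(posts[[1]]$mean)
  S_all <- matrix(0, D, D)      # sum_t E[x x']
  S_0 <- matrix(0, D, D)        # sum_{t<T} E[x x']
  S_1 <- matrix(0, D, D)        # sum_{t>1} E[x x']
  S_cr <- matrix(0, D, D)       # sum E[x_t x_{t+1}']
  sum0 <- rep(0, D); sum1 <- rep(0, D); sum_all <- rep(0, D)
  Syx <- matrix(0, data$N, D); Syy <- matrix(0, data$N, data$N)
  m1s <- matrix(0, length(posts), D); P1 <- matrix(0, D, D)
  n_trans <- 0; n_obs <- 0
  for (k in seq_along(posts)) {
    po <- posts[[k]]; y <- data$y[[k]]; Tk <- nrow(po$mean)
    Exx <- po$var
    for (t in seq_len(Tk)) Exx[, , t] <- Exx[, , t] + tcrossprod(po$mean[t, ])
    tot <- apply(Exx, c(1, 2), sum)
    S_all <- S_all + tot
    sum_all <- sum_all + colSums(po$mean)
    Syx <- Syx + crossprod(y, po$mean)
    Syy <- Syy + crossprod(y)
    n_obs <- n_obs + Tk
    if (Tk > 1) {
      S_0 <- S_0 + tot - Exx[, , Tk]
      S_1 <- S_1 + tot - Exx[, , 1]
      for (t in seq_len(Tk - 1)) {
        S_cr <- S_cr + po$cross[, , t] + tcrossprod(po$mean[t, ], po$mean[t + 1, ])
      }
      sum0 <- sum0 + colSums(po$mean[-Tk, , drop = FALSE])
      sum1 <- sum1 + colSums(po$mean[-1, , drop = FALSE])
      n_trans <- n_trans + Tk - 1
    }
    m1s[k, ] <- po$mean[1, ]
    P1 <- P1 + po$var[, , 1]
  }
  list(S_all = S_all, S_0 = S_0, S_1 = S_1, S_cr = S_cr, sum0 = sum0,
       sum1 = sum1, sum_all = sum_all, Syx = Syx, Syy = Syy, m1s = m1s,
       P1 = P1, n_trans = n_trans, n_obs = n_obs, K = length(posts))
}

# closed-form update of A, b, Q, mu1, Sigma1 from pooled statistics
mstep_dynamics <- function(ss, learn_b = TRUE, ridge = 1e-9) {
  D <- nrow(ss$S_all)
  if (learn_b) {
    M <- rbind(cbind(ss$S_0, ss$sum0), c(ss$sum0, ss$n_trans))
    G <- cbind(t(ss$S_cr), ss$sum1)
    Ab <- t(solve_reg(M, t(G), ridge))
    A <- Ab[, seq_len(D), drop = FALSE]; b <- Ab[, D + 1]
  } else {
    A <- t(solve_reg(ss$S_0, ss$S_cr, ridge)); b <- rep(0, D)
    Ab <- A; G <- t(ss$S_cr)
    M <- ss$S_0
  }
  Q <- (ss$S_1 - Ab %*% t(G) - G %*% t(Ab) + Ab %*% M %*% t(Ab)) / ss$n_trans
  Q <- sym_pd(Q)
  mu1 <- colMeans(ss$m1s)
  dev <- sweep(ss$m1s, 2, mu1)
  Sigma1 <- sym_pd((ss$P1 + crossprod(dev)) / ss$K)
  list(A = A, b = b, Q = Q, mu1 = mu1, Sigma1 = Sigma1)
}

solve_reg <- function(M, rhs, ridge = 1e-9) {
  M <- (M + t(M)) / 2
  out <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(out)) {
    warning("singular sufficient statistics; using ridge-regularized solve")
    out <- solve(M + ridge * mean(diag(M)) * diag(nrow(M)) + ridge * diag(nrow(M)), rhs)
  }
  out
}

sym_pd <- function(M, floor = 1e-10) {
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE)
  ev$vectors %*% (pmax(ev$values, floor) * t(ev$vectors))
}

#' EM control settings for the LDS baseline
#'
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param r_mode `"diagonal"` (default; one variance per channel) or
#'   `"full"` observation noise.
#' @param learn_b Learn the dynamics bias?
#' @return List of class `lds_control`.
#' @export
lds_control <- function(max_iter = 100L, tol = 1e-6, r_mode = c("diagonal", "full"),
                        learn_b = TRUE) {
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 r_mode = match.arg(r_mode), learn_b = isTRUE(learn_b)),
            class = "lds_control")
}

# PCA-based initialization shared by both models: top-D principal axes of the
# pooled (uncentered) second moment; residual channel variances for R.
pca_init <- function(data, D) {
  Y <- do.call(rbind, data$y)
  S <- crossprod(Y) / nrow(Y)
  ev <- eigen(S, symmetric = TRUE)
  Cd <- ev$vectors[, seq_len(D), drop = FALSE]
  resid <- diag(S) - rowSums((Cd %*% diag(sqrt(ev$values[seq_len(D)]), D))^2)
  list(U = ev$vectors, C = Cd, rvar = pmax(resid, 1e-6),
       lambda = ev$values)
}

#' Fit a linear dynamical system by EM
#'
#' Baseline stable-emission model: exact E-step by Kalman smoothing and
#' closed-form M-steps for all parameters. Initialization uses the top-`D`
#' principal axes of the pooled data for `C`, `A = 0.99 I`, `Q = I`, and
#' residual channel variances for `R`.
#'
#' @param data A [trial_data()] object.
#' @param D Latent state dimension.
#' @param control An [lds_control()] list.
#' @param init Optional [lds_params()] to start from.
#' @return Object of class `lds`: fitted `params`, the log-likelihood
#'   `trace`, `loglik` (final), `niter`, `converged`, and smoothed state
#'   posteriors `xpost`.
#' @export
lds <- function(data, D, control = lds_control(), init = NULL) {
  stopifnot(inherits(data, "trial_data"), D >= 1, D <= data$N)
  if (is.null(init)) {
    pc <- pca_init(data, D)
    params <- lds_params(A = 0.99 * diag(D), Q = diag(D), C = pc$C,
                         R = pc$rvar, Sigma1 = diag(D))
  } else params <- init

  trace <- numeric(0); posts <- NULL
  for (it in seq_len(control$max_iter)) {
    posts <- lapply(data$y, function(y) kalman_smooth(params, y))
    ll <- sum(vapply(posts, `[[`, numeric(1), "loglik"))
    trace <- c(trace, ll)
    ss <- pool_suffstats(data, posts)
    dyn <- mstep_dynamics(ss, learn_b = control$learn_b)
    C <- t(solve_reg(ss$S_all, t(ss$Syx)))
    Rfull <- (ss$Syy - C %*% t(ss$Syx) - ss$Syx %*% t(C) +
                C %*% ss$S_all %*% t(C)) / ss$n_obs
    R <- if (control$r_mode == "diagonal") diag(pmax(diag(Rfull), 1e-8), data$N)
         else sym_pd(Rfull, floor = 1e-8)
    params <- lds_params(A = dyn$A, b = dyn$b, Q = dyn$Q, C = C, R = R,
                         mu1 = dyn$mu1, Sigma1 = dyn$Sigma1)
    if (it > 1 && abs(trace[it] - trace[it - 1]) <
          control$tol * (1 + abs(trace[it - 1]))) break
  }
  structure(list(params = params, trace = trace, loglik = trace[length(trace)],
                 niter = length(trace), D = as.integer(D), N = data$N,
                 converged = length(trace) < control$max_iter,
                 control = control, xpost = posts, call = match.call()),
            class = "lds")
}

#' @export
print.lds <- function(x, ...) {
  cat(sprintf("Linear dynamical system fit (EM): D = %d, N = %d\n", x$D, x$N))
  cat(sprintf("  log-likelihood %.2f after %d iterations (%s)\n",
              x$loglik, x$niter,
              if (x$converged) "converged" else "max iterations reached"))
  invisible(x)
}

#' @export
summary.lds <- function(object, ...) {
  cat(sprintf("LDS fit: D = %d latent dimensions, N = %d channels\n",
              object$D, object$N))
  cat(sprintf("  final log-likelihood: %.2f (%d EM iterations)\n",
              object$loglik, object$niter))
  ev <- abs(eigen(object$params$A, only.values = TRUE)$values)
  cat(sprintf("  dynamics spectral radius: %.3f\n", max(ev)))
  cat(sprintf("  mean observation noise variance: %.4f\n",
              mean(diag(object$params$R))))
  invisible(object)
}

#' @export
logLik.lds <- function(object, newdata = NULL, ...) {
  ll <- if (is.null(newdata)) object$loglik else lds_loglik(object$params, newdata)
  structure(ll, class = "logLik",
            df = with(object$params,
                      D^2 + 2 * D + D * (D + 1) + N * D +
                        if (object$control$r_mode == "diagonal") N
                        else N * (N + 1) / 2))
}

#' @export
coef.lds <- function(object, ...) object$params

#' @export
plot.lds <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "b", pch = 16,
                 xlab = "EM iteration", ylab = "log-likelihood", ...)
  invisible(x)
}

#' @export
simulate.lds <- function(object, nsim = 1, seed = NULL, T = 30, ...) {
  sample_lds(object$params, T = T, K = nsim, seed = seed)
}
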