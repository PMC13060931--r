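# Independent oracles used across the suite. Everything here works from the
# model definition directly (dense joint Gaussians, quadrature), never through
# the package's filtering/smoothing code paths.

# Joint Gaussian of (x_1..x_T, y_1..y_T) under an LDS, stacked time-major.
joint_lds <- function(params, T) {
  D <- params$D; N <- params$N
  mu_x <- matrix(0, T, D)
  mu_x[1, ] <- params$mu1
  if (T > 1) for (t in 2:T) mu_x[t, ] <- params$A %*% mu_x[t - 1, ] + params$b
  S_xx <- matrix(0, T * D, T * D)
  bl <- function(t) ((t - 1) * D + 1):(t * D)
  S_xx[bl(1), bl(1)] <- params$Sigma1
  if (T > 1) for (t in 2:T) {
    S_xx[bl(t), bl(t)] <- params$A %*% S_xx[bl(t - 1), bl(t - 1)] %*%
      t(params$A) + params$Q
    for (s in 1:(t - 1)) {
      S_xx[bl(s), bl(t)] <- S_xx[bl(s), bl(t - 1)] %*% t(params$A)
      S_xx[bl(t), bl(s)] <- t(S_xx[bl(s), bl(t)])
    }
  }
  IC <- kronecker(diag(T), params$C)
  S_yy <- IC %*% S_xx %*% t(IC) + kronecker(diag(T), params$R)
  list(mu_x = as.vector(t(mu_x)), S_xx = S_xx,
       mu_y = as.vector(IC %*% as.vector(t(mu_x))), S_yy = S_yy,
       S_xy = S_xx %*% t(IC))
}

gauss_logdens <- function(x, mu, S) {
  L <- chol((S + t(S)) / 2)
  a <- backsolve(L, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(a^2)
}

# Brute-force smoothing: condition the dense joint on the observations.
brute_smooth <- function(params, y) {
  T <- nrow(y); D <- params$D
  j <- joint_lds(params, T)
  yv <- as.vector(t(y))
  W <- solve(j$S_yy)
  post_mu <- j$mu_x + j$S_xy %*% W %*% (yv - j$mu_y)
  post_S <- j$S_xx - j$S_xy %*% W %*% t(j$S_xy)
  bl <- function(t) ((t - 1) * D + 1):(t * D)
  list(
    mean = matrix(post_mu, nrow = T, ncol = D, byrow = TRUE),
    var = lapply(seq_len(T), function(t) post_S[bl(t), bl(t), drop = FALSE]),
    cross = if (T > 1) lapply(seq_len(T - 1), function(t)
      post_S[bl(t), bl(t + 1), drop = FALSE]) else list(),
    loglik = gauss_logdens(yv, j$mu_y, j$S_yy))
}

# Similarity transform of LDS parameters (latent change of basis).
transform_lds <- function(params, Tm) {
  Ti <- solve(Tm)
  lds_params(A = Tm %*% params$A %*% Ti, b = as.vector(Tm %*% params$b),
             Q = Tm %*% params$Q %*% t(Tm), C = params$C %*% Ti,
             R = params$R, mu1 = as.vector(Tm %*% params$mu1),
             Sigma1 = Tm %*% params$Sigma1 %*% t(Tm))
}

random_lds <- function(D, N, seed = NULL, diag_R = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(D * D, sd = 0.4), D, D)
  A <- A / max(1.05 * abs(eigen(A, only.values = TRUE)$values), 1)
  M <- matrix(rnorm(D * D), D, D); Q <- crossprod(M) / D + 0.2 * diag(D)
  C <- matrix(rnorm(N * D), N, D)
  R <- if (diag_R) diag(runif(N, 0.2, 0.8), N) else {
    Mr <- matrix(rnorm(N * N), N, N); crossprod(Mr) / N + 0.3 * diag(N)
  }
  M1 <- matrix(rnorm(D * D), D, D)
  lds_params(A = A, b = rnorm(D, sd = 0.3), Q = Q, C = C, R = R,
             mu1 = rnorm(D), Sigma1 = crossprod(M1) / D + 0.2 * diag(D))
}

random_stiefel <- function(N, D) {
  qr.Q(qr(matrix(rnorm(N * D), N, D)))
}

# Expected complete-data emission log-likelihood of one block under q(x):
# E_q [ sum_t log N(y_t; C x_t, R) ] with C = h(z).
expected_emission_ll <- function(z, frame, y_block, R, xpost_block) {
  C <- displacement_to_emission(z, frame)
  Rinv <- solve(R)
  total <- 0
  for (k in seq_along(y_block)) {
    po <- xpost_block[[k]]; y <- y_block[[k]]
    for (t in seq_len(nrow(y))) {
      resid <- y[t, ] - C %*% po$mean[t, ]
      total <- total + gauss_logdens(as.vector(resid), rep(0, nrow(R)), R) -
        0.5 * sum(diag(t(C) %*% Rinv %*% C %*% po$var[, , t]))
    }
  }
  total
}

# Stationary covariance of x_{t+1} = A x_t + noise(Q): discrete Lyapunov
# equation solved by vectorization.
lyapunov_cov <- function(A, Q) {
  D <- nrow(A)
  matrix(solve(diag(D * D) - kronecker(A, A), as.vector(Q)), D, D)
}
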