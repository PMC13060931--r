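test_that("build_skew assembles the displacement generator", {
  # D=1, N=2: no within-subspace rotation, single tilt coordinate
  B <- build_skew(numeric(0), matrix(0.3, 1, 1), D = 1, N = 2)
  expect_equal(B, matrix(c(0, -0.3, 0.3, 0), 2, 2))

  expect_equal(build_skew(rep(0, 3), matrix(0, 3, 2), D = 3, N = 5),
               matrix(0, 5, 5))

  set.seed(1)
  for (i in 1:5) {
    B <- build_skew(rnorm(3), matrix(rnorm(6), 3, 2), D = 3, N = 5)
    expect_equal(max(abs(B + t(B))), 0)   # skew by construction, exactly
  }

  # w fill is row-major over the strict upper triangle
  B <- build_skew(c(1, 2, 3), matrix(0, 3, 1), D = 3, N = 4)
  expect_equal(B[1, 2], 1); expect_equal(B[1, 3], 2); expect_equal(B[2, 3], 3)

  expect_error(build_skew(rnorm(2), matrix(0, 3, 2), D = 3, N = 5), "length")
  expect_error(build_skew(rnorm(3), matrix(0, 2, 2), D = 3, N = 5), "expected")
})

test_that("cayley transform maps skew matrices to rotations", {
  expect_equal(cayley(matrix(0, 3, 3)), diag(3))
  # 2x2 closed form: B = [[0,1],[-1,0]] -> rotation by 90 degrees
  expect_equal(cayley(matrix(c(0, -1, 1, 0), 2, 2)),
               matrix(c(0, 1, -1, 0), 2, 2))
  set.seed(2)
  for (i in 1:10) {
    M <- matrix(rnorm(36), 6, 6)
    Q <- cayley(M - t(M))
    expect_lt(max(abs(crossprod(Q) - diag(6))), 1e-10)
    expect_equal(det(Q), 1, tolerance = 1e-8)
  }
  expect_error(cayley(matrix(rnorm(9), 3, 3)), "skew")
})

test_that("displacement maps onto the Stiefel manifold", {
  set.seed(3)
  D <- 3; N <- 6
  U <- random_stiefel(N, N)
  frame <- emission_frame(U, D)
  expect_equal(displacement_to_emission(rep(0, displacement_dim(D, N)), frame),
               U[, 1:D])
  for (i in 1:5) {
    z <- rnorm(displacement_dim(D, N), sd = 0.5)
    C <- displacement_to_emission(z, frame)
    expect_lt(max(abs(crossprod(C) - diag(D))), 1e-10)
  }
  # pure within-subspace rotation leaves the subspace unchanged
  w <- rnorm(w_dim <- D * (D - 1) / 2)
  z_w <- combine_displacement(w, matrix(0, D, N - D))
  expect_lt(grassmann_distance(displacement_to_emission(z_w, frame),
                               U[, 1:D]), 1e-6)
  # matrix-exponential retraction also lands on the manifold
  z <- rnorm(displacement_dim(D, N), sd = 0.3)
  Ce <- displacement_to_emission(z, frame, retraction = "expm")
  expect_lt(max(abs(crossprod(Ce) - diag(D))), 1e-10)
})

test_that("principal angles match canonical examples and invariances", {
  set.seed(4)
  C1 <- random_stiefel(5, 2)
  expect_equal(principal_angles(C1, C1), c(0, 0), tolerance = 1e-7)
  e <- diag(2)
  expect_equal(principal_angles(e[, 1, drop = FALSE], e[, 2, drop = FALSE]),
               pi / 2)
  expect_equal(principal_angles(e[, 1, drop = FALSE],
                                matrix(c(1, 1) / sqrt(2))), pi / 4)
  # invariant to right-rotation of either argument
  for (i in 1:5) {
    C2 <- random_stiefel(5, 2)
    O <- cayley(build_skew(rnorm(1), matrix(0, 2, 0), 2, 2))
    expect_equal(principal_angles(C1, C2 %*% O), principal_angles(C1, C2),
                 tolerance = 1e-8)
  }
  expect_error(principal_angles(C1, random_stiefel(6, 2)), "dimensions")
})

test_that("Grassmann distance attains its bounds and known values", {
  E <- diag(4)
  expect_equal(grassmann_distance(E[, 1:2], E[, 1:2]), 0)
  expect_equal(grassmann_distance(E[, 1:2], E[, 3:4]), (pi / 2) * sqrt(2))
  expect_equal(grassmann_distance(E[, 1:2], E[, 3:4], normalized = TRUE), 1)
  # rotate one basis vector out of plane by 45 degrees: angles (0, pi/4)
  C2 <- cbind(E[, 1], cos(pi / 4) * E[, 2] + sin(pi / 4) * E[, 3])
  expect_equal(principal_angles(E[, 1:2], C2), c(0, pi / 4), tolerance = 1e-10)
  expect_equal(grassmann_distance(E[, 1:2], C2), pi / 4, tolerance = 1e-10)
})

test_that("Grassmann distance behaves as a metric on random subspaces", {
  set.seed(5)
  for (i in 1:10) {
    Cs <- replicate(3, random_stiefel(6, 2), simplify = FALSE)
    d12 <- grassmann_distance(Cs[[1]], Cs[[2]])
    d21 <- grassmann_distance(Cs[[2]], Cs[[1]])
    expect_equal(d12, d21)
    d13 <- grassmann_distance(Cs[[1]], Cs[[3]])
    d23 <- grassmann_distance(Cs[[2]], Cs[[3]])
    expect_lte(d13, d12 + d23 + 1e-8)
    # zero iff same column space
    O <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
    expect_lt(grassmann_distance(Cs[[1]], Cs[[1]] %*% O), 1e-6)
    expect_gt(d12, 1e-4)
  }
})

test_that("within-subspace rotations do not move the Grassmann point", {
  set.seed(6)
  D <- 3; N <- 7
  frame <- emission_frame(random_stiefel(N, N), D)
  nw <- D * (D - 1) / 2
  zeroV <- matrix(0, D, N - D)
  for (i in 1:5) {
    # the Cayley map of a block-diagonal skew generator is block-diagonal,
    # so any pure-w displacement spans the same subspace as the origin ...
    w1 <- rnorm(nw, sd = 0.6); w2 <- rnorm(nw, sd = 0.6)
    h1 <- displacement_to_emission(combine_displacement(w1, zeroV), frame)
    h2 <- displacement_to_emission(combine_displacement(w2, zeroV), frame)
    expect_lt(grassmann_distance(h1, h2), 1e-6)
    # ... and adding a shared pure-w component to two such displacements
    # leaves their (zero) Grassmann distance unchanged
    bump <- rnorm(nw, sd = 0.5)
    h1b <- displacement_to_emission(combine_displacement(w1 + bump, zeroV), frame)
    h2b <- displacement_to_emission(combine_displacement(w2 + bump, zeroV), frame)
    expect_lt(grassmann_distance(h1b, h2b), 1e-6)
  }
})

test_that("per-dimension drift angles recover constructed rotations", {
  E <- diag(4)
  C_list <- list(E[, 1:2], E[, 1:2], E[, 1:2])
  expect_equal(per_dimension_drift(C_list), matrix(0, 3, 2,
               dimnames = list(NULL, c("dim1", "dim2"))))
  # sign flip of a column is zero drift
  Cf <- cbind(E[, 1], -E[, 2])
  expect_equal(unname(per_dimension_drift(list(E[, 1:2], Cf))[2, ]), c(0, 0))
  # rotate column 2 by 30 degrees into an orthogonal direction
  a <- 30 * pi / 180
  Cr <- cbind(E[, 1], cos(a) * E[, 2] + sin(a) * E[, 3])
  ang <- per_dimension_drift(list(E[, 1:2], Cr))
  expect_equal(unname(ang[2, ]), c(0, 30), tolerance = 1e-8)
  expect_error(per_dimension_drift(list()), "empty")
})
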