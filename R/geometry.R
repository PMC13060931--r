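#' Dimension of the subspace-displacement vector
#'
#' A `D`-dimensional subspace of `R^N` that is allowed to rotate both within
#' itself and into the orthogonal complement is parametrized by a displacement
#' vector `z` of length `D(2N - D - 1)/2`: the `D(D-1)/2` strict upper-triangle
#' entries of a within-subspace rotation generator `W`, followed by the
#' `D(N-D)` entries of the out-of-subspace coupling block `V`.
#'
#' @param D Latent (subspace) dimension.
#' @param N Ambient (observation) dimension, `N >= D`.
#' @return Integer length of the displacement vector.
#' @export
displacement_dim <- function(D, N) {
  stopifnot(D >= 1, N >= D)
  as.integer(D * (2 * N - D - 1) / 2)
}

w_dim <- function(D) as.integer(D * (D - 1) / 2)

#' Split a displacement vector into its (w, V) parts
#'
#' The first `D(D-1)/2` entries are the strict upper-triangle of `W` in
#' row-major order; the remaining `D(N-D)` entries are `vec(V)` under
#' column-stacking. This convention is fixed package-wide.
#'
#' @param z Numeric displacement vector of length `displacement_dim(D, N)`.
#' @inheritParams displacement_dim
#' @return List with components `w` (length `D(D-1)/2`) and `V`
#'   (`D x (N-D)` matrix).
#' @export
split_displacement <- function(z, D, N) {
  nw <- w_dim(D)
  nz <- displacement_dim(D, N)
  if (length(z) != nz) {
    stop(sprintf("displacement has length %d; expected %d for D=%d, N=%d",
                 length(z), nz, D, N))
  }
  w <- if (nw > 0) z[seq_len(nw)] else numeric(0)
  rest <- if (nw > 0) z[-seq_len(nw)] else z
  V <- matrix(rest, nrow = D, ncol = N - D)
  list(w = w, V = V)
}

#' @rdname split_displacement
#' @param w Strict upper-triangle entries of `W` (row-major).
#' @param V `D x (N-D)` matrix.
#' @export
combine_displacement <- function(w, V) {
  c(w, as.vector(V))
}

# strict upper-triangular fill, row-major: (1,2),(1,3),...,(1,D),(2,3),...
# index matrices are memoized per D (this sits on the hot path of the
# displacement smoother)
.triu_idx_cache <- new.env(parent = emptyenv())

triu_idx <- function(D) {
  key <- as.character(D)
  idx <- .triu_idx_cache[[key]]
  if (is.null(idx)) {
    M <- matrix(0, D, D)
    idx <- which(upper.tri(M), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    .triu_idx_cache[[key]] <- idx
  }
  idx
}

triu_from_w <- function(w, D) {
  W <- matrix(0, D, D)
  if (D > 1) {
    idx <- triu_idx(D)
    if (length(w) != nrow(idx)) {
      stop(sprintf("w has length %d; expected %d for D=%d",
                   length(w), nrow(idx), D))
    }
    W[idx] <- w
  } else if (length(w) != 0) {
    stop("w must be empty when D = 1")
  }
  W
}

#' Build the skew-symmetric displacement generator
#'
#' Assembles `B = [[W - W', V], [-V', 0]]`, the `N x N` skew-symmetric matrix
#' generated by a displacement: `W` (strict upper-triangular, from `w`)
#' rotates within the current subspace, while `V` tilts the subspace into its
#' orthogonal complement.
#'
#' @inheritParams combine_displacement
#' @inheritParams displacement_dim
#' @return Skew-symmetric `N x N` matrix.
#' @export
build_skew <- function(w, V, D, N) {
  V <- as.matrix(V)
  if (D < N && (nrow(V) != D || ncol(V) != N - D)) {
    stop(sprintf("V is %d x %d; expected %d x %d", nrow(V), ncol(V), D, N - D))
  }
  W <- triu_from_w(w, D)
  B <- matrix(0, N, N)
  B[seq_len(D), seq_len(D)] <- W - t(W)
  if (D < N) {
    B[seq_len(D), (D + 1):N] <- V
    B[(D + 1):N, seq_len(D)] <- -t(V)
  }
  B
}

#' Cayley transform of a skew-symmetric matrix
#'
#' Maps a skew-symmetric `B` to the rotation `(I - B)(I + B)^{-1}`. For real
#' skew-symmetric `B` the matrix `I + B` is always invertible and the result
#' is orthogonal with determinant +1.
#'
#' @param B Skew-symmetric square matrix.
#' @param tol Tolerance for the skew-symmetry check.
#' @return Orthogonal matrix of the same size.
#' @export
cayley <- function(B, tol = 1e-8) {
  B <- as.matrix(B)
  if (nrow(B) != ncol(B)) stop("B must be square")
  if (max(abs(B + t(B))) > tol) {
    stop("B is not skew-symmetric to tolerance")
  }
  n <- nrow(B)
  (diag(n) - B) %*% solve(diag(n) + B)
}

#' Emission frame: fixed ambient coordinate axes
#'
#' The drifting emission matrix is expressed relative to a fixed orthonormal
#' basis `U_base` of the ambient space; the readout `O = [I_D; 0]` selects its
#' first `D` columns. In fitting, `U_base` is set from the principal
#' components of the training data.
#'
#' @param U_base `N x N` matrix with orthonormal columns.
#' @param D Subspace dimension.
#' @param tol Orthonormality tolerance.
#' @return Object of class `emission_frame`.
#' @export
emission_frame <- function(U_base, D, tol = 1e-8) {
  U_base <- as.matrix(U_base)
  N <- nrow(U_base)
  if (ncol(U_base) != N) stop("U_base must be square (a full ambient basis)")
  if (D > N) stop("D must not exceed N")
  if (max(abs(crossprod(U_base) - diag(N))) > tol) {
    stop("U_base columns are not orthonormal to tolerance")
  }
  structure(list(U_base = U_base, D = as.integer(D), N = as.integer(N)),
            class = "emission_frame")
}

#' @export
print.emission_frame <- function(x, ...) {
  cat(sprintf("Emission frame: ambient N = %d, subspace D = %d\n", x$N, x$D))
  invisible(x)
}

#' Map a displacement to an orthonormal emission matrix
#'
#' Computes `C = U_base f(B(z)) O_readout`, where `B(z)` is the skew generator
#' of the displacement and `f` is a retraction onto the rotation group
#' (Cayley transform by default, matrix exponential optionally). The result
#' has exactly orthonormal columns up to floating-point error.
#'
#' @param z Displacement vector (see [split_displacement()]).
#' @param frame An [emission_frame()].
#' @param retraction `"cayley"` (default) or `"expm"`.
#' @return `N x D` matrix on the Stiefel manifold.
#' @export
displacement_to_emission <- function(z, frame, retraction = c("cayley", "expm")) {
  retraction <- match.arg(retraction)
  stopifnot(inherits(frame, "emission_frame"))
  D <- frame$D; N <- frame$N
  parts <- split_displacement(z, D, N)
  B <- build_skew(parts$w, parts$V, D, N)
  Fm <- if (retraction == "cayley") cayley(B) else
    as.matrix(Matrix::expm(B))
  frame$U_base %*% Fm[, seq_len(D), drop = FALSE]
}

#' Principal angles between two subspaces
#'
#' Canonical angles between the column spaces of two orthonormal bases,
#' computed from the singular values of `C1' C2` (clipped into `[-1, 1]`
#' before `acos` for numerical safety). Invariant to right-rotation of either
#' basis.
#'
#' @param C1,C2 `N x D` matrices with orthonormal columns.
#' @return Nondecreasing vector of `D` angles in `[0, pi/2]` (radians).
#' @export
principal_angles <- function(C1, C2) {
  C1 <- as.matrix(C1); C2 <- as.matrix(C2)
  if (!all(dim(C1) == dim(C2))) stop("C1 and C2 must have the same dimensions")
  s <- svd(crossprod(C1, C2), nu = 0, nv = 0)$d
  s <- pmin(pmax(s, -1), 1)
  sort(acos(s))
}

#' Grassmann (geodesic) distance between subspaces
#'
#' Root-sum-of-squares of the principal angles. The normalized version
#' divides by the supremum `(pi/2) sqrt(D)`, mapping into `[0, 1]` (1 means
#' the subspaces are fully orthogonal).
#'
#' @inheritParams principal_angles
#' @param normalized Divide by the maximum attainable distance?
#' @return Nonnegative scalar.
#' @export
grassmann_distance <- function(C1, C2, normalized = FALSE) {
  th <- principal_angles(C1, C2)
  d <- sqrt(sum(th^2))
  if (normalized) d <- d / ((pi / 2) * sqrt(length(th)))
  d
}

#' Per-dimension drift angles across a sequence of emission matrices
#'
#' For each block `k` and subspace axis `d`, the angle (degrees) between
#' column `d` of the reference emission matrix and column `d` of block `k`'s,
#' using the absolute inner product so a sign flip counts as zero drift.
#' Columns are identified across blocks by index: the within-subspace
#' rotation is an explicit latent in this model, so axes keep their identity.
#'
#' @param C_list List of `N x D` orthonormal matrices (one per block).
#' @param reference Index of the reference block (default first).
#' @return `length(C_list) x D` matrix of angles in degrees.
#' @export
per_dimension_drift <- function(C_list, reference = 1L) {
  if (length(C_list) == 0) stop("C_list is empty")
  if (reference < 1 || reference > length(C_list)) stop("invalid reference index")
  Cref <- as.matrix(C_list[[reference]])
  D <- ncol(Cref)
  ang <- t(vapply(C_list, function(Ck) {
    ip <- abs(colSums(Cref * as.matrix(Ck)))
    acos(pmin(pmax(ip, -1), 1)) * 180 / pi
  }, numeric(D)))
  ang <- matrix(ang, ncol = D)
  colnames(ang) <- paste0("dim", seq_len(D))
  ang
}
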