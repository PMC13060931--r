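#' Pairwise subspace drift matrix
#'
#' Normalized Grassmann distance between every pair of block emission
#' matrices: symmetric, zero diagonal, entries in `[0, 1]`.
#'
#' @param C_blocks List of `N x D` orthonormal matrices.
#' @return `B x B` matrix.
#' @export
pairwise_drift_matrix <- function(C_blocks) {
  B <- length(C_blocks)
  if (B < 1) stop("C_blocks is empty")
  M <- matrix(0, B, B)
  if (B > 1) for (i in seq_len(B - 1)) for (j in (i + 1):B) {
    M[i, j] <- M[j, i] <- grassmann_distance(C_blocks[[i]], C_blocks[[j]],
                                             normalized = TRUE)
  }
  M
}

#' Sliding-window PCA subspace drift on raw data
#'
#' Model-free drift diagnostic: trials are concatenated within each sliding
#' window, the top principal subspace is extracted, and the pairwise
#' normalized Grassmann distance between window subspaces is returned. On
#' stationary data the off-diagonal entries stay small; drifting data shows
#' a growing band away from the diagonal.
#'
#' @param data A [trial_data()] object.
#' @param n_components Subspace dimension per window.
#' @param window Window length in trials.
#' @param stride Trials between window starts (default `window / 4`,
#'   at least 1).
#' @param center Subtract the window mean before PCA?
#' @return Pairwise distance matrix between windows, with attribute
#'   `"starts"` giving each window's first trial.
#' @export
sliding_window_pca_drift <- function(data, n_components, window,
                                     stride = NULL, center = TRUE) {
  stopifnot(inherits(data, "trial_data"))
  if (window > data$K) stop("window exceeds the number of trials")
  if (n_components > data$N) stop("n_components exceeds the channel count")
  if (is.null(stride)) stride <- max(1L, floor(window / 4))
  starts <- seq(1L, data$K - window + 1L, by = stride)
  subs <- lapply(starts, function(s) {
    Y <- do.call(rbind, data$y[s:(s + window - 1)])
    if (center) Y <- sweep(Y, 2, colMeans(Y))
    sv <- svd(Y, nu = 0, nv = n_components)
    if (sv$d[n_components] < 1e-12) {
      stop("window data has rank below n_components")
    }
    sv$v
  })
  M <- pairwise_drift_matrix(subs)
  attr(M, "starts") <- starts
  M
}

#' Fraction of latent variance per dimension
#'
#' Pools the smoothed second moments `E[x x']` over trials and timesteps and
#' returns the fraction of the total attributable to each latent coordinate.
#' With orthonormal emission columns, this is also each axis's share of the
#' signal variance it contributes to the observations.
#'
#' @param xpost An [smds()] / [lds()] fit, an [estep_states()] result, or a
#'   list of `state_posterior` objects.
#' @return Length-`D` vector of nonnegative fractions summing to 1.
#' @export
variance_per_dimension <- function(xpost) {
  posts <- if (inherits(xpost, c("smds", "lds"))) xpost$xpost else xpost
  if (is.list(posts) && !is.null(posts$posts)) posts <- posts$posts
  if (length(posts) == 0) stop("no state posteriors available")
  D <- ncol(posts[[1]]$mean)
  tot <- rep(0, D)
  for (po in posts) {
    pv <- apply(po$var, 3, diag)
    pv <- if (is.matrix(pv)) rowSums(pv) else sum(pv)
    tot <- tot + pv + colSums(po$mean^2)
  }
  tot / sum(tot)
}

#' Assemble a drift report from a fitted SMDS
#'
#' Bundles the pairwise normalized Grassmann-distance matrix over block
#' emissions, per-dimension drift angles against a reference block, the peak
#' drift per dimension, and each dimension's share of latent variance.
#'
#' @param fit An [smds()] fit.
#' @param reference Reference block position for per-dimension angles
#'   (default the first block).
#' @param peak `"reference"` (default) takes each dimension's peak over the
#'   angles to the reference block; `"all-pairs"` takes the maximum angle
#'   over every pair of blocks.
#' @param scores Optional user-supplied per-dimension score vector (e.g. a
#'   behavioral-decoding weight) carried through for external joins.
#' @return Object of class `drift_report` with fields `pairwise`
#'   (`B x B`), `per_dim` (`B x D`, degrees), `peak_per_dim` (degrees),
#'   `variance_per_dim`, `blocks`, and optional `scores`.
#' @export
drift_report <- function(fit, reference = 1L, peak = c("reference", "all-pairs"),
                         scores = NULL) {
  stopifnot(inherits(fit, "smds"))
  peak <- match.arg(peak)
  per_dim <- per_dimension_drift(fit$C_blocks, reference = reference)
  peak_per_dim <- if (peak == "reference") apply(per_dim, 2, max) else {
    D <- ncol(fit$C_blocks[[1]])
    vapply(seq_len(D), function(d) {
      cols <- vapply(fit$C_blocks, function(C) C[, d],
                     numeric(nrow(fit$C_blocks[[1]])))
      ip <- pmin(pmax(abs(crossprod(cols)), -1), 1)
      max(acos(ip)) * 180 / pi
    }, numeric(1))
  }
  structure(list(pairwise = pairwise_drift_matrix(fit$C_blocks),
                 per_dim = per_dim,
                 peak_per_dim = peak_per_dim,
                 variance_per_dim = variance_per_dimension(fit),
                 blocks = fit$blocks,
                 scores = scores),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  B <- length(x$blocks); D <- ncol(x$per_dim)
  cat(sprintf("Drift report: %d blocks, %d latent dimensions\n", B, D))
  off <- x$pairwise[upper.tri(x$pairwise)]
  if (length(off)) {
    cat(sprintf("  normalized Grassmann distance: median %.3f, max %.3f\n",
                stats::median(off), max(off)))
  }
  cat("  peak drift per dimension (degrees):",
      paste(sprintf("%.1f", x$peak_per_dim), collapse = " "), "\n")
  cat("  latent variance fraction per dimension:",
      paste(sprintf("%.2f", x$variance_per_dim), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.drift_report <- function(x, which = c("pairwise", "per_dim", "scatter"),
                              ...) {
  which <- match.arg(which)
  if (which == "pairwise") {
    graphics::image(x$blocks, x$blocks, x$pairwise, xlab = "block",
                    ylab = "block", main = "pairwise subspace drift", ...)
  } else if (which == "per_dim") {
    graphics::matplot(x$blocks, x$per_dim, type = "l", lty = 1,
                      xlab = "block", ylab = "drift angle (degrees)", ...)
  } else {
    graphics::plot(x$variance_per_dim, x$peak_per_dim, pch = 16,
                   xlab = "variance fraction", ylab = "peak drift (degrees)",
                   ...)
    graphics::text(x$variance_per_dim, x$peak_per_dim,
                   labels = seq_along(x$peak_per_dim), pos = 3)
  }
  invisible(x)
}

#' Serialize a drift report to JSON (and back)
#'
#' @param report A [drift_report()].
#' @param path File path.
#' @return `write_drift_report` returns `path` invisibly;
#'   `read_drift_report` reconstructs the `drift_report`.
#' @export
write_drift_report <- function(report, path) {
  stopifnot(inherits(report, "drift_report"))
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_drift_report
#' @export
read_drift_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$pairwise <- as.matrix(obj$pairwise)
  obj$per_dim <- as.matrix(obj$per_dim)
  if (is.null(obj$scores) || length(obj$scores) == 0) obj$scores <- NULL
  structure(obj, class = "drift_report")
}
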