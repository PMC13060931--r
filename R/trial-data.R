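#' Trial-structured multichannel time series
#'
#' Container for `K` trials of multichannel observations, each a `T_k x N`
#' matrix (timesteps by channels; trial lengths may differ), together with a
#' nondecreasing trial-to-block assignment. A block is a consecutive group of
#' trials that shares one emission matrix in the drift chain; `block = 1:K`
#' gives per-trial drift.
#'
#' @param y List of numeric matrices, all with `N` columns, or a
#'   `K x T x N` array (converted to a list of `T x N` matrices).
#' @param block Integer vector of length `K`, nondecreasing. For a complete
#'   dataset the labels cover `1..B` contiguously; subsets produced by
#'   train/test splitting keep their original labels (with gaps).
#' @param validate Check finiteness and block structure?
#' @return Object of class `trial_data` with fields `y`, `block`, `N`, `K`.
#' @export
trial_data <- function(y, block = NULL, validate = TRUE) {
  if (is.array(y) && length(dim(y)) == 3) {
    y <- lapply(seq_len(dim(y)[1]), function(k) matrix(y[k, , ], ncol = dim(y)[3]))
  }
  if (!is.list(y) || length(y) == 0) stop("y must be a non-empty list of trials")
  y <- lapply(y, as.matrix)
  K <- length(y)
  N <- ncol(y[[1]])
  if (is.null(block)) block <- seq_len(K)
  block <- as.integer(block)
  if (validate) {
    for (k in seq_len(K)) {
      if (ncol(y[[k]]) != N) {
        stop(sprintf("trial %d has %d channels; expected %d", k, ncol(y[[k]]), N))
      }
      if (!all(is.finite(y[[k]]))) {
        bad <- which(!is.finite(y[[k]]), arr.ind = TRUE)[1, ]
        stop(sprintf("non-finite value in trial %d (timestep %d, channel %d)",
                     k, bad[1], bad[2]))
      }
    }
    if (length(block) != K) stop("block must have one entry per trial")
    if (any(diff(block) < 0)) stop("block assignment must be nondecreasing")
  }
  structure(list(y = y, block = block, N = as.integer(N), K = as.integer(K)),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  Ts <- vapply(x$y, nrow, integer(1))
  cat(sprintf("Trial dataset: %d trials, %d channels, %d block(s)\n",
              x$K, x$N, length(unique(x$block))))
  cat(sprintf("  trial lengths: %s\n",
              if (length(unique(Ts)) == 1) sprintf("%d timesteps each", Ts[1])
              else sprintf("%d-%d timesteps", min(Ts), max(Ts))))
  invisible(x)
}

#' Subset trials of a dataset
#'
#' Keeps original block labels, so a training subset remembers where its
#' blocks sit in the session's drift chain.
#'
#' @param x A [trial_data()] object.
#' @param i Trial indices.
#' @param ... Unused.
#' @export
`[.trial_data` <- function(x, i, ...) {
  trial_data(x$y[i], block = x$block[i], validate = FALSE)
}

#' Subset a dataset by block labels
#'
#' @param data A [trial_data()] object.
#' @param blocks Block labels to keep.
#' @return A [trial_data()] with only the trials in those blocks.
#' @export
subset_blocks <- function(data, blocks) {
  data[data$block %in% blocks]
}

#' Write / read a trial dataset as JSON
#'
#' Self-describing plain-text serialization: channel count, per-trial
#' observation matrices (ragged lengths preserved), the block vector, and an
#' optional ground-truth group for simulated data (displacement path and
#' latent states).
#'
#' @param data A [trial_data()] object.
#' @param path File path.
#' @param truth Optional list (e.g. simulation ground truth) stored verbatim.
#' @return `write_trial_data` returns `path` invisibly; `read_trial_data`
#'   returns a [trial_data()] (with a `truth` attribute when present).
#' @export
write_trial_data <- function(data, path, truth = NULL) {
  stopifnot(inherits(data, "trial_data"))
  obj <- list(
    meta = list(N = data$N, K = data$K, format = "smds-trial-data-v1"),
    block_of_trial = data$block,
    y = lapply(data$y, function(m) unclass(m))
  )
  if (!is.null(truth)) obj$truth <- truth
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$meta$N)) stop("not a trial dataset file (missing meta)")
  ylist <- obj$y
  if (is.matrix(ylist) || is.array(ylist)) {
    ylist <- lapply(seq_len(dim(ylist)[1]), function(k) {
      matrix(ylist[k, , ], ncol = dim(ylist)[3])
    })
  } else {
    ylist <- lapply(ylist, function(m) as.matrix(m))
  }
  if (length(ylist) != obj$meta$K) {
    stop(sprintf("file lists K=%d trials but contains %d",
                 obj$meta$K, length(ylist)))
  }
  blk <- as.integer(obj$block_of_trial)
  if (length(blk) != length(ylist)) {
    stop(sprintf("block vector has length %d for %d trials",
                 length(blk), length(ylist)))
  }
  out <- trial_data(ylist, block = blk)
  if (!is.null(obj$truth)) attr(out, "truth") <- obj$truth
  out
}

#' Block-level train/test splits
#'
#' Draws `n_splits` reproducible splits, each holding out `n_heldout` blocks
#' sampled without replacement; held-out blocks never appear in training.
#'
#' @param data A [trial_data()] object.
#' @param n_splits Number of splits.
#' @param n_heldout Held-out blocks per split.
#' @param seed Integer seed.
#' @return List of `n_splits` lists with integer fields `train` and
#'   `heldout` (block labels).
#' @export
make_splits <- function(data, n_splits, n_heldout, seed = 1L) {
  blocks <- sort(unique(data$block))
  if (n_heldout >= length(blocks)) {
    stop("n_heldout must be smaller than the number of blocks")
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  lapply(seq_len(n_splits), function(s) {
    held <- sort(sample(blocks, n_heldout))
    list(train = setdiff(blocks, held), heldout = held)
  })
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
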