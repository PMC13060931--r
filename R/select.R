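#' Latent dimensionality selection by held-out likelihood
#'
#' Fits a model across a grid of latent state dimensions and block-level
#' train/test splits, evaluates the exact marginal log-likelihood on the
#' held-out blocks (drifting emissions are interpolated from the drift
#' posterior for SMDS), and reports the saturation dimension: the smallest
#' dimension whose mean held-out log-likelihood is within one standard error
#' (across splits) of the best.
#'
#' @param data A [trial_data()] object.
#' @param dims Integer vector of candidate latent dimensions.
#' @param model `"smds"` or `"lds"`.
#' @param n_splits Number of train/test splits.
#' @param n_heldout Held-out blocks per split (default: 10% of blocks,
#'   at least 2).
#' @param control Control list for the chosen model.
#' @param seed Integer seed for the splits.
#' @param splits Optional precomputed [make_splits()] result (overrides
#'   `n_splits`/`n_heldout`/`seed`).
#' @return Object of class `dim_selection`: a results data frame
#'   (`model`, `D`, `split`, `loglik`), the per-dimension summary
#'   (`mean`, `se`), and `chosen`, the saturation dimension.
#' @export
select_dimension <- function(data, dims, model = c("smds", "lds"),
                             n_splits = 3, n_heldout = NULL,
                             control = NULL, seed = 1L, splits = NULL) {
  model <- match.arg(model)
  if (is.null(control)) {
    control <- if (model == "smds") smds_control() else lds_control()
  }
  blocks <- sort(unique(data$block))
  if (is.null(n_heldout)) n_heldout <- max(2L, ceiling(0.1 * length(blocks)))
  if (is.null(splits)) splits <- make_splits(data, n_splits, n_heldout, seed)

  rows <- list()
  for (s in seq_along(splits)) {
    train <- subset_blocks(data, splits[[s]]$train)
    test <- subset_blocks(data, splits[[s]]$heldout)
    for (D in dims) {
      ll <- if (model == "smds") {
        fit <- smds(train, D, control = control)
        suppressWarnings(heldout_loglik(fit, test))
      } else {
        fit <- lds(train, D, control = control)
        lds_loglik(fit$params, test)
      }
      rows[[length(rows) + 1]] <- data.frame(model = model, D = D, split = s,
                                             loglik = ll)
    }
  }
  res <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(res, res$D), function(d) {
    data.frame(D = d$D[1], mean = mean(d$loglik),
               se = stats::sd(d$loglik) / sqrt(nrow(d)))
  }))
  smry <- smry[order(smry$D), ]
  structure(list(results = res, summary = smry,
                 chosen = saturation_dimension(smry$mean, smry$se, smry$D),
                 model = model),
            class = "dim_selection")
}

#' One-standard-error saturation rule
#'
#' Given mean held-out log-likelihoods over a dimension grid, returns the
#' smallest dimension whose mean is within one standard error of the best
#' dimension's mean.
#'
#' @param means Mean held-out log-likelihood per dimension.
#' @param ses Standard error (across splits) per dimension.
#' @param dims The dimension grid (defaults to `seq_along(means)`).
#' @return The saturation dimension.
#' @export
saturation_dimension <- function(means, ses, dims = seq_along(means)) {
  best <- which.max(means)
  thresh <- means[best] - ses[best]
  dims[min(which(means >= thresh))]
}

#' @export
print.dim_selection <- function(x, ...) {
  cat(sprintf("Held-out dimensionality selection (%s)\n", toupper(x$model)))
  print(format(x$summary, digits = 6), row.names = FALSE)
  cat(sprintf("saturation dimension (1-SE rule): %d\n", x$chosen))
  invisible(x)
}

#' @export
plot.dim_selection <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$D, s$mean, type = "b", pch = 16,
                 xlab = "latent dimension", ylab = "held-out log-likelihood", ...)
  graphics::arrows(s$D, s$mean - s$se, s$D, s$mean + s$se,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(v = x$chosen, lty = 2)
  invisible(x)
}
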