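#' Greedy layerwise pretraining of a deep belief network
#'
#' Trains a stack of RBMs: the first (Gaussian-visible) on the standardized
#' input data, each subsequent (Bernoulli) on the hidden activation
#' probabilities of the layer below. Seeding is the caller's responsibility
#' (the training entry points seed once per run), so two calls under the
#' same RNG state produce bit-identical stacks.
#'
#' @param dims Integer vector `c(n_input, h1, h2, ...)`.
#' @param data Matrix with `n_input` columns (standardized).
#' @param config A [train_config()] (uses `pretrain_epochs`, `batch_size`,
#'   `learning_rate`, `cd_steps`).
#' @return A `DBNStack`: list with `layers` (list of `RBMParams`), `dims`,
#'   and `recon_traces` (per-layer vector of mean reconstruction error per
#'   epoch).
#' @export
dbn_pretrain <- function(dims, data, config) {
  if (length(dims) < 2L) stop("dims must chain at least input -> one hidden layer")
  if (ncol(data) != dims[[1]])
    stop("data has ", ncol(data), " columns; dims start with ", dims[[1]])
  layers <- list()
  traces <- list()
  x <- data
  batch_size <- min(config$batch_size, nrow(data))
  for (l in seq_len(length(dims) - 1L)) {
    rbm <- rbm_new(dims[[l]], dims[[l + 1L]],
                   if (l == 1L) "gaussian" else "bernoulli")
    state <- NULL
    trace <- numeric(config$pretrain_epochs)
    for (epoch in seq_len(config$pretrain_epochs)) {
      ord <- sample.int(nrow(x))
      errs <- c()
      for (start in seq(1L, nrow(x), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, nrow(x))]
        upd <- rbm_cd_update(rbm, x[idx, , drop = FALSE], config, state)
        rbm <- upd$rbm; state <- upd$state
        errs <- c(errs, upd$recon_error)
      }
      trace[[epoch]] <- mean(errs)
    }
    layers[[l]] <- rbm
    traces[[l]] <- trace
    x <- rbm_hidden_probs(rbm, x)
  }
  structure(list(layers = layers, dims = as.integer(dims), recon_traces = traces),
            class = "DBNStack")
}

#' Propagate data through a pretrained DBN stack
#'
#' @param stack A [dbn_pretrain()] result.
#' @param x Matrix with `stack$dims[1]` columns.
#' @return Matrix of top-layer hidden probabilities.
#' @export
dbn_transform <- function(stack, x) {
  for (rbm in stack$layers)
    x <- rbm_hidden_probs(rbm, x)
  x
}
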