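## Restricted Boltzmann machines trained with contrastive divergence, the
## generative building block of the stage-1 pretraining. Visible units are
## either Bernoulli (binary probabilities) or Gaussian with unit variance
## (for standardized real-valued inputs); hidden units are always Bernoulli.

#' Initialize an RBM
#'
#' @param n_visible,n_hidden Layer widths.
#' @param visible_kind `"gaussian"` for standardized real inputs,
#'   `"bernoulli"` for probabilities in `[0, 1]`.
#' @param init_sd Standard deviation of the Gaussian weight init (drawn from
#'   the current RNG stream).
#' @return An `RBMParams` object (`W` n_visible x n_hidden, visible bias `a`,
#'   hidden bias `b`).
#' @export
rbm_new <- function(n_visible, n_hidden, visible_kind = c("gaussian", "bernoulli"),
                    init_sd = 0.01) {
  visible_kind <- match.arg(visible_kind)
  structure(list(W = matrix(stats::rnorm(n_visible * n_hidden, sd = init_sd),
                            n_visible, n_hidden),
                 a = numeric(n_visible), b = numeric(n_hidden),
                 visible_kind = visible_kind),
            class = "RBMParams")
}

#' Hidden-unit activation probabilities
#'
#' @param rbm An [rbm_new()] model.
#' @param v Matrix of visible configurations (rows = samples).
#' @return Matrix of hidden probabilities.
#' @export
rbm_hidden_probs <- function(rbm, v) {
  .sigmoid(sweep(v %*% rbm$W, 2L, rbm$b, "+"))
}

.rbm_visible_mean <- function(rbm, h) {
  pre <- sweep(h %*% t(rbm$W), 2L, rbm$a, "+")
  if (rbm$visible_kind == "bernoulli") .sigmoid(pre) else pre
}

#' One contrastive-divergence update
#'
#' Runs CD-k from the batch, forms the standard positive-minus-negative
#' statistics, and applies one Adam ascent step on the approximate
#' log-likelihood gradient. Hidden states are sampled at every Gibbs step;
#' visible reconstructions use mean values (the usual variance-reduction
#' choice).
#'
#' @param rbm An `RBMParams` model.
#' @param batch Matrix of visible samples (columns = `n_visible`); must be
#'   standardized when `visible_kind = "gaussian"`.
#' @param config A [train_config()] (uses `learning_rate`, `cd_steps`).
#' @param state Optional Adam state from a previous call.
#' @return List with `rbm`, `state`, and `recon_error` (mean squared
#'   reconstruction error of the batch).
#' @export
rbm_cd_update <- function(rbm, batch, config, state = NULL) {
  if (ncol(batch) != nrow(rbm$W))
    stop("batch has ", ncol(batch), " columns; RBM expects ", nrow(rbm$W))
  n <- nrow(batch)
  h0 <- rbm_hidden_probs(rbm, batch)
  h_sample <- matrix(stats::rbinom(length(h0), 1L, h0), nrow(h0), ncol(h0))
  v_neg <- batch
  for (k in seq_len(config$cd_steps)) {
    v_neg <- .rbm_visible_mean(rbm, h_sample)
    h_neg <- rbm_hidden_probs(rbm, v_neg)
    if (k < config$cd_steps)
      h_sample <- matrix(stats::rbinom(length(h_neg), 1L, h_neg),
                         nrow(h_neg), ncol(h_neg))
  }
  grad <- list(W = -(crossprod(batch, h0) - crossprod(v_neg, h_neg)) / n,
               a = -colMeans(batch - v_neg),
               b = -colMeans(h0 - h_neg))
  params <- list(W = rbm$W, a = rbm$a, b = rbm$b)
  if (is.null(state)) state <- adam_state(params)
  upd <- adam_step(params, grad, state, config$learning_rate)
  if (!all(vapply(upd$params, function(p) all(is.finite(p)), logical(1))))
    stop("non-finite RBM parameters after update (learning rate too high?)")
  rbm$W <- upd$params$W
  rbm$a <- as.numeric(upd$params$a)
  rbm$b <- as.numeric(upd$params$b)
  list(rbm = rbm, state = upd$state,
       recon_error = mean((batch - v_neg)^2))
}

#' Exact log-likelihood gradient of a Bernoulli RBM
#'
#' Enumerates all 2^n_visible visible configurations to compute the exact
#' model expectation, giving the exact gradient of the mean data
#' log-likelihood. Tractable only for toy models; serves as the correctness
#' oracle for the contrastive-divergence code path.
#'
#' @param rbm A Bernoulli-visible `RBMParams` with small `n_visible`.
#' @param data Matrix of binary visible samples.
#' @return List with gradient components `W`, `a`, `b` (ascent direction).
#' @export
rbm_exact_loglik_grad <- function(rbm, data) {
  if (rbm$visible_kind != "bernoulli")
    stop("exact gradient implemented for Bernoulli visible units only")
  nv <- nrow(rbm$W)
  if (nv > 16L) stop("enumeration limited to n_visible <= 16")
  n <- nrow(data)
  ## positive phase: exact E[h | v] under the data
  h_data <- rbm_hidden_probs(rbm, data)
  pos_W <- crossprod(data, h_data) / n
  pos_a <- colMeans(data)
  pos_b <- colMeans(h_data)
  ## negative phase: exact model expectation by enumeration of v
  states <- as.matrix(expand.grid(rep(list(0:1), nv)))[, nv:1, drop = FALSE]
  colnames(states) <- NULL
  pre_h <- sweep(states %*% rbm$W, 2L, rbm$b, "+")
  log_p <- states %*% rbm$a + rowSums(log1p(exp(pre_h)))
  log_p <- log_p - max(log_p)
  p <- exp(log_p) / sum(exp(log_p))
  h_model <- .sigmoid(pre_h)
  neg_W <- crossprod(states * as.numeric(p), h_model)
  neg_a <- colSums(states * as.numeric(p))
  neg_b <- colSums(h_model * as.numeric(p))
  list(W = pos_W - neg_W, a = pos_a - neg_a, b = pos_b - neg_b)
}
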