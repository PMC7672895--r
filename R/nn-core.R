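## Minimal dense-network machinery shared by both stage models: activations,
## softmax + cross-entropy, inverted dropout, and an Adam optimizer operating
## on nested lists of parameter arrays. Everything is plain matrix algebra so
## training is bit-reproducible given (seed, config, data order).

.LEAKY_SLOPE <- 0.01

#' Leaky rectified linear activation
#' @param x Numeric array.
#' @param slope Negative-side slope (package-wide default 0.01).
#' @return Array of the same shape.
#' @export
leaky_relu <- function(x, slope = .LEAKY_SLOPE) {
  x * ifelse(x > 0, 1, slope)
}

.leaky_relu_grad <- function(x, slope = .LEAKY_SLOPE) {
  ifelse(x > 0, 1, slope)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise softmax
#' @param z Numeric matrix of logits (rows = samples).
#' @return Matrix of row distributions summing to 1.
#' @export
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## Mean cross-entropy of row distributions p against integer labels y (0-based)
.cross_entropy <- function(p, y) {
  idx <- cbind(seq_len(nrow(p)), y + 1L)
  -mean(log(pmax(p[idx], 1e-300)))
}

## ---- Adam over nested parameter lists ------------------------------------

.zeros_like <- function(p) {
  if (is.list(p)) lapply(p, .zeros_like) else array(0, dim = dim(p) %||% length(p))
}

adam_state <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}

## Applies one Adam descent step; grads mirror the structure of params.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        # gradient lists may be assembled in reverse (backprop) order:
        # match components by name where names exist
        key <- names(p)[k]
        gk <- if (!is.null(key) && nzchar(key) && !is.null(g[[key]])) g[[key]] else g[[k]]
        r <- walk(p[[k]], gk, m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

## ---- misc helpers ---------------------------------------------------------

## He-style Gaussian init for a dense layer (uses the current RNG stream)
.dense_init <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

## Inverted dropout mask: scales kept units by 1/(1-rate) so inference needs
## no rescaling. rate = 0 returns NULL (no-op).
.dropout_mask <- function(nrow, ncol, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(nrow * ncol, 1L, 1 - rate) / (1 - rate), nrow, ncol)
}

.affine <- function(x, layer) sweep(x %*% layer$W, 2L, layer$b, "+")

#' Training configuration
#'
#' Bundles the optimization hyper-parameters shared by both stage models.
#' Defaults follow the method's stated protocol: Adam with learning rate
#' 1e-4, batches of 500, dropout 0.5 after every hidden layer, early
#' stopping on validation loss.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size (clipped to the data size).
#' @param dropout Dropout rate in `[0, 1)`.
#' @param max_epochs Maximum fine-tuning epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement of at least `min_delta`).
#' @param min_delta Minimum validation-loss improvement that resets patience.
#' @param seed Integer seed controlling every random choice during training.
#' @param cd_steps Gibbs steps per contrastive-divergence update.
#' @param pretrain_epochs Epochs of layerwise RBM pretraining.
#' @param val_fraction Fraction of the training data held out for early
#'   stopping.
#' @return A `TrainConfig` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 500L, dropout = 0.5,
                         max_epochs = 100L, patience = 10L, min_delta = 1e-4,
                         seed = 1L, cd_steps = 1L, pretrain_epochs = 5L,
                         val_fraction = 0.1) {
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 dropout = dropout, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 seed = as.integer(seed), cd_steps = as.integer(cd_steps),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 val_fraction = val_fraction),
            class = "TrainConfig")
}

## Stratified train/validation index split (uses current RNG stream).
.stratified_split <- function(y, val_fraction) {
  val <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    n_val <- max(1L, round(length(idx) * val_fraction))
    if (length(idx) > 1L)
      val <- c(val, sample(idx, min(n_val, length(idx) - 1L)))
  }
  sort(val)
}
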