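## Stage-2 fold classifier: a 1-D convolutional network over the fragment
## vector. Layer stack: COV1 (10 one-dimensional filters, kernel 10, stride
## 1) -> MP1 (max-pool width 10, stride 1) -> stacking of the channel
## outputs into a 2-D map -> COV2 (100 filters spanning the full stack
## height, kernel width 10) -> MP2 (width 5, stride 5; pool height clipped
## to the map height of 1) -> FC1 -> FC2 -> softmax. Convolutions use
## 'valid' (no) padding, so for the default 100-long input the shapes run
## 100 -> 91x10 -> 82x10 -> 10x82 -> 1x73x100 -> 1x14x100 -> 1400.
## Convolutions are evaluated as im2col matrix products.

#' Construct a (untrained) fold-classification CNN
#'
#' @param n_input Length of the fragment vector (= number of fragment
#'   classes; default 100).
#' @param n_folds Number of fold classes.
#' @param n_filters1,kernel1,pool1 First convolution/pooling block: filter
#'   count, kernel width, pool width (stride 1).
#' @param n_filters2,kernel2 Second convolution block: filter count and
#'   kernel width (kernel height always equals `n_filters1`, the stack
#'   height).
#' @param pool2,pool2_stride Second pooling block (width, stride).
#' @param fc_width Width of the two fully-connected layers.
#' @param dropout_rate Dropout applied after FC1 and FC2 in training.
#' @param init `"zero"` or `"random"` weight initialization.
#' @return A `FoldCNN` object carrying its deterministic shape pipeline in
#'   `$shapes`.
#' @export
fold_cnn_new <- function(n_input = 100L, n_folds = 27L,
                         n_filters1 = 10L, kernel1 = 10L, pool1 = 10L,
                         n_filters2 = 100L, kernel2 = 10L,
                         pool2 = 5L, pool2_stride = 5L,
                         fc_width = 100L, dropout_rate = 0.5,
                         init = c("zero", "random")) {
  init <- match.arg(init)
  n1 <- n_input - kernel1 + 1L            # conv1 output positions
  n2 <- n1 - pool1 + 1L                   # pool1 output positions
  n3 <- n2 - kernel2 + 1L                 # conv2 output positions
  n4 <- if (n3 >= pool2) (n3 - pool2) %/% pool2_stride + 1L else 0L
  if (min(n1, n2, n3, n4) < 1L)
    stop("input length ", n_input, " too short for the layer stack ",
         "(shape pipeline ", n_input, " -> ", n1, " -> ", n2, " -> ", n3,
         " -> ", n4, ")")
  mk <- function(n_in, n_out) {
    if (init == "zero") list(W = matrix(0, n_in, n_out), b = numeric(n_out))
    else .dense_init(n_in, n_out)
  }
  structure(list(
    conv1 = mk(kernel1, n_filters1),
    conv2 = mk(n_filters1 * kernel2, n_filters2),
    fc1 = mk(n4 * n_filters2, fc_width),
    fc2 = mk(fc_width, fc_width),
    out = mk(fc_width, as.integer(n_folds)),
    n_input = as.integer(n_input), n_folds = as.integer(n_folds),
    n_filters1 = as.integer(n_filters1), kernel1 = as.integer(kernel1),
    pool1 = as.integer(pool1),
    n_filters2 = as.integer(n_filters2), kernel2 = as.integer(kernel2),
    pool2 = as.integer(pool2), pool2_stride = as.integer(pool2_stride),
    fc_width = as.integer(fc_width), dropout_rate = dropout_rate,
    shapes = list(conv1 = c(n1, n_filters1), pool1 = c(n2, n_filters1),
                  stack = c(n_filters1, n2), conv2 = c(1L, n3, n_filters2),
                  pool2 = c(1L, n4, n_filters2), flatten = n4 * n_filters2)),
    class = "FoldCNN")
}

#' @export
print.FoldCNN <- function(x, ...) {
  cat(sprintf("<FoldCNN: input %d -> flatten %d -> %d folds>\n",
              x$n_input, x$shapes$flatten, x$n_folds))
  invisible(x)
}

## row indices of all samples' position p + (off-1), given per-sample block
## size n_in and n_out positions
.pool_rows <- function(n_in, n_out, B, off, stride = 1L) {
  rep((seq_len(B) - 1L) * n_in, each = n_out) +
    rep((seq_len(n_out) - 1L) * stride, B) + off
}

.cnn_forward_full <- function(model, x, masks = NULL, collect = FALSE) {
  B <- nrow(x)
  f1 <- model$n_filters1; f2 <- model$n_filters2
  n1 <- model$shapes$conv1[[1]]; n2 <- model$shapes$pool1[[1]]
  n3 <- model$shapes$conv2[[2]]; n4 <- model$shapes$pool2[[2]]

  xcol <- matrix(0, B * n1, model$kernel1)
  for (j in seq_len(model$kernel1))
    xcol[, j] <- as.vector(t(x[, j:(j + n1 - 1L), drop = FALSE]))
  z1 <- .affine(xcol, model$conv1)
  a1 <- leaky_relu(z1)

  p1 <- matrix(-Inf, B * n2, f1); o1 <- matrix(0L, B * n2, f1)
  for (o in seq_len(model$pool1)) {
    cand <- a1[.pool_rows(n1, n2, B, o), , drop = FALSE]
    upd <- cand > p1
    p1[upd] <- cand[upd]; o1[upd] <- o
  }

  x2col <- matrix(0, B * n3, f1 * model$kernel2)
  for (u in seq_len(model$kernel2))
    x2col[, (u - 1L) * f1 + seq_len(f1)] <- p1[.pool_rows(n2, n3, B, u), , drop = FALSE]
  z2 <- .affine(x2col, model$conv2)
  a2 <- leaky_relu(z2)

  p2 <- matrix(-Inf, B * n4, f2); o2 <- matrix(0L, B * n4, f2)
  for (o in seq_len(model$pool2)) {
    cand <- a2[.pool_rows(n3, n4, B, o, model$pool2_stride), , drop = FALSE]
    upd <- cand > p2
    p2[upd] <- cand[upd]; o2[upd] <- o
  }

  flat <- matrix(as.vector(t(p2)), nrow = B, byrow = TRUE)
  zf1 <- .affine(flat, model$fc1)
  hf1 <- leaky_relu(zf1)
  if (!is.null(masks)) hf1 <- hf1 * masks$fc1
  zf2 <- .affine(hf1, model$fc2)
  hf2 <- leaky_relu(zf2)
  if (!is.null(masks)) hf2 <- hf2 * masks$fc2
  logits <- .affine(hf2, model$out)
  probs <- softmax_rows(logits)
  if (!collect) return(probs)
  list(probs = probs,
       cache = list(B = B, xcol = xcol, z1 = z1, o1 = o1, x2col = x2col,
                    z2 = z2, o2 = o2, flat = flat, zf1 = zf1, hf1 = hf1,
                    zf2 = zf2, hf2 = hf2))
}

.cnn_backward <- function(model, fwd, y, masks) {
  c_ <- fwd$cache
  B <- c_$B
  f1 <- model$n_filters1; f2 <- model$n_filters2
  n1 <- model$shapes$conv1[[1]]; n2 <- model$shapes$pool1[[1]]
  n3 <- model$shapes$conv2[[2]]; n4 <- model$shapes$pool2[[2]]

  dlogits <- fwd$probs
  idx <- cbind(seq_len(B), y + 1L)
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / B

  g <- list()
  g$out <- list(W = crossprod(c_$hf2, dlogits), b = colSums(dlogits))
  dh2 <- dlogits %*% t(model$out$W)
  if (!is.null(masks)) dh2 <- dh2 * masks$fc2
  dz2 <- dh2 * .leaky_relu_grad(c_$zf2)
  g$fc2 <- list(W = crossprod(c_$hf1, dz2), b = colSums(dz2))
  dh1 <- dz2 %*% t(model$fc2$W)
  if (!is.null(masks)) dh1 <- dh1 * masks$fc1
  dz1 <- dh1 * .leaky_relu_grad(c_$zf1)
  g$fc1 <- list(W = crossprod(c_$flat, dz1), b = colSums(dz1))
  dflat <- dz1 %*% t(model$fc1$W)

  dp2 <- matrix(as.vector(t(dflat)), ncol = f2, byrow = TRUE)
  da2 <- matrix(0, B * n3, f2)
  for (o in seq_len(model$pool2)) {
    sel <- which(c_$o2 == o)
    if (!length(sel)) next
    r <- ((sel - 1L) %% (B * n4)) + 1L
    cc <- ((sel - 1L) %/% (B * n4)) + 1L
    tgt <- .pool_rows(n3, n4, B, o, model$pool2_stride)[r] + (cc - 1L) * (B * n3)
    da2[tgt] <- da2[tgt] + dp2[sel]
  }
  dz2c <- da2 * .leaky_relu_grad(c_$z2)
  g$conv2 <- list(W = crossprod(c_$x2col, dz2c), b = colSums(dz2c))
  dx2col <- dz2c %*% t(model$conv2$W)

  dp1 <- matrix(0, B * n2, f1)
  for (u in seq_len(model$kernel2)) {
    rows <- .pool_rows(n2, n3, B, u)
    dp1[rows, ] <- dp1[rows, ] + dx2col[, (u - 1L) * f1 + seq_len(f1), drop = FALSE]
  }
  da1 <- matrix(0, B * n1, f1)
  for (o in seq_len(model$pool1)) {
    sel <- which(c_$o1 == o)
    if (!length(sel)) next
    r <- ((sel - 1L) %% (B * n2)) + 1L
    cc <- ((sel - 1L) %/% (B * n2)) + 1L
    tgt <- .pool_rows(n1, n2, B, o)[r] + (cc - 1L) * (B * n1)
    da1[tgt] <- da1[tgt] + dp1[sel]
  }
  dz1c <- da1 * .leaky_relu_grad(c_$z1)
  g$conv1 <- list(W = crossprod(c_$xcol, dz1c), b = colSums(dz1c))
  g
}

.cnn_params <- function(model)
  model[c("conv1", "conv2", "fc1", "fc2", "out")]

.cnn_set_params <- function(model, params) {
  model[names(params)] <- params
  model
}

#' Forward a fragment vector through the stage-2 CNN
#'
#' @param model A `FoldCNN`.
#' @param v A fragment vector of length `model$n_input` (a `FragmentVector`,
#'   a numeric vector, or a matrix of row vectors).
#' @return Probability vector over folds (or matrix of row distributions);
#'   rows sum to 1 and inference is deterministic.
#' @export
cnn_forward <- function(model, v) {
  if (inherits(v, "FragmentVector")) v <- v$values
  if (is.matrix(v)) { x <- v; drop_dim <- FALSE }
  else { x <- matrix(as.numeric(v), 1L); drop_dim <- TRUE }
  if (ncol(x) != model$n_input)
    stop("fragment vector length ", ncol(x), " does not match model input ",
         model$n_input)
  p <- .cnn_forward_full(model, x)
  if (drop_dim) p[1L, ] else p
}

#' Train the stage-2 fold classifier
#'
#' Cross-entropy training with Adam, dropout after the fully-connected
#' hidden layers, and early stopping on a stratified validation split; the
#' best-validation parameters are returned.
#'
#' @param v Matrix of fragment vectors (rows = sequences).
#' @param y Integer fold labels in `[0, n_folds)`.
#' @param config A [train_config()].
#' @param n_folds Number of folds (default inferred).
#' @param ... Architecture arguments passed to [fold_cnn_new()].
#' @return List with `model` (a `FoldCNN`) and `history`.
#' @export
train_fold_cnn <- function(v, y, config = train_config(),
                           n_folds = max(y) + 1L, ...) {
  if (length(unique(y)) < 2L) stop("training requires at least 2 folds")
  set.seed(config$seed)
  model <- fold_cnn_new(n_input = ncol(v), n_folds = n_folds,
                        dropout_rate = config$dropout, init = "random", ...)
  val_idx <- .stratified_split(y, config$val_fraction)
  tr_idx <- setdiff(seq_along(y), val_idx)
  x_tr <- v[tr_idx, , drop = FALSE]; y_tr <- y[tr_idx]
  x_val <- v[val_idx, , drop = FALSE]; y_val <- y[val_idx]
  batch_size <- min(config$batch_size, length(tr_idx))

  params <- .cnn_params(model)
  state <- adam_state(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(y_tr))
    losses <- c()
    for (start in seq(1L, length(y_tr), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, length(y_tr))]
      model <- .cnn_set_params(model, params)
      masks <- if (config$dropout > 0)
        list(fc1 = .dropout_mask(length(idx), model$fc_width, config$dropout),
             fc2 = .dropout_mask(length(idx), model$fc_width, config$dropout))
      fwd <- .cnn_forward_full(model, x_tr[idx, , drop = FALSE], masks,
                               collect = TRUE)
      if (!all(is.finite(fwd$probs))) stop("non-finite training loss")
      losses <- c(losses, .cross_entropy(fwd$probs, y_tr[idx]))
      grads <- .cnn_backward(model, fwd, y_tr[idx], masks)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
    }
    model <- .cnn_set_params(model, params)
    val_loss <- .cross_entropy(.cnn_forward_full(model, x_val), y_val)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_loss = val_loss))
    if (val_loss < best$loss - config$min_delta) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > config$patience) break
    }
  }
  model <- .cnn_set_params(model, best$params)
  list(model = model, history = history, best_epoch = best$epoch)
}
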