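## Stage-1 fragment classifier: three per-modality DBN stacks whose top
## representations are concatenated, fused by a joint RBM layer, and read
## out by a fully-connected head with a softmax over the fragment classes.
## Pretraining is generative (contrastive divergence, logistic units); the
## fine-tuned network applies leaky-ReLU activations throughout.

.DEFAULT_MODALITY_DIMS <- list(sequence = c(256L, 128L),
                               physicochemical = c(256L, 128L),
                               evolutionary = c(512L, 256L))

#' Construct a (untrained) fragment predictor
#'
#' Default widths follow the method's stated head (two 1,000-wide
#' fully-connected layers, 100-way softmax); per-modality stack widths taper
#' toward the fusion layer and are configurable.
#'
#' @param n_classes Number of fragment classes (default 100).
#' @param modality_dims Named list of hidden-layer width vectors for the
#'   `sequence` (77-d input), `physicochemical` (82-d) and `evolutionary`
#'   (1600-d) stacks.
#' @param fusion_dim Width of the joint fusion layer.
#' @param fc_width Width of the two fully-connected head layers.
#' @param dropout_rate Dropout applied after every hidden layer in training.
#' @param init `"zero"` for all-zero weights (uniform output; useful for
#'   contract checks) or `"random"` (He init from the current RNG stream).
#' @return A `FragmentPredictor` object.
#' @export
fragment_predictor_new <- function(n_classes = 100L,
                                   modality_dims = .DEFAULT_MODALITY_DIMS,
                                   fusion_dim = 512L, fc_width = 1000L,
                                   dropout_rate = 0.5,
                                   init = c("zero", "random")) {
  init <- match.arg(init)
  layout <- feature_layout()
  spans <- layout$group_spans
  mk <- function(n_in, n_out) {
    if (init == "zero") list(W = matrix(0, n_in, n_out), b = numeric(n_out))
    else .dense_init(n_in, n_out)
  }
  modality <- list()
  tops <- integer(0)
  for (m in names(spans)) {
    dims <- c(spans[[m]][2] - spans[[m]][1] + 1L, modality_dims[[m]])
    modality[[m]] <- lapply(seq_len(length(dims) - 1L),
                            function(l) mk(dims[[l]], dims[[l + 1L]]))
    tops[[m]] <- dims[[length(dims)]]
  }
  structure(list(
    spans = spans,
    mu = numeric(layout$total), sd = rep(1, layout$total),
    modality = modality,
    fusion = mk(sum(tops), fusion_dim),
    head = list(fc1 = mk(fusion_dim, fc_width),
                fc2 = mk(fc_width, fc_width),
                out = mk(fc_width, as.integer(n_classes))),
    n_classes = as.integer(n_classes),
    fc_width = as.integer(fc_width),
    dropout_rate = dropout_rate), class = "FragmentPredictor")
}

#' @export
print.FragmentPredictor <- function(x, ...) {
  cat(sprintf("<FragmentPredictor: %d classes, head %d x %d>\n",
              x$n_classes, x$fc_width, x$fc_width))
  invisible(x)
}

## Forward pass. masks = NULL for inference; for training, a list produced by
## .fp_masks with one mask per hidden layer. Returns probs and (optionally)
## all caches needed for backprop.
.fp_forward <- function(model, x, masks = NULL, collect = FALSE) {
  x <- sweep(sweep(x, 2L, model$mu, "-"), 2L, model$sd, "/")
  cache <- list(modality = list())
  hs <- list()
  for (m in names(model$spans)) {
    sp <- model$spans[[m]]
    h <- x[, sp[1]:sp[2], drop = FALSE]
    layer_cache <- list(input = h)
    for (l in seq_along(model$modality[[m]])) {
      z <- .affine(h, model$modality[[m]][[l]])
      h <- leaky_relu(z)
      if (!is.null(masks)) h <- h * masks$modality[[m]][[l]]
      layer_cache$z[[l]] <- z
      layer_cache$h[[l]] <- h
    }
    cache$modality[[m]] <- layer_cache
    hs[[m]] <- h
  }
  concat <- do.call(cbind, hs)
  zf <- .affine(concat, model$fusion)
  hf <- leaky_relu(zf)
  if (!is.null(masks)) hf <- hf * masks$fusion
  z1 <- .affine(hf, model$head$fc1)
  h1 <- leaky_relu(z1)
  if (!is.null(masks)) h1 <- h1 * masks$fc1
  z2 <- .affine(h1, model$head$fc2)
  h2 <- leaky_relu(z2)
  if (!is.null(masks)) h2 <- h2 * masks$fc2
  logits <- .affine(h2, model$head$out)
  probs <- softmax_rows(logits)
  if (!collect) return(probs)
  cache$x <- x; cache$concat <- concat
  cache$zf <- zf; cache$hf <- hf
  cache$z1 <- z1; cache$h1 <- h1
  cache$z2 <- z2; cache$h2 <- h2
  list(probs = probs, cache = cache)
}

.fp_masks <- function(model, n, rate) {
  if (rate <= 0) return(NULL)
  masks <- list(modality = list())
  for (m in names(model$modality))
    masks$modality[[m]] <- lapply(model$modality[[m]], function(l)
      .dropout_mask(n, ncol(l$W), rate))
  masks$fusion <- .dropout_mask(n, ncol(model$fusion$W), rate)
  masks$fc1 <- .dropout_mask(n, ncol(model$head$fc1$W), rate)
  masks$fc2 <- .dropout_mask(n, ncol(model$head$fc2$W), rate)
  masks
}

## Backward pass: gradients of mean cross-entropy wrt every parameter.
.fp_backward <- function(model, fwd, y, masks) {
  cache <- fwd$cache
  n <- nrow(fwd$probs)
  dlogits <- fwd$probs
  idx <- cbind(seq_len(n), y + 1L)
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / n

  g <- list(modality = list(), fusion = NULL, head = list())
  g$head$out <- list(W = crossprod(cache$h2, dlogits), b = colSums(dlogits))
  dh2 <- dlogits %*% t(model$head$out$W)
  if (!is.null(masks)) dh2 <- dh2 * masks$fc2
  dz2 <- dh2 * .leaky_relu_grad(cache$z2)
  g$head$fc2 <- list(W = crossprod(cache$h1, dz2), b = colSums(dz2))
  dh1 <- dz2 %*% t(model$head$fc2$W)
  if (!is.null(masks)) dh1 <- dh1 * masks$fc1
  dz1 <- dh1 * .leaky_relu_grad(cache$z1)
  g$head$fc1 <- list(W = crossprod(cache$hf, dz1), b = colSums(dz1))
  dhf <- dz1 %*% t(model$head$fc1$W)
  if (!is.null(masks)) dhf <- dhf * masks$fusion
  dzf <- dhf * .leaky_relu_grad(cache$zf)
  g$fusion <- list(W = crossprod(cache$concat, dzf), b = colSums(dzf))
  dconcat <- dzf %*% t(model$fusion$W)

  offset <- 0L
  for (m in names(model$modality)) {
    mc <- cache$modality[[m]]
    n_layers <- length(model$modality[[m]])
    width <- ncol(model$modality[[m]][[n_layers]]$W)
    dh <- dconcat[, (offset + 1L):(offset + width), drop = FALSE]
    offset <- offset + width
    g$modality[[m]] <- vector("list", n_layers)
    for (l in rev(seq_len(n_layers))) {
      if (!is.null(masks)) dh <- dh * masks$modality[[m]][[l]]
      dz <- dh * .leaky_relu_grad(mc$z[[l]])
      h_in <- if (l == 1L) mc$input else mc$h[[l - 1L]]
      g$modality[[m]][[l]] <- list(W = crossprod(h_in, dz), b = colSums(dz))
      if (l > 1L) dh <- dz %*% t(model$modality[[m]][[l]]$W)
    }
  }
  g
}

.fp_params <- function(model) {
  list(modality = model$modality, fusion = model$fusion, head = model$head)
}

.fp_set_params <- function(model, params) {
  model$modality <- params$modality
  model$fusion <- params$fusion
  model$head <- params$head
  model
}

#' Forward a fragment's features through the stage-1 model
#'
#' @param model A trained `FragmentPredictor`.
#' @param features A `FragmentFeatureSet`, a length-1759 numeric vector, or a
#'   matrix of such rows.
#' @return A probability vector over fragment classes (or a matrix of row
#'   distributions for matrix input); rows sum to 1. Dropout is disabled:
#'   inference is deterministic.
#' @export
multimodal_forward <- function(model, features) {
  if (inherits(features, "FragmentFeatureSet")) {
    missing <- setdiff(names(model$spans), names(features$group_spans))
    if (length(missing))
      stop("feature set is missing group(s): ", paste(missing, collapse = ", "))
    x <- matrix(feature_vector(features), 1L)
    drop_dim <- TRUE
  } else if (is.matrix(features)) {
    x <- features; drop_dim <- FALSE
  } else {
    x <- matrix(as.numeric(features), 1L); drop_dim <- TRUE
  }
  if (ncol(x) != length(model$mu))
    stop("expected ", length(model$mu), " feature columns, got ", ncol(x))
  p <- .fp_forward(model, x)
  if (drop_dim) p[1L, ] else p
}

#' Train the stage-1 fragment classifier
#'
#' Greedy generative pretraining (per-modality DBNs, then a joint Bernoulli
#' fusion RBM on the concatenated top representations) followed by
#' supervised fine-tuning of the full network with cross-entropy, Adam,
#' dropout after every hidden layer, and early stopping on a stratified
#' validation split. The best-validation parameters are returned.
#'
#' @param x Feature matrix (rows = fragments, 1759 columns).
#' @param y Integer class labels in `[0, n_classes)`.
#' @param config A [train_config()].
#' @param n_classes Number of fragment classes (default inferred from `y`).
#' @param modality_dims,fusion_dim,fc_width Architecture widths (see
#'   [fragment_predictor_new()]).
#' @return List with `model` (a `FragmentPredictor`) and `history` (data
#'   frame of per-epoch training and validation loss).
#' @export
train_fragment_predictor <- function(x, y, config = train_config(),
                                     n_classes = max(y) + 1L,
                                     modality_dims = .DEFAULT_MODALITY_DIMS,
                                     fusion_dim = 512L, fc_width = 1000L) {
  if (length(unique(y)) < 2L) stop("training requires at least 2 classes")
  set.seed(config$seed)
  counts <- table(y)
  if (length(unique(counts)) > 1L)
    message("train_fragment_predictor: classes are unbalanced (",
            min(counts), "-", max(counts), " samples per class)")

  val_idx <- .stratified_split(y, config$val_fraction)
  tr_idx <- setdiff(seq_along(y), val_idx)
  mu <- colMeans(x[tr_idx, , drop = FALSE])
  sd <- apply(x[tr_idx, , drop = FALSE], 2L, stats::sd)
  sd[sd < 1e-8] <- 1
  xs <- sweep(sweep(x, 2L, mu, "-"), 2L, sd, "/")

  model <- fragment_predictor_new(n_classes, modality_dims, fusion_dim,
                                  fc_width, config$dropout, init = "random")
  model$mu <- mu
  model$sd <- sd

  ## generative pretraining
  tops <- list()
  for (m in names(model$spans)) {
    sp <- model$spans[[m]]
    dims <- c(sp[2] - sp[1] + 1L, modality_dims[[m]])
    stack <- dbn_pretrain(dims, xs[tr_idx, sp[1]:sp[2], drop = FALSE], config)
    model$modality[[m]] <- lapply(stack$layers, function(r) list(W = r$W, b = r$b))
    tops[[m]] <- dbn_transform(stack, xs[tr_idx, sp[1]:sp[2], drop = FALSE])
  }
  concat <- do.call(cbind, tops)
  fusion_rbm <- rbm_new(ncol(concat), fusion_dim, "bernoulli")
  f_state <- NULL
  batch_size <- min(config$batch_size, length(tr_idx))
  for (epoch in seq_len(config$pretrain_epochs)) {
    ord <- sample.int(nrow(concat))
    for (start in seq(1L, nrow(concat), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, nrow(concat))]
      upd <- rbm_cd_update(fusion_rbm, concat[idx, , drop = FALSE], config, f_state)
      fusion_rbm <- upd$rbm; f_state <- upd$state
    }
  }
  model$fusion <- list(W = fusion_rbm$W, b = fusion_rbm$b)

  ## supervised fine-tuning
  params <- .fp_params(model)
  state <- adam_state(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  x_tr <- x[tr_idx, , drop = FALSE]; y_tr <- y[tr_idx]
  x_val <- x[val_idx, , drop = FALSE]; y_val <- y[val_idx]
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(y_tr))
    losses <- c()
    for (start in seq(1L, length(y_tr), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, length(y_tr))]
      xb <- x_tr[idx, , drop = FALSE]; yb <- y_tr[idx]
      model <- .fp_set_params(model, params)
      masks <- .fp_masks(model, length(idx), config$dropout)
      fwd <- .fp_forward(model, xb, masks, collect = TRUE)
      if (!all(is.finite(fwd$probs))) stop("non-finite training loss")
      losses <- c(losses, .cross_entropy(fwd$probs, yb))
      grads <- .fp_backward(model, fwd, yb, masks)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
    }
    model <- .fp_set_params(model, params)
    val_probs <- .fp_forward(model, x_val)
    val_loss <- .cross_entropy(val_probs, y_val)
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
  model <- .fp_set_params(model, best$params)
  list(model = model, history = history, best_epoch = best$epoch)
}
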