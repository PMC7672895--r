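small_dims <- list(sequence = c(8L), physicochemical = c(8L), evolutionary = c(12L))

test_that("DBN pretraining chains layer shapes and is seed-deterministic", {
  set.seed(31)
  data <- matrix(rnorm(200 * 10), 200, 10)
  cfg <- train_config(batch_size = 50, pretrain_epochs = 2, seed = 1)
  run <- function() {
    set.seed(99)
    dbn_pretrain(c(10, 8, 4), data, cfg)
  }
  stack <- run()
  expect_length(stack$layers, 2L)
  expect_equal(dim(stack$layers[[1]]$W), c(10L, 8L))
  expect_equal(dim(stack$layers[[2]]$W), c(8L, 4L))
  expect_equal(stack$layers[[1]]$visible_kind, "gaussian")
  expect_equal(stack$layers[[2]]$visible_kind, "bernoulli")
  expect_equal(ncol(dbn_transform(stack, data)), 4L)
  expect_length(stack$recon_traces[[1]], 2L)

  stack2 <- run()
  expect_identical(stack$layers, stack2$layers)
})

test_that("stage-1 forward is a normalized, deterministic distribution", {
  set.seed(32)
  model <- fragment_predictor_new(n_classes = 9, modality_dims = small_dims,
                                  fusion_dim = 8L, fc_width = 8L, init = "random")
  x <- matrix(rnorm(3 * 1759), 3)
  p <- multimodal_forward(model, x)
  expect_equal(dim(p), c(3L, 9L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_identical(p, multimodal_forward(model, x))

  zero <- fragment_predictor_new(n_classes = 5, modality_dims = small_dims,
                                 fusion_dim = 8L, fc_width = 8L, init = "zero")
  expect_equal(multimodal_forward(zero, x[1, ]), rep(0.2, 5))

  fs <- fragment_features(aa_sequence("f", "ACDEFG"), synth_pssm("ACDEFG", 1, seed = 1))
  fs$group_spans$evolutionary <- NULL
  expect_error(multimodal_forward(model, fs), "evolutionary")
})

test_that("stage-1 backprop gradients agree with finite differences", {
  ns <- asNamespace("deepfragk")
  set.seed(33)
  fp <- fragment_predictor_new(n_classes = 4, modality_dims = small_dims,
                               fusion_dim = 6L, fc_width = 6L,
                               dropout_rate = 0, init = "random")
  x <- matrix(rnorm(3 * 1759), 3); y <- c(0L, 1L, 2L)
  fwd <- ns$.fp_forward(fp, x, NULL, collect = TRUE)
  g <- ns$.fp_backward(fp, fwd, y, NULL)
  loss <- function(model) ns$.cross_entropy(ns$.fp_forward(model, x), y)
  eps <- 1e-6
  check <- function(getter, setter, garr) {
    arr <- getter(fp)
    for (i in sample(length(arr), min(6, length(arr)))) {
      up <- setter(fp, i, arr[i] + eps); dn <- setter(fp, i, arr[i] - eps)
      expect_equal(garr[i], (loss(up) - loss(dn)) / (2 * eps), tolerance = 1e-5)
    }
  }
  check(function(m) m$head$out$W,
        function(m, i, v) { m$head$out$W[i] <- v; m }, g$head$out$W)
  check(function(m) m$fusion$W,
        function(m, i, v) { m$fusion$W[i] <- v; m }, g$fusion$W)
  check(function(m) m$modality$sequence[[1]]$W,
        function(m, i, v) { m$modality$sequence[[1]]$W[i] <- v; m },
        g$modality$sequence[[1]]$W)
  check(function(m) m$modality$evolutionary[[1]]$b,
        function(m, i, v) { m$modality$evolutionary[[1]]$b[i] <- v; m },
        g$modality$evolutionary[[1]]$b)
})

test_that("stage-1 training rejects degenerate input and stops early", {
  x <- matrix(rnorm(20 * 1759), 20)
  expect_error(train_fragment_predictor(x, rep(0L, 20), train_config(seed = 1)),
               "at least 2 classes")
})

test_that("the stage-2 stack follows the documented shape arithmetic", {
  m <- fold_cnn_new(n_input = 100, n_folds = 27)
  expect_equal(ncol(m$conv1$W), 10L)        # 10 first-layer filters
  expect_equal(m$shapes$conv1, c(91L, 10L))
  expect_equal(m$shapes$pool1, c(82L, 10L))
  expect_equal(m$shapes$stack, c(10L, 82L))
  expect_equal(m$shapes$conv2, c(1L, 73L, 100L))
  expect_equal(m$shapes$pool2, c(1L, 14L, 100L))
  expect_equal(m$shapes$flatten, 1400L)
  expect_error(fold_cnn_new(n_input = 20, n_folds = 3), "too short")
})

test_that("stage-2 forward normalizes and a zero model is uniform", {
  set.seed(34)
  m <- fold_cnn_new(n_input = 40, n_folds = 6, init = "random")
  v <- matrix(runif(5 * 40), 5)
  p <- cnn_forward(m, v)
  expect_equal(dim(p), c(5L, 6L))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  zero <- fold_cnn_new(n_input = 40, n_folds = 4, init = "zero")
  expect_equal(cnn_forward(zero, v[1, ]), rep(0.25, 4))
  expect_error(cnn_forward(m, runif(39)), "does not match")
})

test_that("stage-2 backprop gradients agree with finite differences", {
  ns <- asNamespace("deepfragk")
  set.seed(35)
  m <- fold_cnn_new(n_input = 34, n_folds = 3, n_filters1 = 4, kernel1 = 5,
                    pool1 = 4, n_filters2 = 6, kernel2 = 5, pool2 = 5,
                    pool2_stride = 5, fc_width = 8, dropout_rate = 0,
                    init = "random")
  x <- matrix(rnorm(3 * 34), 3); y <- c(0L, 1L, 2L)
  fwd <- ns$.cnn_forward_full(m, x, NULL, collect = TRUE)
  g <- ns$.cnn_backward(m, fwd, y, NULL)
  loss <- function(model) ns$.cross_entropy(ns$.cnn_forward_full(model, x), y)
  eps <- 1e-6
  for (nm in c("conv1", "conv2", "fc1", "out")) for (f in c("W", "b")) {
    arr <- m[[nm]][[f]]
    for (i in sample(length(arr), min(6, length(arr)))) {
      up <- m; up[[nm]][[f]][i] <- up[[nm]][[f]][i] + eps
      dn <- m; dn[[nm]][[f]][i] <- dn[[nm]][[f]][i] - eps
      expect_equal(g[[nm]][[f]][i], (loss(up) - loss(dn)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("stage-2 training is reproducible under a fixed seed", {
  set.seed(36)
  v <- matrix(runif(40 * 40), 40)
  y <- rep(0:1, each = 20)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 20, max_epochs = 3,
                      patience = 2, seed = 7)
  f1 <- train_fold_cnn(v, y, cfg)
  f2 <- train_fold_cnn(v, y, cfg)
  expect_identical(f1$model$conv1, f2$model$conv1)
  expect_identical(f1$model$out, f2$model$out)
  expect_identical(f1$history, f2$history)
  expect_error(train_fold_cnn(v, rep(0L, 40), cfg), "at least 2 folds")
})

test_that("patience 0 stops training after the first non-improving epoch", {
  set.seed(37)
  v <- matrix(runif(30 * 40), 30)
  y <- rep(0:1, each = 15)
  # zero learning rate: validation loss can never improve after epoch 1
  cfg <- train_config(learning_rate = 0, batch_size = 15, max_epochs = 50,
                      patience = 0, seed = 8)
  fit <- train_fold_cnn(v, y, cfg)
  expect_equal(nrow(fit$history), 2L)
  expect_equal(fit$best_epoch, 1L)
})
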