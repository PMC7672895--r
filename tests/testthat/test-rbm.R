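test_that("the exact-gradient helper matches full joint enumeration", {
  set.seed(21)
  for (i in 1:5) {
    rbm <- rbm_new(3, 2, "bernoulli", init_sd = 0.8)
    data <- matrix(rbinom(15, 1, runif(1, 0.2, 0.8)), 5, 3)
    g <- rbm_exact_loglik_grad(rbm, data)
    o <- oracle_rbm_grad(rbm, data)
    expect_lt(max(abs(g$W - o$W)), 1e-10)
    expect_lt(max(abs(g$a - o$a)), 1e-10)
    expect_lt(max(abs(g$b - o$b)), 1e-10)
  }
})

test_that("zero learning rate leaves the parameters unchanged", {
  set.seed(22)
  rbm <- rbm_new(6, 3, "bernoulli")
  batch <- matrix(rbinom(30, 1, 0.5), 5, 6)
  upd <- rbm_cd_update(rbm, batch, train_config(learning_rate = 0, seed = 1))
  expect_identical(upd$rbm$W, rbm$W)
  expect_identical(upd$rbm$a, rbm$a)
  expect_identical(upd$rbm$b, rbm$b)
})

test_that("CD-1 reconstruction error trends downward on a repeated batch", {
  set.seed(23)
  rbm <- rbm_new(8, 4, "bernoulli")
  batch <- matrix(rep(rbinom(8, 1, 0.5), times = 20), 20, 8, byrow = TRUE)
  cfg <- train_config(learning_rate = 0.05, seed = 1)
  errs <- numeric(50)
  state <- NULL
  for (k in 1:50) {
    upd <- rbm_cd_update(rbm, batch, cfg, state)
    rbm <- upd$rbm; state <- upd$state; errs[k] <- upd$recon_error
  }
  expect_lt(mean(errs[41:50]), mean(errs[1:10]))
})

test_that("the average CD-1 step ascends the exact likelihood gradient", {
  set.seed(24)
  rbm <- rbm_new(3, 2, "bernoulli", init_sd = 0.5)
  data <- matrix(rbinom(30, 1, 0.6), 10, 3)
  exact <- rbm_exact_loglik_grad(rbm, data)
  cfg <- train_config(learning_rate = 1e-3, seed = 1)
  dW <- matrix(0, 3, 2)
  for (r in 1:200) {
    upd <- rbm_cd_update(rbm, data, cfg)   # fresh Adam state: direction ~ sign of CD gradient
    dW <- dW + (upd$rbm$W - rbm$W)
  }
  expect_gt(sum(dW * exact$W), 0)
})

test_that("mismatched batch width is rejected", {
  rbm <- rbm_new(4, 2, "bernoulli")
  expect_error(rbm_cd_update(rbm, matrix(0, 3, 5), train_config(seed = 1)),
               "expects 4")
})
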