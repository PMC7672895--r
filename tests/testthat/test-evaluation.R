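test_that("confusion matrices tally true/predicted pairs", {
  y <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  p <- c(0, 0, 0, 0, 0, 0, 0, 1, 1, 1)
  cm <- confusion(y, p, 2)
  expect_equal(unclass(cm), matrix(c(5L, 2L, 0L, 3L), 2, 2),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 10L)

  perfect <- confusion(c(0, 1, 2), c(0, 1, 2), 3)
  expect_equal(unclass(unname(perfect)), diag(1L, 3), ignore_attr = TRUE)
  expect_equal(sum(confusion(integer(0), integer(0), 3)), 0L)
  expect_error(confusion(c(0, 3), c(0, 1), 2), "labels must lie")
})

test_that("metrics reproduce the hand-computed 2x2 example", {
  cm <- confusion(c(rep(0, 5), rep(1, 5)), c(rep(0, 7), rep(1, 3)), 2)
  m <- metrics(cm)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$per_class$precision, c(5 / 7, 1))
  expect_equal(m$per_class$recall, c(1, 0.6))
  expect_equal(m$macro_precision, (5 / 7 + 1) / 2)
  expect_equal(m$macro_recall, 0.8)

  ident <- metrics(confusion(c(0, 1, 1, 2), c(0, 1, 1, 2), 3))
  expect_equal(ident$accuracy, 1)
  expect_equal(ident$macro_precision, 1)
  expect_equal(ident$macro_recall, 1)
  expect_error(metrics(confusion(integer(0), integer(0), 2)), "empty")
})

test_that("never-predicted classes are flagged and contribute zero precision", {
  cm <- confusion(c(0, 0, 1, 1), c(0, 0, 0, 0), 2)
  expect_message(m <- metrics(cm), "never predicted")
  expect_true(m$per_class$never_predicted[[2]])
  expect_equal(m$macro_precision, (2 / 4 + 0) / 2)
})

test_that("accuracy is invariant under class-index permutation", {
  set.seed(51)
  y <- sample(0:3, 60, replace = TRUE)
  p <- sample(0:3, 60, replace = TRUE)
  perm <- sample(0:3)
  a1 <- metrics(confusion(y, p, 4))$accuracy
  a2 <- metrics(confusion(perm[y + 1], perm[p + 1], 4))$accuracy
  expect_equal(a1, a2)
})

test_that("stratified ten-fold CV partitions exactly and evaluates train_fn", {
  set.seed(52)
  x <- matrix(rnorm(100 * 3), 100, 3)
  y <- rep(0:9, each = 10)
  majority_train <- function(x_tr, y_tr)
    as.integer(names(which.max(table(y_tr))))
  majority_predict <- function(model, x_te) rep(model, nrow(x_te))

  rep_cv <- ten_fold_cv(x, y, majority_train, majority_predict, seed = 1)
  # 100 items, 10 classes: each partition holds exactly one item per class
  tab <- table(rep_cv$assignment, y)
  expect_true(all(tab == 1L))
  expect_equal(sort(unique(rep_cv$assignment)), 1:10)
  # majority classifier on balanced data scores the class prior
  expect_equal(rep_cv$aggregate$mean[[1]], 0.1, tolerance = 1e-12)
  expect_equal(rep_cv$pooled$accuracy, 0.1)

  # unbalanced prior: majority class has 60 of 100 items
  y2 <- rep(c(0L, 1L), c(60, 40))
  rep2 <- ten_fold_cv(x, y2, majority_train, majority_predict, seed = 2)
  expect_equal(rep2$pooled$accuracy, 0.6)

  expect_error(ten_fold_cv(x[1:5, ], y[1:5], majority_train, majority_predict),
               "fewer items")
  expect_warning(ten_fold_cv(x[1:30, ], rep(0:4, each = 6), majority_train,
                             majority_predict, seed = 3),
                 "stratification degrades")
})
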