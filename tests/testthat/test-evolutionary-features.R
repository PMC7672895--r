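test_that("the logistic transform maps scores into (0,1) monotonically", {
  p <- pssm_profile("ACD", matrix(0, 3, 20))
  expect_equal(unname(transform_pssm(p)$values), matrix(0.5, 3, 20))

  p2 <- pssm_profile("AC", rbind(rep(2, 20), rep(-2, 20)))
  tv <- transform_pssm(p2)$values
  expect_equal(tv[1, 1][[1]], 1 / (1 + exp(-2)), tolerance = 1e-10)
  expect_equal(round(tv[1, 1][[1]], 4), 0.8808)
  expect_true(all(tv[1, ] > tv[2, ]))
})

test_that("P-PSSM averages transformed rows by query residue type", {
  p <- pssm_profile("AC", matrix(0, 2, 20))
  v <- matrix(p_pssm(p)$values, 20, 20, byrow = TRUE,
              dimnames = list(PSSM_COLUMN_ORDER, PSSM_COLUMN_ORDER))
  expect_equal(unname(v["A", ]), rep(0.5, 20))
  expect_equal(unname(v["C", ]), rep(0.5, 20))
  expect_equal(sum(v != 0), 40L)

  sc <- rbind(1:20, 21:40) / 10
  p2 <- pssm_profile("AA", sc)
  v2 <- matrix(p_pssm(p2)$values, 20, 20, byrow = TRUE,
               dimnames = list(PSSM_COLUMN_ORDER, PSSM_COLUMN_ORDER))
  tv <- 1 / (1 + exp(-sc))
  expect_equal(unname(v2["A", ]), unname((tv[1, ] + tv[2, ]) / 2))

  p3 <- pssm_profile("W", matrix(rnorm(20), 1, 20))
  v3 <- matrix(p_pssm(p3)$values, 20, 20, byrow = TRUE,
               dimnames = list(PSSM_COLUMN_ORDER, PSSM_COLUMN_ORDER))
  expect_equal(unname(v3["W", ]), unname(1 / (1 + exp(-p3$scores[1, ]))))
})

test_that("PSSM-DC, bigram and ED blocks satisfy their closed-form cases", {
  # all transformed values 0.5 -> every DC entry 0.25, every ED entry 0
  p <- pssm_profile("ACDE", matrix(0, 4, 20))
  expect_equal(pssm_dc(p)$values, rep(0.25, 400))
  expect_equal(ed_pssm(p)$values, rep(0, 400))
  # uniform bigram rows: every entry (L-1)/400, total L-1
  expect_equal(bigram_pssm(p)$values, rep(3 / 400, 400))

  # L = 2: DC is the outer product of the two transformed rows
  sc <- rbind(rnorm(20), rnorm(20))
  p2 <- pssm_profile("AC", sc)
  tv <- 1 / (1 + exp(-sc))
  expect_equal(pssm_dc(p2)$values, as.vector(t(outer(tv[1, ], tv[2, ]))),
               tolerance = 1e-12)
  v <- pssm_dc(p2)$values
  expect_true(all(v > 0 & v < 1))

  # identical rows, d = 1: diagonal of ED vanishes
  p3 <- pssm_profile("ACD", matrix(rep(rnorm(20), each = 3), 3, 20))
  m <- matrix(ed_pssm(p3)$values, 20, 20, byrow = TRUE)
  expect_equal(unname(diag(m)), rep(0, 20))
  expect_true(all(ed_pssm(p3)$values >= 0))
})

test_that("double-loop oracles reproduce the vectorized blocks on random profiles", {
  set.seed(11)
  for (i in 1:50) {
    p <- random_profile(sample(4:12, 1))
    tv <- transform_pssm(p)$values
    expect_equal(pssm_dc(p)$values, oracle_pssm_dc(tv), tolerance = 1e-12)
    expect_equal(bigram_pssm(p)$values, oracle_bigram(p$scores), tolerance = 1e-12)
    d <- sample(1:2, 1)
    expect_equal(ed_pssm(p, d)$values, oracle_ed_pssm(tv, d), tolerance = 1e-12)
  }
})

test_that("bigram sums to L-1 and is shift-invariant; sigmoid blocks are not", {
  set.seed(12)
  for (i in 1:10) {
    p <- random_profile()
    L <- nrow(p$scores)
    expect_equal(sum(bigram_pssm(p)$values), L - 1, tolerance = 1e-9)
    shifted <- pssm_profile(p$sequence, p$scores + 3)
    expect_equal(bigram_pssm(shifted)$values, bigram_pssm(p)$values,
                 tolerance = 1e-9)
    expect_false(isTRUE(all.equal(p_pssm(shifted)$values, p_pssm(p)$values)))
    expect_false(isTRUE(all.equal(pssm_dc(shifted)$values, pssm_dc(p)$values)))
  }
})

test_that("the evolutionary group concatenates its four blocks in order", {
  p <- random_profile(8)
  g <- evolutionary_group_features(p)
  expect_equal(vapply(g, `[[`, character(1), "name"),
               c("p_pssm", "pssm_dc", "bigram_pssm", "ed_pssm"))
  expect_equal(sum(vapply(g, `[[`, integer(1), "dim")), 1600L)
  expect_equal(g[[2]]$values, pssm_dc(p)$values)
  expect_equal(g[[4]]$values, ed_pssm(p)$values)
})
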