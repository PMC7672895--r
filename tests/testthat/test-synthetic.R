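test_that("library generation honours counts, determinism and motif strength", {
  spec <- synthetic_library_spec(n_classes = 10, samples_per_class = 100, seed = 3)
  lib <- make_fragment_library(spec)
  expect_length(lib$records, 1000L)
  labels <- vapply(lib$records, `[[`, integer(1), "class_label")
  expect_equal(unname(table(labels)), rep(100L, 10L), ignore_attr = TRUE)

  lib2 <- make_fragment_library(spec)
  expect_identical(vapply(lib$records, function(r) r$sequence$residues, character(1)),
                   vapply(lib2$records, function(r) r$sequence$residues, character(1)))

  pure <- make_fragment_library(synthetic_library_spec(
    n_classes = 3, samples_per_class = 5, motif_strength = 1, seed = 4))
  for (cl in 0:2) {
    seqs <- unique(vapply(pure$records[vapply(pure$records, `[[`, integer(1),
                                              "class_label") == cl],
                          function(r) r$sequence$residues, character(1)))
    expect_length(seqs, 1L)
  }
})

test_that("higher motif strength raises within-class sequence identity", {
  identity_of <- function(ms) {
    lib <- make_fragment_library(synthetic_library_spec(
      n_classes = 4, samples_per_class = 10, motif_strength = ms, seed = 5))
    mean(vapply(0:3, function(cl) {
      recs <- lib$records[vapply(lib$records, `[[`, integer(1), "class_label") == cl]
      mats <- vapply(recs, function(r) strsplit(r$sequence$residues, "")[[1]],
                     character(nchar(recs[[1]]$sequence$residues)))
      cons <- apply(mats, 1, function(col) names(which.max(table(col))))
      mean(mats == cons)
    }, numeric(1)))
  }
  expect_gt(identity_of(0.9), identity_of(0.3))
})

test_that("synthetic PSSMs are noisy BLOSUM62 rows in the ASCII dialect", {
  p0 <- synth_pssm("ACDE", noise = 0)
  b62 <- blosum62()
  expect_equal(unname(p0$scores), unname(b62[c("A", "C", "D", "E"), ]))

  path <- withr::local_tempfile(fileext = ".pssm")
  p <- synth_pssm("ACDEFGH", noise = 2, seed = 6)
  write_pssm_ascii(p, path)
  expect_no_warning(got <- read_pssm_ascii(path))
  expect_equal(unname(got$scores), unname(p$scores))
  expect_identical(synth_pssm("ACDEFGH", noise = 2, seed = 6)$scores, p$scores)

  dev_of <- function(noise) {
    mean(vapply(1:20, function(i)
      mean(abs(synth_pssm("ACDEFGHIKL", noise, seed = 100 + i)$scores -
                 b62[strsplit("ACDEFGHIKL", "")[[1]], ])), numeric(1)))
  }
  expect_gt(dev_of(2), dev_of(0.5))
})

test_that("fold datasets realize the requested mixtures", {
  lib <- make_fragment_library(synthetic_library_spec(
    n_classes = 4, samples_per_class = 5, seed = 7))

  onehot <- matrix(c(1, 0, 0, 0, 0, 0, 0, 1), 2, 4, byrow = TRUE)
  ds <- make_fold_dataset(synthetic_fold_spec(onehot, seqs_per_fold = 5,
                                              seq_length_range = c(20L, 30L),
                                              seed = 8), lib)
  expect_length(ds, 10L)
  for (rec in ds) {
    used <- which(rec$class_usage > 0)
    expect_length(used, 1L)
    expect_equal(used, if (rec$fold_label == 0) 1L else 4L)
    expect_true(nchar(rec$sequence$residues) >= 20 &&
                  nchar(rec$sequence$residues) <= 30)
  }

  mix <- matrix(c(0.4, 0.3, 0.2, 0.1), 1, 4)
  mix <- rbind(mix, mix)  # spec requires >= 2 folds
  big <- make_fold_dataset(synthetic_fold_spec(mix, seqs_per_fold = 500,
                                               seq_length_range = c(25L, 35L),
                                               seed = 9), lib)
  usage <- colSums(do.call(rbind, lapply(big, `[[`, "class_usage")))
  expect_true(all(abs(usage / sum(usage) - mix[1, ]) < 0.03))

  expect_error(make_fold_dataset(synthetic_fold_spec(matrix(0.5, 2, 2),
                                                     seqs_per_fold = 1,
                                                     seed = 1), lib),
               "mixture width")
})
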