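## Desk-scale validation experiments on synthetic data. These encode the
## package's reference study conditions (class counts, motif strength,
## sample sizes, reduced layer widths) in one place so tests, scripts and
## users run the same experiments. Desk-scale training uses the Adam
## default step size 1e-3 and a few hundred epochs, because these runs take
## thousands of optimizer steps rather than the millions of a full-scale
## run; all other protocol elements (batching, dropout 0.5, early stopping)
## follow the method's stated training protocol.

.benchmark_config <- function(seed, batch_size = 100L, max_epochs = 150L,
                              patience = 15L) {
  train_config(learning_rate = 1e-3, batch_size = batch_size, dropout = 0.5,
               max_epochs = max_epochs, patience = patience, seed = seed,
               pretrain_epochs = 3L)
}

.REDUCED_MODALITY_DIMS <- list(sequence = c(64L, 32L),
                               physicochemical = c(64L, 32L),
                               evolutionary = c(128L, 64L))

## Stratified train/test split: returns test indices.
.holdout_idx <- function(y, fraction, seed) {
  set.seed(seed)
  .stratified_split(y, fraction)
}

#' Stage-1 parameter-recovery benchmark
#'
#' Generates a well-separated synthetic fragment library (10 classes, 100
#' samples per class, motif strength 0.9), trains the stage-1 classifier at
#' reduced layer widths on a stratified 80% split, and reports held-out
#' accuracy. A label-shuffled negative control (training labels permuted,
#' same protocol) verifies that accuracy collapses to the class prior.
#'
#' @param seed Integer seed controlling generation, splits and training.
#' @param n_classes,samples_per_class,motif_strength Library conditions.
#' @param with_control Also run the label-shuffled control.
#' @return List with `accuracy`, `control_accuracy` (NA unless requested),
#'   `n_test`, `n_classes`, and the trained `model`.
#' @export
run_stage1_benchmark <- function(seed = 1L, n_classes = 10L,
                                 samples_per_class = 100L,
                                 motif_strength = 0.9,
                                 with_control = TRUE) {
  lib <- make_fragment_library(synthetic_library_spec(
    n_classes = n_classes, samples_per_class = samples_per_class,
    motif_strength = motif_strength, seed = seed))
  feats <- featurize_library(lib)
  te <- .holdout_idx(feats$y, 0.2, seed + 1L)
  tr <- setdiff(seq_along(feats$y), te)
  cfg <- .benchmark_config(seed + 2L)
  fit <- train_fragment_predictor(feats$x[tr, ], feats$y[tr], cfg,
                                  n_classes = n_classes,
                                  modality_dims = .REDUCED_MODALITY_DIMS,
                                  fusion_dim = 64L, fc_width = 64L)
  pred <- max.col(multimodal_forward(fit$model, feats$x[te, ]),
                  ties.method = "first") - 1L
  acc <- mean(pred == feats$y[te])

  control_acc <- NA_real_
  if (with_control) {
    set.seed(seed + 3L)
    y_shuf <- sample(feats$y[tr])
    fit0 <- train_fragment_predictor(feats$x[tr, ], y_shuf, cfg,
                                     n_classes = n_classes,
                                     modality_dims = .REDUCED_MODALITY_DIMS,
                                     fusion_dim = 64L, fc_width = 64L)
    pred0 <- max.col(multimodal_forward(fit0$model, feats$x[te, ]),
                     ties.method = "first") - 1L
    control_acc <- mean(pred0 == feats$y[te])
  }
  list(accuracy = acc, control_accuracy = control_acc,
       n_test = length(te), n_classes = n_classes, model = fit$model)
}

#' End-to-end fold-recovery benchmark
#'
#' Builds a 40-class synthetic fragment library, trains stage 1 at reduced
#' widths, generates four synthetic folds with disjoint block mixtures over
#' the fragment classes, runs the full pipeline (segmentation,
#' featurization, fragment vectors) and trains the stage-2 CNN on the
#' training sequences' fragment vectors; reports held-out fold accuracy.
#'
#' @param seed Integer seed.
#' @param n_classes,samples_per_class Library conditions (the 40-class
#'   default keeps the fragment vector long enough for the CNN stack).
#' @param n_folds,seqs_per_fold Fold-dataset conditions.
#' @return List with `accuracy`, `n_test`, `stage1`, `stage2`, and the
#'   fragment-vector matrix.
#' @export
run_fold_benchmark <- function(seed = 1L, n_classes = 40L,
                               samples_per_class = 50L,
                               n_folds = 4L, seqs_per_fold = 25L) {
  lib <- make_fragment_library(synthetic_library_spec(
    n_classes = n_classes, samples_per_class = samples_per_class,
    motif_strength = 0.9, seed = seed))
  feats <- featurize_library(lib)
  cfg <- .benchmark_config(seed + 2L)
  s1 <- train_fragment_predictor(feats$x, feats$y, cfg,
                                 n_classes = n_classes,
                                 modality_dims = .REDUCED_MODALITY_DIMS,
                                 fusion_dim = 64L, fc_width = 64L)

  ds <- make_fold_dataset(synthetic_fold_spec(
    block_fold_mixtures(n_folds, n_classes),
    seqs_per_fold = seqs_per_fold, seq_length_range = c(25L, 40L),
    seed = seed + 10L), lib)
  y <- vapply(ds, `[[`, integer(1), "fold_label")
  vecs <- t(vapply(ds, function(rec) {
    windows <- segment_sequence(rec$sequence, rec$profile)
    build_fragment_vector(windows, s1$model)$values
  }, numeric(n_classes)))

  te <- .holdout_idx(y, 0.25, seed + 11L)
  tr <- setdiff(seq_along(y), te)
  cfg2 <- .benchmark_config(seed + 12L, batch_size = 50L, max_epochs = 300L,
                            patience = 30L)
  s2 <- train_fold_cnn(vecs[tr, ], y[tr], cfg2, n_folds = n_folds)
  pred <- max.col(cnn_forward(s2$model, vecs[te, ]), ties.method = "first") - 1L
  list(accuracy = mean(pred == y[te]), n_test = length(te),
       stage1 = s1$model, stage2 = s2$model, vectors = vecs, labels = y)
}

#' Write a small self-contained synthetic workspace
#'
#' Generates a fragment library and a fold dataset on disk together with
#' ready-to-run YAML configurations for [run_train()] and [run_predict()],
#' at a deliberately small scale. Two invocations with the same seed produce
#' byte-identical artifacts.
#'
#' @param dir Workspace directory (created).
#' @param seed Integer seed.
#' @param n_classes,samples_per_class,n_folds,seqs_per_fold Scale knobs.
#' @param max_epochs Training epochs written into the config.
#' @return List with paths: `train_config`, `predict_config`, `out_dir`.
#' @export
make_demo_workspace <- function(dir, seed = 1L, n_classes = 40L,
                                samples_per_class = 10L, n_folds = 2L,
                                seqs_per_fold = 6L, max_epochs = 2L) {
  lib <- make_fragment_library(synthetic_library_spec(
    n_classes = n_classes, samples_per_class = samples_per_class,
    motif_strength = 0.9, seed = seed))
  write_fragment_library(lib, file.path(dir, "library"))
  ds <- make_fold_dataset(synthetic_fold_spec(
    block_fold_mixtures(n_folds, n_classes), seqs_per_fold = seqs_per_fold,
    seq_length_range = c(25L, 32L), seed = seed + 10L), lib)
  write_fold_dataset(ds, file.path(dir, "folds"))
  out_dir <- file.path(dir, "out")
  train_cfg <- list(
    seed = seed, library_dir = file.path(dir, "library"), out_dir = out_dir,
    architecture = list(modality_dims = list(sequence = c(16L, 8L),
                                             physicochemical = c(16L, 8L),
                                             evolutionary = c(32L, 16L)),
                        fusion_dim = 16L, fc_width = 16L),
    training = list(learning_rate = 1e-3, batch_size = 100L,
                    max_epochs = max_epochs, patience = 5L,
                    pretrain_epochs = 1L),
    fold_data = list(fasta = file.path(dir, "folds", "sequences.fasta"),
                     pssm_dir = file.path(dir, "folds", "pssm"),
                     labels = file.path(dir, "folds", "labels.tsv")))
  predict_cfg <- list(
    seed = seed, stage1 = file.path(out_dir, "stage1.rds"),
    stage2 = file.path(out_dir, "stage2.rds"),
    fasta = file.path(dir, "folds", "sequences.fasta"),
    pssm_dir = file.path(dir, "folds", "pssm"),
    out_dir = out_dir)
  yaml::write_yaml(train_cfg, file.path(dir, "train.yaml"))
  yaml::write_yaml(predict_cfg, file.path(dir, "predict.yaml"))
  list(train_config = file.path(dir, "train.yaml"),
       predict_config = file.path(dir, "predict.yaml"),
       out_dir = out_dir)
}
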