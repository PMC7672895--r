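## End-to-end orchestration: sliding-window segmentation, per-window
## featurization and fragment-class prediction, aggregation into a
## per-sequence fragment vector, and fold classification.

#' Segment a sequence into sliding-window fragments
#'
#' Emits every window of every length in `[min_len, max_len]` at stride 1,
#' in (length, start) lexicographic order; total count is
#' `sum_k max(0, L - k + 1)`.
#'
#' @param seq An [aa_sequence()].
#' @param profile A [pssm_profile()] aligned to `seq`.
#' @param min_len,max_len Window length range (default 4-20).
#' @return List of `FragmentWindow` objects (fields `parent_id`, `start`
#'   0-based, `length`, `sequence`, `profile_slice`).
#' @export
segment_sequence <- function(seq, profile, min_len = 4L, max_len = 20L) {
  L <- nchar(seq$residues)
  if (L < min_len)
    stop("sequence '", seq$id, "' too short (", L, " < ", min_len, ")")
  Lp <- nrow(profile$scores)
  if (Lp > L)
    stop("profile not aligned to sequence '", seq$id, "'")
  if (Lp < L) {
    # a profile can come up short when its reader dropped rows; windows
    # without a complete score slice are dropped rather than zero-filled
    warning("profile for '", seq$id, "' covers ", Lp, " of ", L,
            " positions; windows beyond it are dropped")
    L <- Lp
    if (L < min_len)
      stop("sequence '", seq$id, "' too short after profile truncation")
  }
  windows <- list()
  for (k in min_len:min(max_len, L)) {
    for (start in 0:(L - k)) {
      windows[[length(windows) + 1L]] <- structure(
        list(parent_id = seq$id, start = start, length = k,
             sequence = substr(seq$residues, start + 1L, start + k),
             profile_slice = profile$scores[(start + 1L):(start + k), ,
                                            drop = FALSE]),
        class = "FragmentWindow")
    }
  }
  windows
}

#' Featurize one fragment window
#'
#' @param w A `FragmentWindow` from [segment_sequence()].
#' @return A `FragmentFeatureSet` with all ten blocks (1,759 values).
#' @export
featurize_window <- function(w) {
  fragment_features(aa_sequence(sprintf("%s:%d+%d", w$parent_id, w$start, w$length),
                                w$sequence),
                    pssm_profile(w$sequence, w$profile_slice),
                    fragment_id = sprintf("%s:%d+%d", w$parent_id, w$start, w$length))
}

#' Featurize a list of windows into a matrix
#'
#' @param windows List of `FragmentWindow`s.
#' @return Numeric matrix, one 1759-long row per window.
#' @export
featurize_windows <- function(windows) {
  layout <- feature_layout()
  x <- matrix(0, length(windows), layout$total)
  for (i in seq_along(windows))
    x[i, ] <- .fragment_feature_values(windows[[i]]$sequence,
                                       windows[[i]]$profile_slice)
  x
}

#' Aggregate per-window predictions into a fragment vector
#'
#' Soft mode (default) averages the per-window softmax distributions, so the
#' vector retains prediction uncertainty and sums to one; hard mode is the
#' normalized histogram of per-window argmax classes.
#'
#' @param windows List of `FragmentWindow`s (at least one).
#' @param predictor A trained `FragmentPredictor`.
#' @param mode `"soft"` or `"hard"`.
#' @param batch_size Windows featurized and forwarded per batch.
#' @return A `FragmentVector` (fields `parent_id`, `values`, `n_windows`,
#'   `mode`).
#' @export
build_fragment_vector <- function(windows, predictor, mode = c("soft", "hard"),
                                  batch_size = 2000L) {
  mode <- match.arg(mode)
  if (!length(windows)) stop("cannot build a fragment vector from zero windows")
  acc <- numeric(predictor$n_classes)
  for (start in seq(1L, length(windows), by = batch_size)) {
    chunk <- windows[start:min(start + batch_size - 1L, length(windows))]
    probs <- multimodal_forward(predictor, featurize_windows(chunk))
    if (mode == "soft") acc <- acc + colSums(probs)
    else acc <- acc + tabulate(max.col(probs, ties.method = "first"),
                               nbins = predictor$n_classes)
  }
  structure(list(parent_id = windows[[1]]$parent_id,
                 values = acc / length(windows),
                 n_windows = length(windows), mode = mode),
            class = "FragmentVector")
}

#' Predict the fold of one sequence
#'
#' Runs the full two-stage pipeline: segment, featurize, predict per-window
#' fragment distributions, aggregate, classify. Deterministic at inference.
#'
#' @param seq An [aa_sequence()].
#' @param profile A [pssm_profile()] aligned to `seq`.
#' @param stage1 A trained `FragmentPredictor`.
#' @param stage2 A trained `FoldCNN` whose input length equals
#'   `stage1$n_classes`.
#' @param min_len,max_len Window length range.
#' @param mode Fragment-vector aggregation mode.
#' @return A `FoldPrediction` (fields `parent_id`, `fold_probs`, `top_fold`
#'   0-based argmax with ties broken toward the lowest index, and
#'   `fragment_vector`).
#' @export
predict_fold <- function(seq, profile, stage1, stage2,
                         min_len = 4L, max_len = 20L, mode = "soft") {
  if (stage2$n_input != stage1$n_classes)
    stop("model mismatch: stage-2 input length ", stage2$n_input,
         " != stage-1 class count ", stage1$n_classes)
  windows <- segment_sequence(seq, profile, min_len, max_len)
  fv <- build_fragment_vector(windows, stage1, mode)
  probs <- cnn_forward(stage2, fv$values)
  structure(list(parent_id = seq$id, fold_probs = probs,
                 top_fold = which.max(probs) - 1L, fragment_vector = fv),
            class = "FoldPrediction")
}

## ---- config-driven entry points ------------------------------------------

.read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (field in c("seed"))
    if (is.null(cfg[[field]])) stop("config is missing required field: ", field)
  cfg
}

.config_train_config <- function(cfg) {
  tc <- cfg$training %||% list()
  train_config(learning_rate = tc$learning_rate %||% 1e-4,
               batch_size = tc$batch_size %||% 500L,
               dropout = tc$dropout %||% 0.5,
               max_epochs = tc$max_epochs %||% 100L,
               patience = tc$patience %||% 10L,
               seed = cfg$seed,
               cd_steps = tc$cd_steps %||% 1L,
               pretrain_epochs = tc$pretrain_epochs %||% 5L)
}

#' Train both stage models from a YAML run configuration
#'
#' The configuration names a fragment-library directory (stage-1 training
#' data), a fold dataset (FASTA + PSSM directory + label table) for stage 2,
#' a seed, optional architecture/training overrides, and an output
#' directory. Produces `stage1.rds`, `stage2.rds` and tab-separated training
#' histories under the output directory.
#'
#' @param config_path Path to the YAML configuration.
#' @return Invisibly, the output directory.
#' @export
run_train <- function(config_path) {
  cfg <- .read_run_config(config_path)
  for (field in c("library_dir", "out_dir"))
    if (is.null(cfg[[field]])) stop("config is missing required field: ", field)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tc <- .config_train_config(cfg)
  arch <- cfg$architecture %||% list()

  lib <- read_fragment_library(cfg$library_dir)
  feats <- featurize_library(lib)
  s1 <- train_fragment_predictor(
    feats$x, feats$y, tc, n_classes = lib$n_classes,
    modality_dims = .arch_modality_dims(arch),
    fusion_dim = arch$fusion_dim %||% 512L,
    fc_width = arch$fc_width %||% 1000L)
  save_checkpoint(s1$model, file.path(out_dir, "stage1.rds"))
  utils::write.table(s1$history, file.path(out_dir, "stage1_history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(cfg$fold_data)) {
    fd <- .read_fold_dataset(cfg$fold_data)
    win <- cfg$windows %||% list()
    vecs <- t(vapply(seq_along(fd$seqs), function(i) {
      windows <- segment_sequence(fd$seqs[[i]], fd$profiles[[i]],
                                  win$min_len %||% 4L, win$max_len %||% 20L)
      build_fragment_vector(windows, s1$model)$values
    }, numeric(lib$n_classes)))
    s2 <- train_fold_cnn(vecs, fd$labels, tc,
                         n_folds = max(fd$labels) + 1L,
                         fc_width = arch$cnn_fc_width %||% 100L)
    save_checkpoint(s2$model, file.path(out_dir, "stage2.rds"))
    utils::write.table(s2$history, file.path(out_dir, "stage2_history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

.arch_modality_dims <- function(arch) {
  md <- arch$modality_dims
  if (is.null(md)) return(.DEFAULT_MODALITY_DIMS)
  lapply(md, as.integer)
}

## fold_data config block: fasta, pssm_dir, labels (tsv with id, fold_label)
.read_fold_dataset <- function(fd) {
  for (field in c("fasta", "pssm_dir", "labels"))
    if (is.null(fd[[field]])) stop("fold_data config is missing field: ", field)
  seqs <- read_fasta(fd$fasta)
  labels_tab <- utils::read.delim(fd$labels, stringsAsFactors = FALSE)
  ids <- vapply(seqs, `[[`, character(1), "id")
  lab <- labels_tab$fold_label[match(ids, labels_tab$id)]
  if (anyNA(lab)) stop("labels table is missing ids: ",
                       paste(ids[is.na(lab)], collapse = ", "))
  profiles <- lapply(ids, function(id)
    read_pssm_ascii(file.path(fd$pssm_dir, paste0(id, ".pssm")), id = id))
  list(seqs = seqs, profiles = profiles, labels = as.integer(lab))
}

#' Predict folds for a FASTA of sequences from a YAML run configuration
#'
#' Loads the two stage checkpoints and writes a tab-separated prediction
#' table (`id`, `top_fold`, `n_windows`, then one probability column per
#' fold, 1-based user-facing fold names) to `predictions.tsv` in the output
#' directory.
#'
#' @param config_path Path to the YAML configuration (fields: `stage1`,
#'   `stage2` checkpoint paths, `fasta`, `pssm_dir`, `out_dir`, `seed`).
#' @return Invisibly, the path of the prediction table.
#' @export
run_predict <- function(config_path) {
  cfg <- .read_run_config(config_path)
  for (field in c("stage1", "stage2", "fasta", "pssm_dir", "out_dir"))
    if (is.null(cfg[[field]])) stop("config is missing required field: ", field)
  stage1 <- load_checkpoint(cfg$stage1)
  stage2 <- load_checkpoint(cfg$stage2, n_classes = stage1$n_classes)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- read_fasta(cfg$fasta)
  win <- cfg$windows %||% list()
  rows <- vapply(seqs, function(s) {
    prof <- read_pssm_ascii(file.path(cfg$pssm_dir, paste0(s$id, ".pssm")),
                            id = s$id)
    pred <- predict_fold(s, prof, stage1, stage2,
                         win$min_len %||% 4L, win$max_len %||% 20L)
    paste(c(s$id, pred$top_fold, pred$fragment_vector$n_windows,
            sprintf("%.6f", pred$fold_probs)), collapse = "\t")
  }, character(1))
  out_path <- file.path(cfg$out_dir, "predictions.tsv")
  header <- paste(c("id", "top_fold", "n_windows",
                    sprintf("fold%d_prob", seq_len(stage2$n_folds) - 1L)),
                  collapse = "\t")
  writeLines(c(header, rows), out_path)
  invisible(out_path)
}
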