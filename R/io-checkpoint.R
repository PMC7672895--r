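.CHECKPOINT_VERSION <- 1L

#' Save a trained model to a checkpoint file
#'
#' Stores either stage model (or a named list of both) in a single RDS
#' container together with a format version and its shape signature, so
#' loading can verify compatibility before use. Parameters round-trip
#' bit-exactly: a reloaded model produces identical forward outputs.
#'
#' @param model A `FragmentPredictor`, a `FoldCNN`, or a named list of models.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(version = .CHECKPOINT_VERSION,
                  type = class(model)[[1]],
                  shapes = .model_shapes(model),
                  model = model)
  saveRDS(payload, path)
  invisible(path)
}

.model_shapes <- function(model) {
  if (inherits(model, "FragmentPredictor"))
    list(n_classes = model$n_classes, input_dim = length(model$mu))
  else if (inherits(model, "FoldCNN"))
    list(n_folds = model$n_folds, n_input = model$n_input)
  else if (is.list(model))
    lapply(model, .model_shapes)
  else stop("cannot checkpoint object of class ", class(model)[[1]])
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @param n_classes,n_folds Optional expected shapes; a mismatch raises a
#'   checkpoint error reporting expected vs found values.
#' @return The stored model (or named list of models).
#' @export
load_checkpoint <- function(path, n_classes = NULL, n_folds = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  payload <- readRDS(path)
  if (!is.list(payload) || is.null(payload$version))
    stop("not a model checkpoint: ", path)
  if (payload$version != .CHECKPOINT_VERSION)
    stop("checkpoint version mismatch: expected ", .CHECKPOINT_VERSION,
         ", found ", payload$version)
  m <- payload$model
  if (!is.null(n_classes)) {
    found <- if (inherits(m, "FragmentPredictor")) m$n_classes
             else if (inherits(m, "FoldCNN")) m$n_input  # fragment-class count
             else payload$shapes$n_classes
    if (!identical(as.integer(found), as.integer(n_classes)))
      stop("checkpoint shape mismatch: expected n_classes = ", n_classes,
           ", found ", found %||% "none")
  }
  if (!is.null(n_folds)) {
    found <- if (inherits(m, "FoldCNN")) m$n_folds else payload$shapes$n_folds
    if (!identical(as.integer(found), as.integer(n_folds)))
      stop("checkpoint shape mismatch: expected n_folds = ", n_folds,
           ", found ", found %||% "none")
  }
  m
}
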