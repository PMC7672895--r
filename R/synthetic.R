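## Synthetic data with controllable class separation, so the whole pipeline
## is trainable and verifiable at desk scale. Fragment classes carry a
## class-specific sequence signal (a consensus sequence receiving
## `motif_strength` of the probability mass per position); folds are defined
## as characteristic mixtures of fragment-class usage; profiles are BLOSUM62
## log-odds rows of the sequence plus rounded Gaussian noise. Every
## generator is a pure function of (spec, seed).

#' Specification of a synthetic fragment library
#'
#' @param n_classes Number of fragment classes (>= 2).
#' @param samples_per_class Fragments generated per class.
#' @param length_range Inclusive fragment-length range within `[4, 20]`.
#' @param motif_strength Probability mass on the class consensus residue at
#'   each position (1 = every sample equals the consensus; 0.05 = uniform).
#' @param profile_noise Standard deviation of the rounded Gaussian noise
#'   added to BLOSUM62 rows when synthesizing profiles.
#' @param seed Integer seed.
#' @return A `SyntheticLibrarySpec` list.
#' @export
synthetic_library_spec <- function(n_classes = 10L, samples_per_class = 100L,
                                   length_range = c(4L, 20L),
                                   motif_strength = 0.9, profile_noise = 1,
                                   seed = 1L) {
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (motif_strength < 0 || motif_strength > 1)
    stop("motif_strength must be in [0, 1]")
  if (length_range[1] < 4L || length_range[2] > 20L)
    stop("length_range must lie within [4, 20]")
  list(n_classes = as.integer(n_classes),
       samples_per_class = as.integer(samples_per_class),
       length_range = as.integer(length_range),
       motif_strength = motif_strength, profile_noise = profile_noise,
       seed = as.integer(seed))
}

.sample_residues <- function(n, consensus = NULL, motif_strength = 0) {
  if (is.null(consensus))
    return(sample(AA_ALPHABET, n, replace = TRUE))
  take <- stats::runif(n) < motif_strength
  out <- consensus
  if (any(!take))
    out[!take] <- vapply(consensus[!take], function(cres)
      sample(setdiff(AA_ALPHABET, cres), 1L), character(1))
  out
}

#' Synthesize a PSSM profile for a sequence
#'
#' Row k is the BLOSUM62 log-odds row of residue k plus independent rounded
#' Gaussian noise, giving integer scores as in the ASCII dialect.
#'
#' @param seq An [aa_sequence()] or residue string.
#' @param noise Noise standard deviation (0 = exact BLOSUM62 rows).
#' @param seed Optional seed (omit to draw from the current RNG stream).
#' @return A [pssm_profile()].
#' @export
synth_pssm <- function(seq, noise = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(seq)) seq <- aa_sequence("synthetic", seq)
  res <- .residues_of(seq)
  b62 <- blosum62()
  scores <- b62[res, , drop = FALSE]
  if (noise > 0)
    scores <- scores + matrix(round(stats::rnorm(length(scores), sd = noise)),
                              nrow(scores), 20L)
  rownames(scores) <- NULL
  pssm_profile(seq, scores)
}

#' Generate a synthetic fragment library
#'
#' Per class: draw a consensus sequence and length, then sample each
#' fragment position from a categorical distribution putting
#' `motif_strength` on the consensus residue and the remainder uniformly on
#' the other 19; attach a synthetic profile per fragment.
#'
#' @param spec A [synthetic_library_spec()].
#' @return A [fragment_library()]; deterministic under `spec$seed`.
#' @export
make_fragment_library <- function(spec) {
  set.seed(spec$seed)
  records <- list()
  for (cl in seq_len(spec$n_classes) - 1L) {
    len <- sample(spec$length_range[1]:spec$length_range[2], 1L)
    consensus <- .sample_residues(len)
    for (s in seq_len(spec$samples_per_class)) {
      res <- paste(.sample_residues(len, consensus, spec$motif_strength),
                   collapse = "")
      id <- sprintf("c%03d_s%04d", cl, s)
      sq <- aa_sequence(id, res)
      records[[length(records) + 1L]] <-
        fragment_record(sq, cl, synth_pssm(sq, spec$profile_noise))
    }
  }
  fragment_library(records, spec$n_classes)
}

#' Specification of a synthetic fold dataset
#'
#' @param fragment_mixtures Matrix (n_folds x n_classes) of per-fold
#'   probability vectors over fragment classes; rows must sum to 1.
#' @param seqs_per_fold Sequences generated per fold.
#' @param seq_length_range Inclusive target sequence-length range.
#' @param profile_noise Profile noise standard deviation.
#' @param seed Integer seed.
#' @return A `SyntheticFoldSpec` list.
#' @export
synthetic_fold_spec <- function(fragment_mixtures, seqs_per_fold = 50L,
                                seq_length_range = c(30L, 45L),
                                profile_noise = 1, seed = 1L) {
  fragment_mixtures <- as.matrix(fragment_mixtures)
  if (nrow(fragment_mixtures) < 2L) stop("need at least 2 folds")
  if (any(abs(rowSums(fragment_mixtures) - 1) > 1e-8))
    stop("each fold mixture must sum to 1")
  list(n_folds = nrow(fragment_mixtures),
       fragment_mixtures = fragment_mixtures,
       seqs_per_fold = as.integer(seqs_per_fold),
       seq_length_range = as.integer(seq_length_range),
       profile_noise = profile_noise, seed = as.integer(seed))
}

#' Block-structured fold mixtures
#'
#' Convenience constructor for well-separated folds: fold f puts its mass
#' uniformly on its own contiguous block of fragment classes.
#'
#' @param n_folds Number of folds.
#' @param n_classes Number of fragment classes (divisible by `n_folds`).
#' @return Mixture matrix for [synthetic_fold_spec()].
#' @export
block_fold_mixtures <- function(n_folds, n_classes) {
  if (n_classes %% n_folds != 0L)
    stop("n_classes must be divisible by n_folds")
  per <- n_classes %/% n_folds
  m <- matrix(0, n_folds, n_classes)
  for (f in seq_len(n_folds))
    m[f, ((f - 1L) * per + 1L):(f * per)] <- 1 / per
  m
}

#' Generate a synthetic fold dataset
#'
#' Each sequence is built by concatenating fragments drawn from the fold's
#' class mixture (a uniformly-sampled member of each drawn class) until the
#' target length is reached, truncating the final fragment; a profile is
#' synthesized for the concatenated sequence.
#'
#' @param spec A [synthetic_fold_spec()].
#' @param library A [fragment_library()] with
#'   `ncol(spec$fragment_mixtures)` classes.
#' @return List of records, each with `sequence`, `profile`, `fold_label`
#'   (0-based) and `class_usage` (realized fragment-class counts);
#'   deterministic under `spec$seed`.
#' @export
make_fold_dataset <- function(spec, library) {
  if (ncol(spec$fragment_mixtures) != library$n_classes)
    stop("mixture width ", ncol(spec$fragment_mixtures),
         " != library n_classes ", library$n_classes)
  by_class <- split(library$records,
                    vapply(library$records, `[[`, integer(1), "class_label"))
  for (cl in which(colSums(spec$fragment_mixtures) > 0))
    if (!length(by_class[[as.character(cl - 1L)]]))
      stop("mixture puts mass on empty fragment class ", cl - 1L)
  set.seed(spec$seed)
  out <- list()
  for (f in seq_len(spec$n_folds)) {
    mix <- spec$fragment_mixtures[f, ]
    for (s in seq_len(spec$seqs_per_fold)) {
      target <- sample(spec$seq_length_range[1]:spec$seq_length_range[2], 1L)
      res <- ""
      usage <- numeric(library$n_classes)
      while (nchar(res) < target) {
        cl <- sample.int(library$n_classes, 1L, prob = mix)
        members <- by_class[[as.character(cl - 1L)]]
        frag <- members[[sample.int(length(members), 1L)]]$sequence$residues
        res <- paste0(res, frag)
        usage[[cl]] <- usage[[cl]] + 1
      }
      res <- substr(res, 1L, target)
      id <- sprintf("f%02d_s%04d", f - 1L, s)
      sq <- aa_sequence(id, res)
      out[[length(out) + 1L]] <- list(sequence = sq,
                                      profile = synth_pssm(sq, spec$profile_noise),
                                      fold_label = f - 1L,
                                      class_usage = usage)
    }
  }
  out
}
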