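## Assembly of the full per-fragment feature representation: ten blocks in
## three groups, concatenated into a fixed 1,759-long vector.
##
##   sequence        group_freq 10 | entropy 2 | distribution 20 | transition 45
##   physicochemical pseaac 40 | dwt 42
##   evolutionary    p_pssm 400 | pssm_dc 400 | bigram_pssm 400 | ed_pssm 400

#' The fixed feature layout
#'
#' @return List with `blocks` (named integer vector of block dimensions in
#'   order), `total` (1759), and `group_spans` (list of `c(first, last)`
#'   1-based column ranges for the three feature groups).
#' @export
feature_layout <- function() {
  dims <- c(group_freq = 10L, entropy = 2L, distribution = 20L, transition = 45L,
            pseaac = 40L, dwt = 42L,
            p_pssm = 400L, pssm_dc = 400L, bigram_pssm = 400L, ed_pssm = 400L)
  ends <- cumsum(dims)
  list(blocks = dims, total = sum(dims),
       starts = ends - dims + 1L, ends = ends,
       group_spans = list(sequence = c(1L, 77L),
                          physicochemical = c(78L, 159L),
                          evolutionary = c(160L, 1759L)))
}

#' Compute all ten feature blocks for one fragment
#'
#' @param sequence An [aa_sequence()] (length >= 4) or residue string.
#' @param profile A [pssm_profile()] over the same residues.
#' @param fragment_id Identifier stored in the result.
#' @return A `FragmentFeatureSet`: list with `fragment_id`, `blocks` (ordered
#'   list of `FeatureBlock`s), and `group_spans`.
#' @export
fragment_features <- function(sequence, profile,
                              fragment_id = if (inherits(sequence, "AminoAcidSequence"))
                                sequence$id else "fragment") {
  blocks <- c(sequence_group_features(sequence),
              physchem_group_features(sequence),
              evolutionary_group_features(profile))
  layout <- feature_layout()
  got <- vapply(blocks, `[[`, integer(1), "dim")
  if (!identical(unname(got), unname(layout$blocks)))
    stop("feature blocks do not match the fixed layout")
  structure(list(fragment_id = fragment_id, blocks = blocks,
                 group_spans = layout$group_spans),
            class = "FragmentFeatureSet")
}

#' Flatten a feature set into its 1,759-long numeric vector
#'
#' @param fs A `FragmentFeatureSet`.
#' @return Numeric vector of length 1759.
#' @export
feature_vector <- function(fs) {
  unlist(lapply(fs$blocks, `[[`, "values"), use.names = FALSE)
}

## Fast path used by batch featurization: residue string + score matrix in,
## bare numeric vector out, skipping the per-block containers.
.fragment_feature_values <- function(residues, scores) {
  p <- pssm_profile(residues, scores, id = "w")
  unlist(lapply(c(sequence_group_features(residues),
                  physchem_group_features(residues),
                  evolutionary_group_features(p)),
                `[[`, "values"), use.names = FALSE)
}

#' Featurize a fragment library into a matrix
#'
#' @param library A [fragment_library()].
#' @return List with `x` (n_records x 1759 matrix) and `y` (integer labels).
#' @export
featurize_library <- function(library) {
  layout <- feature_layout()
  n <- length(library$records)
  x <- matrix(0, n, layout$total)
  for (i in seq_len(n)) {
    r <- library$records[[i]]
    x[i, ] <- .fragment_feature_values(r$sequence$residues, r$profile$scores)
  }
  colnames(x) <- feature_column_names()
  list(x = x, y = vapply(library$records, `[[`, integer(1), "class_label"))
}

#' Column names for the flattened feature vector
#' @return Character vector of length 1759 (`block.index`).
#' @export
feature_column_names <- function() {
  layout <- feature_layout()
  unlist(lapply(names(layout$blocks), function(b)
    sprintf("%s.%d", b, seq_len(layout$blocks[[b]]))), use.names = FALSE)
}
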