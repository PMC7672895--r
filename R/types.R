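## Core domain containers. All are plain S3 lists so they serialize cleanly
## through checkpoints and are cheap to construct in tight loops.

#' Construct an amino-acid sequence record
#'
#' @param id Sequence identifier.
#' @param residues String over the 20-letter standard alphabet (upper case).
#' @return An `AminoAcidSequence` object.
#' @export
aa_sequence <- function(id, residues) {
  residues <- toupper(residues)
  if (nchar(residues) < 1L)
    stop("sequence '", id, "' is empty")
  bad <- setdiff(strsplit(residues, "")[[1]], AA_ALPHABET)
  if (length(bad))
    stop("sequence '", id, "' contains non-standard residues: ",
         paste(unique(bad), collapse = ""))
  structure(list(id = id, residues = residues), class = "AminoAcidSequence")
}

#' @export
print.AminoAcidSequence <- function(x, ...) {
  cat(sprintf("<AminoAcidSequence %s: %d aa>\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Remove non-standard characters from a raw residue string
#'
#' Gaps and non-protein letters (X, B, Z, U, O, '-', '.', '*') are removed,
#' not remapped; the number of removals is returned alongside.
#'
#' @param raw Character scalar.
#' @return List with `residues` (clean upper-case string) and `removed`
#'   (integer count of characters dropped).
#' @export
sanitize_residues <- function(raw) {
  up <- toupper(gsub("[[:space:]]", "", raw))
  clean <- gsub(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), "", up)
  list(residues = clean, removed = nchar(up) - nchar(clean))
}

#' Construct a PSSM profile
#'
#' @param sequence An [aa_sequence()] (or a bare residue string, in which case
#'   `id` is used).
#' @param scores L x 20 numeric matrix of log-odds scores, columns in
#'   [PSSM_COLUMN_ORDER].
#' @param id Identifier used when `sequence` is a bare string.
#' @return A `PSSMProfile` object.
#' @export
pssm_profile <- function(sequence, scores, id = "query") {
  if (is.character(sequence)) sequence <- aa_sequence(id, sequence)
  scores <- as.matrix(scores)
  if (nrow(scores) != nchar(sequence$residues))
    stop("profile row count (", nrow(scores), ") != sequence length (",
         nchar(sequence$residues), ")")
  if (ncol(scores) != 20L)
    stop("profile must have 20 columns")
  colnames(scores) <- PSSM_COLUMN_ORDER
  rownames(scores) <- NULL
  structure(list(sequence = sequence, scores = scores), class = "PSSMProfile")
}

#' @export
print.PSSMProfile <- function(x, ...) {
  cat(sprintf("<PSSMProfile %s: %d x 20>\n", x$sequence$id, nrow(x$scores)))
  invisible(x)
}

#' Slice a window out of a whole-sequence profile
#'
#' Rows `start+1 .. start+length` (0-based `start`) are excised together with
#' the matching residues, supporting fragment profiles cut from whole-protein
#' profiles.
#'
#' @param profile A [pssm_profile()].
#' @param start 0-based start of the window.
#' @param length Window length.
#' @param id Identifier for the sliced profile.
#' @return A `PSSMProfile` over the window.
#' @export
pssm_slice <- function(profile, start, length,
                       id = sprintf("%s:%d-%d", profile$sequence$id,
                                    start + 1L, start + length)) {
  L <- nrow(profile$scores)
  if (start < 0L || start + length > L)
    stop("window [", start, ", ", start + length, ") outside profile of length ", L)
  sub <- substr(profile$sequence$residues, start + 1L, start + length)
  pssm_profile(aa_sequence(id, sub),
               profile$scores[(start + 1L):(start + length), , drop = FALSE])
}

#' Construct a fragment record
#'
#' @param sequence An [aa_sequence()] of length 4-20.
#' @param class_label Integer class label in `[0, n_classes)`.
#' @param profile A [pssm_profile()] over the same sequence.
#' @return A `FragmentRecord` object.
#' @export
fragment_record <- function(sequence, class_label, profile) {
  L <- nchar(sequence$residues)
  if (L < 4L || L > 20L)
    stop("fragment '", sequence$id, "' has length ", L, "; must be in [4, 20]")
  if (!identical(profile$sequence$residues, sequence$residues))
    stop("fragment '", sequence$id, "': profile sequence does not match")
  structure(list(sequence = sequence, class_label = as.integer(class_label),
                 profile = profile), class = "FragmentRecord")
}

#' Construct a fragment library
#'
#' @param records List of [fragment_record()]s.
#' @param n_classes Number of fragment classes.
#' @param class_names Optional character vector of class names.
#' @return A `FragmentLibrary` object.
#' @export
fragment_library <- function(records, n_classes,
                             class_names = sprintf("frag%03d", seq_len(n_classes) - 1L)) {
  n_classes <- as.integer(n_classes)
  labels <- vapply(records, `[[`, integer(1), "class_label")
  if (length(records) && (min(labels) < 0L || max(labels) >= n_classes))
    stop("class labels must lie in [0, ", n_classes, ")")
  present <- sort(unique(labels))
  if (!identical(present, seq_len(n_classes) - 1L))
    stop("every class must have at least one record; missing: ",
         paste(setdiff(seq_len(n_classes) - 1L, present), collapse = ", "))
  structure(list(records = records, n_classes = n_classes,
                 class_names = class_names), class = "FragmentLibrary")
}

#' @export
print.FragmentLibrary <- function(x, ...) {
  cat(sprintf("<FragmentLibrary: %d records, %d classes>\n",
              length(x$records), x$n_classes))
  invisible(x)
}
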