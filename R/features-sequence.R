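## Sequence-composition feature blocks: functional-group frequencies (10),
## residue/dipeptide information entropy (2), mean relative positions (20),
## and cross-group transition frequencies (45). All operate on short
## fragments (4-20 residues) but are defined for any sequence meeting the
## stated minimum length.

.residues_of <- function(seq) {
  if (inherits(seq, "AminoAcidSequence")) seq <- seq$residues
  if (length(seq) > 1L) return(seq)  # already a residue vector
  strsplit(seq, "")[[1]]
}

.feature_block <- function(name, values) {
  structure(list(name = name, values = as.numeric(values),
                 dim = length(values)), class = "FeatureBlock")
}

#' Functional-group frequency block (dimension 10)
#'
#' Fraction of fragment residues falling in each of the ten side-chain
#' chemistry groups; entries sum to one.
#'
#' @param seq An [aa_sequence()] or residue string.
#' @param partition A [group_partition()]; defaults to the bundled one.
#' @return A `FeatureBlock` of dimension 10.
#' @export
functional_group_frequencies <- function(seq, partition = functional_groups()) {
  res <- .residues_of(seq)
  if (!length(res)) stop("empty sequence")
  g <- partition$index[res]
  .feature_block("group_freq", tabulate(g, nbins = 10L) / length(res))
}

.shannon_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Information-entropy block (dimension 2)
#'
#' Shannon entropy (bits) of the residue-type distribution and of the
#' overlapping-dipeptide distribution.
#'
#' @inheritParams functional_group_frequencies
#' @return A `FeatureBlock` of dimension 2.
#' @export
sequence_entropy <- function(seq) {
  res <- .residues_of(seq)
  L <- length(res)
  if (L < 2L) stop("sequence_entropy requires length >= 2")
  code <- match(res, AA_ALPHABET)
  h1 <- .shannon_bits(tabulate(code, 20L))
  h2 <- .shannon_bits(tabulate((code[-L] - 1L) * 20L + code[-1L], 400L))
  .feature_block("entropy", c(h1, h2))
}

#' Residue relative-position block (dimension 20)
#'
#' For each residue type, the mean of its relative positions i/L (1-based i)
#' over all occurrences; 0 when the type is absent.
#'
#' @inheritParams functional_group_frequencies
#' @return A `FeatureBlock` of dimension 20 in [AA_ALPHABET] order.
#' @export
residue_distribution <- function(seq) {
  res <- .residues_of(seq)
  if (!length(res)) stop("empty sequence")
  L <- length(res)
  relpos <- seq_len(L) / L
  out <- vapply(AA_ALPHABET, function(a) {
    hit <- res == a
    if (any(hit)) mean(relpos[hit]) else 0
  }, numeric(1))
  .feature_block("distribution", out)
}

#' Functional-group transition block (dimension 45)
#'
#' For each unordered pair of distinct groups, the fraction of adjacent
#' residue pairs whose groups are that pair (either order), out of L-1
#' adjacencies; same-group adjacencies contribute to no entry.
#'
#' @inheritParams functional_group_frequencies
#' @return A `FeatureBlock` of dimension 45, pairs ordered (1,2), (1,3), ...,
#'   (9,10).
#' @export
group_transitions <- function(seq, partition = functional_groups()) {
  res <- .residues_of(seq)
  L <- length(res)
  if (L < 2L) stop("group_transitions requires length >= 2")
  g <- partition$index[res]
  a <- pmin(g[-L], g[-1L])
  b <- pmax(g[-L], g[-1L])
  keep <- a != b
  counts <- numeric(45L)
  if (any(keep)) {
    # index of unordered pair (a,b), a < b, in lexicographic order
    idx <- (a[keep] - 1L) * 10L - a[keep] * (a[keep] - 1L) / 2 + (b[keep] - a[keep])
    tab <- table(idx)
    counts[as.integer(names(tab))] <- as.numeric(tab)
  }
  .feature_block("transition", counts / (L - 1L))
}

#' Concatenated sequence-composition feature group (dimension 77)
#'
#' Group frequencies, entropies, residue distribution and group transitions
#' in that fixed order.
#'
#' @inheritParams functional_group_frequencies
#' @return List of four `FeatureBlock`s totalling 77 values.
#' @export
sequence_group_features <- function(seq, partition = functional_groups()) {
  list(functional_group_frequencies(seq, partition),
       sequence_entropy(seq),
       residue_distribution(seq),
       group_transitions(seq, partition))
}
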