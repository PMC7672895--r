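## Evolutionary feature blocks: four 400-dimensional summaries of a
## fragment's PSSM. All 20x20 matrices are flattened row-major, rows indexed
## by the first residue/column of the pair in [PSSM_COLUMN_ORDER].

#' Logistic transform of a PSSM
#'
#' Elementwise `1 / (1 + exp(-score))`, mapping log-odds into (0, 1) so that
#' fragments of different score ranges are comparable.
#'
#' @param p A [pssm_profile()].
#' @return A `TransformedProfile` (list with `values` L x 20 matrix and
#'   `source` profile).
#' @export
transform_pssm <- function(p) {
  structure(list(values = 1 / (1 + exp(-p$scores)), source = p),
            class = "TransformedProfile")
}

.as_transformed <- function(t) {
  if (inherits(t, "PSSMProfile")) t <- transform_pssm(t)
  if (!inherits(t, "TransformedProfile")) stop("expected a TransformedProfile")
  t
}

.flatten_rowmajor <- function(m, name) .feature_block(name, as.vector(t(m)))

#' Profile-PSSM block (dimension 400)
#'
#' Entry (a, b) is the mean transformed score in column b over the positions
#' whose query residue is a; rows of residue types absent from the query are
#' zero.
#'
#' @param t A `TransformedProfile` (or a [pssm_profile()], transformed on the
#'   fly).
#' @return A `FeatureBlock` of dimension 400.
#' @export
p_pssm <- function(t) {
  t <- .as_transformed(t)
  res <- .residues_of(t$source$sequence)
  m <- matrix(0, 20L, 20L, dimnames = list(PSSM_COLUMN_ORDER, PSSM_COLUMN_ORDER))
  for (a in unique(res))
    m[a, ] <- colMeans(t$values[res == a, , drop = FALSE])
  .flatten_rowmajor(m, "p_pssm")
}

#' PSSM dipeptide-composition block (dimension 400)
#'
#' Entry (a, b) averages the product of the transformed score for residue
#' type a at position k and type b at position k+1 over the L-1 adjacent
#' position pairs.
#'
#' @inheritParams p_pssm
#' @return A `FeatureBlock` of dimension 400.
#' @export
pssm_dc <- function(t) {
  t <- .as_transformed(t)
  v <- t$values
  L <- nrow(v)
  if (L < 2L) stop("pssm_dc requires a profile of length >= 2")
  m <- crossprod(v[-L, , drop = FALSE], v[-1L, , drop = FALSE]) / (L - 1L)
  .flatten_rowmajor(m, "pssm_dc")
}

#' Bigram-PSSM block (dimension 400)
#'
#' Rows of the raw log-odds profile are softmax-normalized into per-position
#' residue distributions; entry (a, b) sums the product n[k, a] * n[k+1, b]
#' over adjacent positions (no length normalization, so all 400 entries sum
#' to L-1).
#'
#' @param p A [pssm_profile()].
#' @return A `FeatureBlock` of dimension 400.
#' @export
bigram_pssm <- function(p) {
  if (inherits(p, "TransformedProfile")) p <- p$source
  s <- p$scores
  L <- nrow(s)
  if (L < 2L) stop("bigram_pssm requires a profile of length >= 2")
  e <- exp(s - apply(s, 1L, max))
  n <- e / rowSums(e)
  m <- crossprod(n[-L, , drop = FALSE], n[-1L, , drop = FALSE])
  .flatten_rowmajor(m, "bigram_pssm")
}

#' Evolutionary-difference PSSM block (dimension 400)
#'
#' Entry (a, b) is the mean squared difference between the transformed score
#' of type a at position k and of type b at position k+d, averaged over the
#' L-d valid positions.
#'
#' @inheritParams p_pssm
#' @param d Positional lag (default 1); requires L > d.
#' @return A `FeatureBlock` of dimension 400.
#' @export
ed_pssm <- function(t, d = 1L) {
  t <- .as_transformed(t)
  v <- t$values
  L <- nrow(v)
  if (d < 1L) stop("d must be >= 1")
  if (L <= d) stop("ed_pssm requires profile length > d")
  v1 <- v[1:(L - d), , drop = FALSE]
  v2 <- v[(1 + d):L, , drop = FALSE]
  m <- (outer(colSums(v1^2), rep(1, 20L)) + outer(rep(1, 20L), colSums(v2^2)) -
          2 * crossprod(v1, v2)) / (L - d)
  dimnames(m) <- list(PSSM_COLUMN_ORDER, PSSM_COLUMN_ORDER)
  .flatten_rowmajor(m, "ed_pssm")
}

#' Concatenated evolutionary feature group (dimension 1600)
#'
#' P-PSSM, PSSM-DC, bigram-PSSM and ED-PSSM blocks in fixed order.
#'
#' @param p A [pssm_profile()] of length >= 2.
#' @param d Lag for the evolutionary-difference block.
#' @return List of four `FeatureBlock`s totalling 1600 values.
#' @export
evolutionary_group_features <- function(p, d = 1L) {
  t <- transform_pssm(p)
  list(p_pssm(t), pssm_dc(t), bigram_pssm(p), ed_pssm(t, d))
}
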