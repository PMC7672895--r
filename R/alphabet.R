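#' @keywords internal
"_PACKAGE"

## Canonical residue orderings used throughout the package.
##
## AA_ALPHABET fixes the order of composition-style feature entries;
## PSSM_COLUMN_ORDER is the PSI-BLAST column order every profile matrix is
## re-mapped to on read, so all downstream evolutionary features see one
## consistent layout.

#' The 20-letter amino-acid alphabet (alphabetical by one-letter code)
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Canonical PSSM column order (PSI-BLAST order)
#' @format Character vector of length 20.
#' @export
PSSM_COLUMN_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

.pkg_cache <- new.env(parent = emptyenv())

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "deepfragk")
  if (!nzchar(path)) stop("missing package data file: ", name)
  path
}

#' Load the bundled per-residue property scales
#'
#' Returns the five physicochemical scales used by the feature blocks
#' (Kyte-Doolittle hydrophobicity, Hopp-Woods hydrophilicity,
#' Bhaskaran-Ponnuswamy flexibility, Rose mean accessible surface area,
#' monoisotopic side-chain mass), each as a named numeric vector over the
#' 20 standard residues.
#'
#' @return Named list of `PropertyScale` objects (named numeric vectors with a
#'   `name` attribute).
#' @export
property_scales <- function() {
  if (is.null(.pkg_cache$scales)) {
    tab <- utils::read.delim(.extdata("property_scales.tsv"), comment.char = "#",
                             stringsAsFactors = FALSE)
    stopifnot(setequal(tab$residue, AA_ALPHABET))
    scales <- lapply(setdiff(names(tab), "residue"), function(col) {
      v <- stats::setNames(tab[[col]], tab$residue)[AA_ALPHABET]
      property_scale(col, v)
    })
    .pkg_cache$scales <- stats::setNames(scales, setdiff(names(tab), "residue"))
  }
  .pkg_cache$scales
}

#' Construct a property scale
#'
#' @param name Scale name.
#' @param values Named numeric vector covering all 20 standard residues.
#' @return A `PropertyScale` object.
#' @export
property_scale <- function(name, values) {
  if (!all(AA_ALPHABET %in% names(values)))
    stop("property scale '", name, "' must cover all 20 residues")
  v <- values[AA_ALPHABET]
  structure(v, name = name, class = "PropertyScale")
}

#' Load the bundled functional-group partition
#'
#' Ten disjoint side-chain chemistry classes covering the alphabet; the order
#' fixes the layout of the group-frequency and group-transition blocks.
#'
#' @return A `GroupPartition`: list with `groups` (list of 10 character
#'   vectors), `names` (length-10 character), and `index` (named integer
#'   mapping each residue to its group).
#' @export
functional_groups <- function() {
  if (is.null(.pkg_cache$groups)) {
    tab <- utils::read.delim(.extdata("functional_groups.tsv"), comment.char = "#",
                             stringsAsFactors = FALSE)
    groups <- strsplit(tab$residues, "")
    .pkg_cache$groups <- group_partition(groups, tab$name)
  }
  .pkg_cache$groups
}

#' Construct a functional-group partition
#'
#' @param groups List of 10 disjoint character vectors jointly covering the
#'   20-letter alphabet.
#' @param names Character vector of 10 group names.
#' @return A `GroupPartition` object.
#' @export
group_partition <- function(groups, names) {
  if (length(groups) != 10L) stop("a group partition must have exactly 10 groups")
  all_res <- unlist(groups)
  if (anyDuplicated(all_res) || !setequal(all_res, AA_ALPHABET))
    stop("groups must be pairwise disjoint and cover the 20-letter alphabet")
  index <- integer(0)
  for (g in seq_along(groups))
    index[groups[[g]]] <- g
  structure(list(groups = groups, names = names, index = index[AA_ALPHABET]),
            class = "GroupPartition")
}

#' Load the bundled BLOSUM62 substitution matrix
#'
#' @return 20x20 integer matrix with rows and columns in [PSSM_COLUMN_ORDER].
#' @export
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum)) {
    tab <- utils::read.delim(.extdata("blosum62.tsv"), check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1])
    rownames(m) <- tab$residue
    .pkg_cache$blosum <- m[PSSM_COLUMN_ORDER, PSSM_COLUMN_ORDER]
  }
  .pkg_cache$blosum
}
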